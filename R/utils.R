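# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global \code{.Random.seed}, so seeded operations do
#' not disturb the caller's random stream. All stochastic operations in the
#' package funnel through this helper, which is what makes them
#' seed-deterministic.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation (Lehmer-style step, kept below 2^31).
derive_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i)) %% 2147483629) + 1L
}

#' Exact multivariate hypergeometric draw
#'
#' Draws \code{k} items without replacement from urns with \code{counts} items
#' each, by the sequential conditional decomposition into univariate
#' hypergeometrics. Uses the current RNG state (callers wrap in a seed).
#'
#' @param k number of items to draw (\code{k <= sum(counts)}).
#' @param counts nonnegative integer vector of urn sizes.
#' @return integer vector, same length as \code{counts}, summing to \code{k}.
#' @keywords internal
rmvhyper <- function(k, counts) {
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (k > total) stop("cannot draw ", k, " items from a pool of ", total, call. = FALSE)
  out <- integer(length(counts))
  remaining <- total
  k <- as.numeric(k)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    m <- counts[i]
    if (m <= 0) {
      remaining <- remaining - m
      next
    }
    x <- stats::rhyper(1L, m, remaining - m, k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - m
  }
  out
}

# Parse an is_control-style flag column: accepts logical, 0/1, "true"/"false".
parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t")] <- TRUE
  out[v %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out) && length(v)) {
    bad <- unique(v[is.na(out)])
    stop("unrecognised logical flag value(s): ", paste(bad, collapse = ", "),
         " (expected 0/1/true/false)", call. = FALSE)
  }
  as.logical(out)
}

# Random distinct DNA sequences of a fixed length.
random_dna <- function(n, len) {
  if (n == 0) return(character())
  if (4^len < n) {
    stop("cannot generate ", n, " distinct sequences of length ", len,
         " (4^", len, " < ", n, ")", call. = FALSE)
  }
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  seqs <- draw(n)
  repeat {
    dup <- duplicated(seqs)
    if (!any(dup)) break
    seqs[dup] <- draw(sum(dup))
  }
  seqs
}
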