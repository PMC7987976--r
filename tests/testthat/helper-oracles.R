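# Independent brute-force oracle for the percentile-method z-scores: plain
# per-element loops, sharing no code with the package implementation.

bf_zscores <- function(counts, groups, control) {
  ids <- rownames(counts)
  stats <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    n <- length(cols)
    mu <- sd <- k <- sem <- numeric(length(ids))
    for (i in seq_along(ids)) {
      v <- as.numeric(counts[i, cols])
      mu[i] <- sum(v) / n
      ss <- 0
      for (x in v) ss <- ss + (x - mu[i])^2
      sd[i] <- sqrt(ss / (n - 1))
      k[i] <- sum(v > 0)
      sem[i] <- if (k[i] >= 1) sd[i] / sqrt(k[i]) else NA_real_
    }
    stats[[g]] <- list(mu = mu, sd = sd, k = k, sem = sem)
  }
  lung <- setdiff(colnames(counts), groups[[control]])
  grp_of <- function(s) names(groups)[vapply(groups, function(x) s %in% x,
                                             logical(1))]
  z <- matrix(NA_real_, length(ids), length(lung),
              dimnames = list(ids, lung))
  for (s in lung) {
    g <- grp_of(s)
    st <- stats[[g]]
    for (i in seq_along(ids)) {
      if (!is.na(st$sem[i]) && st$sem[i] > 0) {
        z[i, s] <- (counts[i, s] - stats[[control]]$mu[i]) / st$sem[i]
      }
    }
  }
  z
}
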