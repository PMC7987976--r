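# Joint guide-efficacy x gene-effect model over log ratios (a JACKS-style
# bilinear decomposition, not a bit-compatible reimplementation), ranked by
# the late-vs-early contrast.

#' Log2 ratios of lung samples against the control mean
#'
#' \code{y[g, s] = log2((n[g, s] + alpha) / (mean_control[g] + alpha))} for
#' every sample whose group is mapped to a model condition. The pseudocount
#' \code{alpha > 0} keeps every entry finite.
#'
#' @param cm normalized \code{count_matrix}.
#' @param control control group label.
#' @param alpha pseudocount (> 0).
#' @param condition_map named vector mapping group labels to condition labels.
#' @return object of class \code{log_fold_matrix}: list with \code{y},
#'   \code{condition} (per sample), \code{alpha}, \code{control_mean}.
#' @export
compute_log_ratios <- function(cm, control = "cells_500x", alpha = 0.5,
                               condition_map = c(lung_4h = "t4h",
                                                 lung_19d = "t19d")) {
  stopifnot(inherits(cm, "count_matrix"), alpha > 0)
  grp <- stats::setNames(cm$samples$group, cm$samples$sample_id)
  ctrl_ids <- names(grp)[grp == control]
  if (!length(ctrl_ids)) {
    stop("control group \"", control, "\" not found", call. = FALSE)
  }
  mu <- rowMeans(cm$counts[, ctrl_ids, drop = FALSE])
  smp <- names(grp)[grp %in% names(condition_map)]
  if (!length(smp)) stop("no samples belong to a mapped condition", call. = FALSE)
  y <- log2(sweep(cm$counts[, smp, drop = FALSE] + alpha, 1, mu + alpha, "/"))
  structure(
    list(y = y,
         condition = stats::setNames(unname(condition_map[grp[smp]]), smp),
         alpha = alpha, control_mean = mu),
    class = "log_fold_matrix"
  )
}

#' Fit the joint guide-efficacy / gene-effect model
#'
#' Models \code{y[g, s] ~ N(x_g * w[gene(g), cond(s)], tau2[cond(s)])} with
#' Gaussian priors \code{x ~ N(1, sigma_x^2)} and \code{w ~ N(0, sigma_w^2)},
#' a single efficacy per guide shared across conditions. Inference is
#' alternating exact conditional (ridge) updates of w, x and the
#' per-condition noise variances. The bilinear scale degeneracy is removed by
#' the identifiability constraint that each gene's guide efficacies average 1;
#' because the conditional x-objective has equal curvature for all guides of a
#' gene, the constraint is enforced exactly inside the x-update by a
#' closed-form Lagrangian shift, so every block update is an exact ascent step
#' and the penalized objective is non-decreasing across iterations.
#' Non-targeting controls are excluded from gene fitting but their residuals
#' (against effect 0) feed the noise estimate. Posterior standard deviations
#' come from the conditional Gaussian precisions at the constrained solution.
#'
#' Initialization is deterministic (x = 1, w = per-gene median of y per
#' condition); \code{init_jitter > 0} adds seeded Gaussian jitter to the
#' initial efficacies for identifiability checks via random restarts.
#'
#' @param y a \code{log_fold_matrix}.
#' @param lib the \code{guide_library} (gene map, control flags).
#' @param tol convergence tolerance on the max parameter change.
#' @param max_iter iteration cap; non-convergence returns a fit with
#'   \code{converged = FALSE} and a warning.
#' @param seed RNG seed (only used when \code{init_jitter > 0}).
#' @param sigma_x,sigma_w prior standard deviations.
#' @param init_jitter SD of the jitter on the initial w.
#' @return object of class \code{joint_fit}: gene effects \code{w} and
#'   posterior sds \code{w_sd} (genes x conditions), guide efficacies \code{x}
#'   and \code{x_sd}, noise variances \code{tau2}, \code{iterations},
#'   \code{converged}, and the penalized objective trace.
#' @export
fit_joint_model <- function(y, lib, tol = 1e-8, max_iter = 500, seed = 1,
                            sigma_x = 0.5, sigma_w = 10, init_jitter = 0) {
  stopifnot(inherits(y, "log_fold_matrix"), inherits(lib, "guide_library"))
  Y <- y$y
  cond <- y$condition[colnames(Y)]
  conds <- unique(unname(cond))
  gmap <- stats::setNames(lib$guides$gene, lib$guides$guide_id)
  ctrl <- stats::setNames(lib$guides$is_control, lib$guides$guide_id)
  if (anyNA(match(rownames(Y), names(gmap)))) {
    stop("log-ratio matrix contains guides absent from the library", call. = FALSE)
  }
  gene <- gmap[rownames(Y)]
  is_ctrl <- ctrl[rownames(Y)]
  targ <- !is_ctrl
  if (!any(targ)) stop("no targeting guides to fit", call. = FALSE)
  genes <- sort(unique(gene[targ]))
  gidx <- match(gene, genes)          # NA for controls
  gidx_t <- gidx[targ]
  n_per_gene <- tabulate(gidx_t, nbins = length(genes))

  cols <- lapply(conds, function(cc) which(cond == cc))
  names(cols) <- conds
  n_c <- vapply(cols, length, integer(1))
  # Sufficient statistic: per-guide sum of y over each condition's samples.
  ysum <- matrix(vapply(conds, function(cc) rowSums(Y[, cols[[cc]], drop = FALSE]),
                        numeric(nrow(Y))),
                 nrow = nrow(Y), dimnames = list(rownames(Y), conds))

  # Deterministic init: w = per-gene median of y within condition; x = 1.
  W <- vapply(conds, function(cc) {
    v <- Y[targ, cols[[cc]], drop = FALSE]
    vapply(split(as.vector(v), gidx_t[row(v)]), stats::median, numeric(1))
  }, numeric(length(genes)))
  W <- matrix(W, nrow = length(genes), dimnames = list(genes, conds))
  x <- stats::setNames(rep(1, nrow(Y)), rownames(Y))
  if (init_jitter > 0) {
    jit <- with_seed(seed, stats::rnorm(sum(targ), 0, init_jitter))
    xj <- 1 + jit
    xj <- xj - (rowsum(xj, gidx_t)[, 1L] / n_per_gene)[gidx_t] + 1
    x[targ] <- xj
  }
  tau2 <- stats::setNames(rep(1, length(conds)), conds)

  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  prec_w <- NULL
  for (iter in seq_len(max_iter)) {
    W_old <- W; x_old <- x
    xt <- x[targ]
    # w update: exact conditional maximizer per (gene, condition).
    sxy <- rowsum(xt * ysum[targ, , drop = FALSE], gidx_t)  # genes x conds
    sxx <- rowsum(xt^2, gidx_t)[, 1L]
    prec_w <- sweep(matrix(sxx, length(genes), length(conds)), 2,
                    n_c / tau2, "*") + 1 / sigma_w^2
    W <- sweep(sxy, 2, tau2, "/") / prec_w
    dimnames(W) <- list(genes, conds)
    # x update: exact conditional maximizer per targeting guide, subject to
    # the gene-mean-1 constraint. The curvature is constant within a gene, so
    # the constrained maximizer is the free ridge solution shifted per gene
    # (closed-form Lagrange multiplier).
    Wg <- W[gidx_t, , drop = FALSE]
    num <- rowSums(sweep(Wg * ysum[targ, , drop = FALSE], 2, tau2, "/")) +
      1 / sigma_x^2
    den <- rowSums(sweep(Wg^2, 2, n_c / tau2, "*")) + 1 / sigma_x^2
    x_free <- num / den
    x[targ] <- x_free - (rowsum(x_free, gidx_t)[, 1L] / n_per_gene)[gidx_t] + 1
    # Noise update from residuals; controls contribute against effect 0.
    fitted <- matrix(0, nrow(Y), ncol(Y))
    fitted[targ, ] <- (x[targ] * W[gidx_t, , drop = FALSE])[, cond, drop = FALSE]
    R2 <- (Y - fitted)^2
    for (cc in conds) tau2[cc] <- max(mean(R2[, cols[[cc]]]), 1e-12)
    # Penalized objective after the iteration's exact block updates.
    ll <- -sum(vapply(conds, function(cc)
      0.5 * nrow(Y) * n_c[[cc]] * log(2 * pi * tau2[[cc]]) +
        sum(R2[, cols[[cc]]]) / (2 * tau2[[cc]]), numeric(1)))
    objective <- c(objective, ll - sum((x[targ] - 1)^2) / (2 * sigma_x^2) -
                     sum(W^2) / (2 * sigma_w^2))
    delta <- max(abs(W - W_old), abs(x - x_old))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("joint model did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  }
  # Posterior sds at the final constrained solution.
  xt <- x[targ]
  sxx <- rowsum(xt^2, gidx_t)[, 1L]
  prec_w <- sweep(matrix(sxx, length(genes), length(conds)), 2,
                  n_c / tau2, "*") + 1 / sigma_w^2
  W_sd <- 1 / sqrt(prec_w)
  dimnames(W_sd) <- dimnames(W)
  Wg <- W[gidx_t, , drop = FALSE]
  den <- rowSums(sweep(Wg^2, 2, n_c / tau2, "*")) + 1 / sigma_x^2
  x_sd <- stats::setNames(rep(NA_real_, length(x)), names(x))
  x_sd[targ] <- 1 / sqrt(den)
  structure(
    list(w = W, w_sd = W_sd, x = x, x_sd = x_sd, gene = gene,
         is_control = is_ctrl, tau2 = tau2, iterations = iter,
         converged = converged, objective = objective,
         hyper = list(tol = tol, sigma_x = sigma_x, sigma_w = sigma_w)),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("joint_fit: %d genes x %d condition(s), %d guides; %s in %d iteration(s)\n",
              nrow(x$w), ncol(x$w), sum(!x$is_control),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Rank genes by the late-minus-early effect contrast
#'
#' \code{d = w[, test] - w[, ref]}, and \code{z = d / w_sd[, test]} (the
#' contrast divided by the standard deviation of the late effect). Genes are
#' ranked by both statistics; ties break on gene id, and genes with zero late
#' sd get a masked z.
#'
#' @param fit a \code{joint_fit}.
#' @param test condition whose enrichment is of interest (default
#'   \code{"t19d"}).
#' @param ref reference condition (default \code{"t4h"}).
#' @return data.frame (class \code{gene_ranking}) with columns gene, w_ref,
#'   sd_ref, w_test, sd_test, d, z, rank_d, rank_z, sorted by rank_d.
#' @export
rank_genes <- function(fit, test = "t19d", ref = "t4h") {
  stopifnot(inherits(fit, "joint_fit"))
  missing <- setdiff(c(test, ref), colnames(fit$w))
  if (length(missing)) {
    stop("condition(s) absent from fit: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- fit$w[, test] - fit$w[, ref]
  sd_test <- fit$w_sd[, test]
  z <- ifelse(sd_test > 0, d / sd_test, NA_real_)
  out <- data.frame(
    gene = rownames(fit$w),
    w_ref = fit$w[, ref], sd_ref = fit$w_sd[, ref],
    w_test = fit$w[, test], sd_test = sd_test,
    d = d, z = z, stringsAsFactors = FALSE
  )
  ord_d <- order(-out$d, out$gene)
  out$rank_d <- NA_integer_
  out$rank_d[ord_d] <- seq_len(nrow(out))
  ord_z <- order(-out$z, out$gene, na.last = TRUE)
  out$rank_z <- NA_integer_
  out$rank_z[ord_z] <- seq_len(nrow(out))
  out <- out[order(out$rank_d), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}
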