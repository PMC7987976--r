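# Screen simulator: lentiviral transduction, control aliquots, per-mouse
# engraftment bottleneck, selective clonal outgrowth, and overdispersed
# sequencing. All operations are seed-deterministic.

#' Screen design parameters
#'
#' Describes the experimental layout of an in vivo screen. The defaults match
#' the wildtype two-timepoint design: 12e6 cells transduced at MOI 0.3,
#' expanded in culture, two pre-injection "cells_500x" aliquots of 5.5e6 cells
#' snap-frozen at 0 h, and 5.5e5 cells (50x library coverage) tail-vein dosed
#' into 35 mice per timepoint, collected at 4 h and at 19 days.
#'
#' For the multi-cohort end-stage design set \code{cohorts} to a named integer
#' vector (e.g. \code{c(A = 23, B = 23, C = 24)}): each cohort then receives
#' its own mice plus \code{controls_per_cohort} control aliquots, and all
#' lungs are collected at \code{growth_days}.
#'
#' @param n_mice_per_group mice per timepoint (wildtype design).
#' @param dose_cells cells injected per mouse.
#' @param control_replicates named vector of control-aliquot cell numbers.
#' @param timepoints timepoint labels, subset of \code{c("t4h","t19d")}.
#' @param cohorts optional named vector of per-cohort mouse counts.
#' @param controls_per_cohort control aliquots per cohort (cohort mode).
#' @param control_cells cells per control aliquot in cohort mode.
#' @param moi lentiviral multiplicity of infection.
#' @param growth_days days of outgrowth for the late timepoint.
#' @param read_depth sequencing reads per sample.
#' @param n_cells_transduced cells exposed to the library virus.
#' @param n_cells_expanded culture size after puromycin selection and
#'   expansion, from which aliquots and doses are drawn.
#' @return object of class \code{screen_design}.
#' @export
screen_design <- function(n_mice_per_group = 35,
                          dose_cells = 550000,
                          control_replicates = c(cells_500x_a = 5.5e6,
                                                 cells_500x_b = 5.5e6),
                          timepoints = c("t4h", "t19d"),
                          cohorts = NULL,
                          controls_per_cohort = 3,
                          control_cells = 5.5e6,
                          moi = 0.3,
                          growth_days = 19,
                          read_depth = 5e6,
                          n_cells_transduced = 12e6,
                          n_cells_expanded = 1e8) {
  stopifnot(n_mice_per_group > 0, dose_cells > 0, moi >= 0, growth_days >= 0,
            read_depth > 0, n_cells_transduced > 0, n_cells_expanded > 0)
  if (!length(timepoints)) stop("at least one timepoint is required", call. = FALSE)
  if (!all(timepoints %in% c("t4h", "t19d"))) {
    stop("timepoints must be among t4h, t19d", call. = FALSE)
  }
  if (!is.null(cohorts)) {
    if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
      stop("`cohorts` must be a named vector of mouse counts", call. = FALSE)
    }
    stopifnot(all(cohorts > 0), controls_per_cohort > 0, control_cells > 0)
  }
  # tolerate list input and lost names (e.g. a config round-tripped via JSON)
  control_replicates <- unlist(control_replicates)
  if (is.null(names(control_replicates)) || any(!nzchar(names(control_replicates)))) {
    names(control_replicates) <- paste0("cells_500x_",
                                        letters[seq_along(control_replicates)])
  }
  stopifnot(all(control_replicates > 0))
  structure(
    list(n_mice_per_group = as.integer(n_mice_per_group),
         dose_cells = dose_cells,
         control_replicates = control_replicates,
         timepoints = timepoints,
         cohorts = cohorts,
         controls_per_cohort = as.integer(controls_per_cohort),
         control_cells = control_cells,
         moi = moi,
         growth_days = growth_days,
         read_depth = read_depth,
         n_cells_transduced = n_cells_transduced,
         n_cells_expanded = n_cells_expanded),
    class = "screen_design"
  )
}

#' Selection profile: bottleneck, growth effects and noise
#'
#' Holds the biological parameters the simulator plants: per-gene log2 growth
#' advantages (doublings/day, 0 for neutral genes and for NTC), per-guide
#' efficacies in [0,1], the per-cell probability of surviving the lung
#' bottleneck, sequencing overdispersion, clonal growth noise, and the
#' baseline growth rate.
#'
#' The default survival probability \code{-log(0.8)/49} (~0.004553) is a
#' calibration: at a dose of 49 cells per guide it makes the expected fraction
#' of guides with at least one surviving founder equal 20 percent, the
#' reported per-mouse library representation.
#'
#' @param lib a \code{guide_library}.
#' @param hit_genes genes to plant as hits.
#' @param beta log2 growth advantage (doublings/day) for planted genes; scalar
#'   or named per-gene vector.
#' @param guide_efficacy per-guide efficacy in [0,1]; scalar or named vector
#'   over the library's guides. Defaults to 1.
#' @param survival_prob per-cell probability of surviving the bottleneck.
#' @param dispersion sequencing overdispersion (per-guide Dirichlet
#'   concentration is \code{1/dispersion} for a uniform pool; 0 = multinomial).
#' @param sigma_clone lognormal clone-size noise SD on the log2 scale.
#' @param b0 baseline growth rate (doublings/day); cosmetic for rankings since
#'   reads are compositional.
#' @return object of class \code{selection_profile}.
#' @export
selection_profile <- function(lib, hit_genes = character(), beta = 0.5,
                              guide_efficacy = 1,
                              survival_prob = -log(0.8) / 49,
                              dispersion = 0.05, sigma_clone = 1, b0 = 1) {
  stopifnot(inherits(lib, "guide_library"),
            survival_prob >= 0, survival_prob <= 1,
            dispersion >= 0, sigma_clone >= 0)
  g <- lib$guides
  genes <- unique(g$gene)
  gene_effect <- stats::setNames(rep(0, length(genes)), genes)
  if (length(hit_genes)) {
    unknown <- setdiff(hit_genes, genes)
    if (length(unknown)) {
      stop("hit gene(s) not in library: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if ("NTC" %in% hit_genes) stop("NTC cannot carry a growth effect", call. = FALSE)
    if (!is.null(names(beta))) {
      gene_effect[names(beta)] <- beta
    } else {
      gene_effect[hit_genes] <- beta
    }
  }
  gene_effect["NTC"] <- 0
  if (length(guide_efficacy) == 1 && is.null(names(guide_efficacy))) {
    guide_efficacy <- stats::setNames(rep(guide_efficacy, nrow(g)), g$guide_id)
  } else {
    unknown <- setdiff(names(guide_efficacy), g$guide_id)
    if (length(unknown)) {
      stop("efficacy given for unknown guide(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(rep(1, nrow(g)), g$guide_id)
    full[names(guide_efficacy)] <- guide_efficacy
    guide_efficacy <- full
  }
  if (any(guide_efficacy < 0 | guide_efficacy > 1)) {
    stop("guide efficacies must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(gene_effect = gene_effect,
         guide_efficacy = guide_efficacy,
         gene_of = stats::setNames(g$gene, g$guide_id),
         survival_prob = survival_prob,
         dispersion = dispersion,
         sigma_clone = sigma_clone,
         b0 = b0),
    class = "selection_profile"
  )
}

#' Assign guides to cells by Poisson transduction
#'
#' Each of \code{n_cells} cells receives \code{K ~ Poisson(moi)} lentiviral
#' integrations; cells with \code{K >= 1} survive puromycin selection and are
#' assigned one guide uniformly at random (multiple integrations are rare at
#' MOI 0.3 and collapsed to a single guide).
#'
#' @param n_cells number of cells exposed.
#' @param moi multiplicity of infection.
#' @param lib a \code{guide_library}.
#' @param seed RNG seed.
#' @return named integer vector of infected-cell counts per guide, summing to
#'   the number of infected cells.
#' @export
assign_guides_by_transduction <- function(n_cells, moi, lib, seed) {
  stopifnot(inherits(lib, "guide_library"), n_cells > 0, moi >= 0)
  n_guides <- nrow(lib$guides)
  if (n_guides == 0) stop("cannot transduce with an empty library", call. = FALSE)
  with_seed(seed, {
    n_infected <- stats::rbinom(1L, as.integer(n_cells), 1 - exp(-moi))
    counts <- stats::rmultinom(1L, n_infected, rep(1, n_guides))[, 1L]
    stats::setNames(as.integer(counts), lib$guides$guide_id)
  })
}

# Draw n cells without replacement from a per-guide pool. Uses the multinomial
# approximation when the draw is < 1% of the pool, exact multivariate
# hypergeometric otherwise (design decision d2).
draw_from_pool <- function(pool, n_cells) {
  total <- sum(pool)
  if (n_cells > total) {
    stop("cannot draw ", n_cells, " cells from a pool of ", total, call. = FALSE)
  }
  if (n_cells == 0) return(stats::setNames(integer(length(pool)), names(pool)))
  out <- if (n_cells < 0.01 * total) {
    stats::rmultinom(1L, n_cells, pool / total)[, 1L]
  } else {
    rmvhyper(n_cells, pool)
  }
  stats::setNames(as.integer(out), names(pool))
}

#' Sample a control aliquot from the cell pool
#'
#' Draws \code{n_cells} cells without replacement (exact multivariate
#' hypergeometric; a multinomial approximation is used when the aliquot is
#' under 1 percent of the pool).
#'
#' @param pool named per-guide cell counts.
#' @param n_cells aliquot size (\code{<= sum(pool)}).
#' @param seed RNG seed.
#' @return named integer vector of cells per guide, summing to \code{n_cells}.
#' @export
sample_control_aliquot <- function(pool, n_cells, seed) {
  with_seed(seed, draw_from_pool(pool, n_cells))
}

# Dirichlet-multinomial read draw over clone masses. Per-guide concentration
# alpha_g = (m_g / mean of present masses) / dispersion, so a uniform pool has
# per-guide concentration 1/dispersion and dispersion -> 0 is multinomial.
dirichlet_multinomial <- function(masses, depth, dispersion) {
  counts <- stats::setNames(integer(length(masses)), names(masses))
  present <- masses > 0
  if (!any(present) || depth <= 0) return(counts)
  w <- masses[present]
  if (dispersion > 0) {
    shape <- (w / mean(w)) / dispersion
    wt <- stats::rgamma(length(shape), shape = shape, rate = 1)
    if (sum(wt) > 0) w <- wt
  }
  counts[present] <- stats::rmultinom(1L, as.integer(depth), w)[, 1L]
  counts
}

#' Simulate one mouse: dose, bottleneck, outgrowth, sequencing
#'
#' (1) \code{dose_cells} cells are drawn from the pool; (2) each dosed cell
#' survives the lung bottleneck independently with probability
#' \code{sel$survival_prob}; survivors are the founders; (3) at \code{t19d}
#' each founder grows for \code{growth_days} days to expected clone size
#' \code{2^((b0 + x_g * beta_gene) * days)} with lognormal clone noise
#' (\code{sigma_clone} on the log2 scale); at \code{t4h} clone size is 1;
#' (4) reads are drawn by Dirichlet-multinomial over clone masses at
#' \code{read_depth}. A mouse with zero founders yields an all-zero column and
#' an empty founder set.
#'
#' @param pool named per-guide cell counts of the injected population.
#' @param design a \code{screen_design}.
#' @param sel a \code{selection_profile}.
#' @param timepoint \code{"t4h"} or \code{"t19d"}.
#' @param seed RNG seed.
#' @return list with \code{counts} (named integer vector summing to
#'   \code{read_depth}, or all zeros), \code{founders} (guide ids with >= 1
#'   surviving founder) and \code{n_founders} (per-guide founder counts).
#' @export
simulate_mouse <- function(pool, design, sel, timepoint = c("t19d", "t4h"), seed) {
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(design, "screen_design"), inherits(sel, "selection_profile"))
  ids <- names(pool)
  with_seed(seed, {
    dose <- draw_from_pool(pool, design$dose_cells)
    # Per-cell survival via shared uniforms: with a common seed, founder sets
    # are nested across survival probabilities (coupling property).
    n_dosed <- sum(dose)
    idx <- rep.int(seq_along(dose), dose)
    surv <- stats::runif(n_dosed) < sel$survival_prob
    n_founders <- tabulate(idx[surv], nbins = length(dose))
    names(n_founders) <- ids
    if (sum(n_founders) == 0) {
      list(counts = stats::setNames(integer(length(pool)), ids),
           founders = character(), n_founders = n_founders)
    } else {
      if (timepoint == "t4h") {
        masses <- as.numeric(n_founders)
      } else {
        fidx <- rep.int(seq_along(n_founders), n_founders)
        rate <- sel$b0 + sel$guide_efficacy[ids] * sel$gene_effect[sel$gene_of[ids]]
        log2size <- rate[fidx] * design$growth_days +
          stats::rnorm(length(fidx), 0, sel$sigma_clone)
        masses <- numeric(length(n_founders))
        agg <- rowsum(2^log2size, fidx)
        masses[as.integer(rownames(agg))] <- agg[, 1L]
      }
      names(masses) <- ids
      counts <- dirichlet_multinomial(masses, design$read_depth, sel$dispersion)
      list(counts = counts, founders = ids[n_founders > 0], n_founders = n_founders)
    }
  })
}

#' Simulate a full screen
#'
#' Transduces the library, expands the selected population proportionally to
#' \code{n_cells_expanded}, sequences the control aliquots, and simulates each
#' mouse at its timepoint (or cohort). Emits a raw \code{count_matrix}, a
#' sample sheet with unique random 8-mer barcodes, and a ground-truth record
#' (planted genes, guide efficacies, per-mouse founder sets). Fully
#' deterministic given (design, profile, library, seed).
#'
#' @param design a \code{screen_design}.
#' @param sel a \code{selection_profile}.
#' @param lib the \code{guide_library}.
#' @param seed RNG seed.
#' @return object of class \code{simulated_screen}: list with \code{counts}
#'   (raw \code{count_matrix}), \code{sample_sheet}, \code{truth},
#'   \code{design}, \code{profile}.
#' @export
simulate_screen <- function(design, sel, lib, seed) {
  stopifnot(inherits(design, "screen_design"), inherits(sel, "selection_profile"),
            inherits(lib, "guide_library"))
  pool_infected <- assign_guides_by_transduction(
    design$n_cells_transduced, design$moi, lib, derive_seed(seed, 1))
  if (sum(pool_infected) == 0) {
    stop("transduction produced no infected cells (moi too low?)", call. = FALSE)
  }
  # Deterministic proportional expansion to the day-9 culture size; culture
  # drift during expansion is not modelled.
  pool <- stats::setNames(
    as.integer(round(pool_infected / sum(pool_infected) * design$n_cells_expanded)),
    names(pool_infected))

  columns <- list()
  sheet <- list()
  founders <- list()
  step <- 1L
  add_control <- function(sid, n_cells, group) {
    cells <- sample_control_aliquot(pool, n_cells, derive_seed(seed, 100 + step))
    reads <- with_seed(derive_seed(seed, 200 + step),
                       dirichlet_multinomial(as.numeric(cells), design$read_depth,
                                             sel$dispersion))
    columns[[sid]] <<- stats::setNames(reads, names(pool))
    sheet[[sid]] <<- data.frame(sample_id = sid, group = group,
                                mouse_id = NA_character_, stringsAsFactors = FALSE)
    step <<- step + 1L
  }
  add_mouse <- function(sid, group, timepoint) {
    res <- simulate_mouse(pool, design, sel, timepoint, derive_seed(seed, 300 + step))
    columns[[sid]] <<- res$counts
    founders[[sid]] <<- res$founders
    sheet[[sid]] <<- data.frame(sample_id = sid, group = group, mouse_id = sid,
                                stringsAsFactors = FALSE)
    step <<- step + 1L
  }

  if (is.null(design$cohorts)) {
    for (i in seq_along(design$control_replicates)) {
      add_control(names(design$control_replicates)[i],
                  design$control_replicates[[i]], "cells_500x")
    }
    for (tp in design$timepoints) {
      grp <- if (tp == "t4h") "lung_4h" else "lung_19d"
      for (m in seq_len(design$n_mice_per_group)) {
        add_mouse(sprintf("%s_%02d", grp, m), grp, tp)
      }
    }
  } else {
    for (co in names(design$cohorts)) {
      for (r in seq_len(design$controls_per_cohort)) {
        add_control(sprintf("cells_%s_%d", co, r), design$control_cells, "cells_500x")
      }
      for (m in seq_len(design$cohorts[[co]])) {
        add_mouse(sprintf("lung_%s_%02d", co, m), co, "t19d")
      }
    }
  }

  counts <- do.call(cbind, columns)
  rownames(counts) <- names(pool)
  sheet <- do.call(rbind, sheet)
  sheet$barcode <- with_seed(derive_seed(seed, 7), random_dna(nrow(sheet), 8))
  sheet$run <- "run1"
  rownames(sheet) <- NULL
  sheet <- sheet[c("sample_id", "barcode", "group", "mouse_id", "run")]

  cm <- count_matrix(counts, stats::setNames(lib$guides$gene, lib$guides$guide_id),
                     samples = sheet, normalized = FALSE)
  truth <- list(
    hit_genes = sel$gene_effect[sel$gene_effect != 0],
    guide_efficacy = sel$guide_efficacy,
    founders = founders,
    survival_prob = sel$survival_prob
  )
  structure(list(counts = cm, sample_sheet = sheet, truth = truth,
                 design = design, profile = sel),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("simulated_screen: %d guides x %d samples; %d planted hit gene(s)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(x$truth$hit_genes)))
  invisible(x)
}

#' Per-mouse library representation under the engraftment bottleneck
#'
#' Fast calibration check for the bottleneck model: for each simulated mouse,
#' per-guide dosed cells are multinomial over a uniform library (marginally
#' Binomial(dose, 1/n_guides)), each dosed cell survives with probability
#' \code{sel$survival_prob}, and the mouse's representation is the fraction of
#' guides with at least one surviving founder. The mean fraction has the
#' closed form \code{1 - exp(-lambda * p)} with \code{lambda = dose/n_guides}.
#'
#' @param n_mice number of mice to simulate.
#' @param lib a \code{guide_library}.
#' @param design a \code{screen_design} (uses \code{dose_cells}).
#' @param sel a \code{selection_profile} (uses \code{survival_prob}).
#' @param seed RNG seed.
#' @return numeric vector of per-mouse represented fractions, length
#'   \code{n_mice}.
#' @export
simulate_representation <- function(n_mice, lib, design = screen_design(),
                                    sel = selection_profile(lib), seed = 1) {
  stopifnot(inherits(lib, "guide_library"), n_mice > 0)
  n_guides <- nrow(lib$guides)
  if (n_guides == 0) stop("empty library", call. = FALSE)
  with_seed(seed, {
    prob <- rep(1 / n_guides, n_guides)
    vapply(seq_len(n_mice), function(i) {
      dose <- stats::rmultinom(1L, as.integer(design$dose_cells), prob)[, 1L]
      founders <- stats::rbinom(n_guides, dose, sel$survival_prob)
      mean(founders > 0)
    }, numeric(1))
  })
}
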