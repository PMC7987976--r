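# Shared fixtures, built in code at test time.

tiny_library <- function(n_genes = 4, guides_per_gene = 2, n_controls = 2,
                         L = 12, seed = 11) {
  build_synthetic_library(n_genes, guides_per_gene, n_controls, L, seed)
}

# A small but structurally complete screen: weak bottleneck (high survival) so
# planted recovery is not founder-luck limited at this scale.
small_screen <- function(hit_genes = c("gene0003", "gene0007"), seed = 42,
                         n_mice = 6, beta = 0.5, survival_prob = 0.05,
                         n_genes = 20) {
  lib <- build_synthetic_library(n_genes, 5, 10, 20, seed = 3)
  design <- screen_design(
    n_mice_per_group = n_mice, dose_cells = 5000,
    control_replicates = c(cells_500x_a = 50000, cells_500x_b = 50000),
    read_depth = 1e5, n_cells_transduced = 5e5, n_cells_expanded = 1e6
  )
  sel <- selection_profile(lib, hit_genes = hit_genes, beta = beta,
                           survival_prob = survival_prob)
  sim <- simulate_screen(design, sel, lib, seed = seed)
  list(lib = lib, design = design, sel = sel, sim = sim)
}

# Random raw count matrix with a control group and two lung groups.
random_count_matrix <- function(n_guides = 50, n_ctrl = 2, n_4h = 3, n_19d = 3,
                                seed = 1, lambda = 80, normalized = FALSE) {
  set.seed(seed)
  n_s <- n_ctrl + n_4h + n_19d
  m <- matrix(rpois(n_guides * n_s, lambda), n_guides, n_s)
  # sprinkle zeros so group counts vary
  m[sample(length(m), floor(length(m) * 0.2))] <- 0
  gids <- sprintf("g%03d", seq_len(n_guides))
  sids <- c(sprintf("ctrl_%d", seq_len(n_ctrl)),
            sprintf("l4_%d", seq_len(n_4h)),
            sprintf("l19_%d", seq_len(n_19d)))
  dimnames(m) <- list(gids, sids)
  samples <- data.frame(
    sample_id = sids,
    group = c(rep("cells_500x", n_ctrl), rep("lung_4h", n_4h),
              rep("lung_19d", n_19d)),
    stringsAsFactors = FALSE
  )
  gene <- stats::setNames(paste0("gene", rep(seq_len(ceiling(n_guides / 5)),
                                             each = 5)[seq_len(n_guides)]), gids)
  count_matrix(m, gene, samples, normalized = normalized)
}
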