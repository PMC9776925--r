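# Fixtures built in code; no binary files.

# small random cell_matrix with labelled types
random_cell_matrix <- function(n_genes = 30, types = c("T1", "T2", "T3"),
                               cells_per_type = 45, species = "spX",
                               lambda = 2, seed = 42) {
  set.seed(seed)
  n_cells <- length(types) * cells_per_type
  counts <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- sprintf("c%04d", seq_len(n_cells))
  cell_types <- setNames(rep(types, each = cells_per_type), colnames(counts))
  cell_matrix(counts, species, cell_types)
}

# two-species simulation used by several planted-signal tests:
# 5 types per species, T1 and T2 planted homologous, 100 single-copy orthologs
planted_two_species_spec <- function(seed, n_cells_per_type = 200,
                                     marker_fc = 4) {
  types <- paste0("T", 1:5)
  simulation_spec(
    n_species = 2,
    cell_types = setNames(rep(list(types), 2), c("spA", "spB")),
    homology_map = data.frame(species_a = "spA", type_a = c("T1", "T2"),
                              species_b = "spB", type_b = c("T1", "T2"),
                              stringsAsFactors = FALSE),
    n_orthologs_111 = 100, n_orthogroups_other = 0,
    n_specific_per_species = 150, n_cells_per_type = n_cells_per_type,
    marker_fc = marker_fc, stage_order = types, seed = seed
  )
}

# hand-built celltype_profiles over 1-1 pairs (for marker / KLD unit tests)
profiles_fixture <- function(values, species, side, pairs) {
  structure(
    list(values = values, species = species,
         n_cells = setNames(rep(10L, ncol(values)), colnames(values)),
         pairs = pairs, side = side),
    class = "celltype_profiles"
  )
}

# brute-force AUROC: count concordant (positive, negative) pairs, ties = 1/2
auroc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# brute-force two-sided signed-rank p by literal enumeration of sign patterns
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in seq_len(2^n)) {
    signs <- as.logical(bitwAnd(m - 1, 2^(seq_len(n) - 1)))
    ws[m] <- sum(r[signs])
  }
  p_le <- mean(ws <= w_obs + 1e-12)
  p_ge <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
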