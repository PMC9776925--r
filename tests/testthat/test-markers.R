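test_that("exact signed-rank p agrees with literal sign-pattern enumeration", {
  # n = 6, all differences positive: W = 21, p = 2/64
  res <- paired_wilcoxon(11:16, 1:6)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 0.03125)
  expect_equal(signed_rank_enum_p(11:16 - 1:6), 0.03125)

  set.seed(51)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    d <- sample(c(-3:-1, 1:4), n, replace = TRUE)  # ties and both signs
    res <- paired_wilcoxon(d, rep(0, n), method = "exact")
    expect_equal(res$p_value, signed_rank_enum_p(d))
  }
})

test_that("identical paired vectors give p = 1 with a warning", {
  expect_warning(res <- paired_wilcoxon(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
})

test_that("exact p matches the reference implementation when no ties or zeros", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- paired_wilcoxon(x, y, method = "exact")
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # all-positive two-sided p is 2 / 2^n at every small n
  for (n in 5:10)
    expect_equal(paired_wilcoxon(seq_len(n) + 10, seq_len(n))$p_value, 2 / 2^n)
})

test_that("the normal approximation tracks the exact p at n = 12", {
  set.seed(53)
  for (i in 1:100) {
    x <- rnorm(12); y <- rnorm(12)
    pe <- paired_wilcoxon(x, y, method = "exact")$p_value
    pa <- paired_wilcoxon(x, y, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

toy_marker_profiles <- function() {
  pairs <- data.frame(orthogroup = sprintf("OG%d", 1:6),
                      gene_a = sprintf("a%d", 1:6),
                      gene_b = sprintf("b%d", 1:6), stringsAsFactors = FALSE)
  #          in   out1 out2 out3        per-species FC vs mean(out)
  va <- rbind(c(4,   1,   1,   1),    # OG1: 4       -> retained
              c(1.3, 1,   1,   1),    # OG2: exactly 1.3 -> excluded (strict >)
              c(2,   1,   1,   1),    # OG3: 2 in A but 1.1 in B -> excluded
              c(0,   1,   1,   1),    # OG4: zero in-group -> excluded
              c(1.4, 1,   1,   1),    # OG5: 1.4     -> retained
              c(0.5, 1,   1,   1))    # OG6: 0.5     -> excluded
  vb <- rbind(c(4,   1,   1,   1),
              c(4,   1,   1,   1),
              c(1.1, 1,   1,   1),
              c(4,   1,   1,   1),
              c(1.4, 1,   1,   1),
              c(0.5, 1,   1,   1))
  colnames(va) <- paste0("A", 1:4); colnames(vb) <- paste0("B", 1:4)
  list(pa = profiles_fixture(va, "spA", "a", pairs),
       pb = profiles_fixture(vb, "spB", "b", pairs))
}

test_that("shared markers require FC strictly above threshold in both species", {
  p <- toy_marker_profiles()
  tab <- shared_markers(p$pa, p$pb, group_a = "A1", group_b = "B1")
  expect_setequal(tab$orthogroup, c("OG1", "OG5"))  # hand enumeration
  expect_true(all(tab$fc_a > 1.3 & tab$fc_b > 1.3))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$p_adj, p.adjust(tab$p_value, "BH"))
  # in-group means exceed every out-group type, so signed-rank W is maximal
  expect_equal(tab$statistic, rep(6 * 7 / 2, 2))
})

test_that("a group covering every type of one species is rejected", {
  p <- toy_marker_profiles()
  expect_error(shared_markers(p$pa, p$pb, group_a = paste0("A", 1:4),
                              group_b = "B1"),
               "out-group is empty")
  expect_error(shared_markers(p$pa, p$pb, group_a = "A9", group_b = "B1"),
               "A9")
})

test_that("marker tables are invariant to cell-type column order", {
  p <- toy_marker_profiles()
  tab <- shared_markers(p$pa, p$pb, group_a = "A1", group_b = "B1")
  pa2 <- p$pa; pa2$values <- pa2$values[, c(3, 1, 4, 2)]
  pb2 <- p$pb; pb2$values <- pb2$values[, c(2, 4, 1, 3)]
  tab2 <- shared_markers(pa2, pb2, group_a = "A1", group_b = "B1")
  expect_equal(tab2$orthogroup, tab$orthogroup)
  expect_equal(tab2$fc_a, tab$fc_a)
  expect_equal(tab2$p_value, tab$p_value)
})

# three species sharing 100 single-copy orthologs; 30 planted with a 5-fold
# boost in species A only
triad_fixture <- function(seed, n_genes = 100, n_planted = 30, fc = 5) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(2), 0.8)
  types <- c("T1", "T2", "T3"); cells_per_type <- 60
  species <- c("spA", "spB", "spC")
  pseudos <- list()
  for (s in species) {
    mult <- rep(1, n_genes)
    if (s == "spA") mult[seq_len(n_planted)] <- fc
    n_cells <- length(types) * cells_per_type
    counts <- matrix(rnbinom(n_genes * n_cells, size = 2.5,
                             mu = rep(base * mult, n_cells)),
                     n_genes, n_cells,
                     dimnames = list(sprintf("%s_g%03d", s, seq_len(n_genes)),
                                     sprintf("%s_c%03d", s, seq_len(n_cells))))
    cm <- cell_matrix(counts, s,
                      setNames(rep(types, each = cells_per_type), colnames(counts)))
    # linear-scale values: fold-change gates are not meaningful on log1p
    pseudos[[s]] <- build_pseudocells(normalize_cells(cm, "cp10k"), k = 10, seed = seed)
  }
  singlecopy <- data.frame(orthogroup = sprintf("OG%03d", seq_len(n_genes)),
                           spA = sprintf("spA_g%03d", seq_len(n_genes)),
                           spB = sprintf("spB_g%03d", seq_len(n_genes)),
                           spC = sprintf("spC_g%03d", seq_len(n_genes)),
                           stringsAsFactors = FALSE)
  list(pseudos = pseudos, singlecopy = singlecopy,
       planted = sprintf("OG%03d", seq_len(n_planted)))
}

test_that("species-differential orthologs recover planted species-A programs", {
  for (seed in 61:65) {
    fx <- triad_fixture(seed)
    res <- species_differential_orthologs(fx$pseudos, fx$singlecopy)
    expect_gte(length(intersect(res$flagged$spA, fx$planted)), 27)
    false_flags <- length(setdiff(res$flagged$spA, fx$planted)) +
      length(res$flagged$spB) + length(res$flagged$spC)
    expect_lte(false_flags, 2)
  }
})

test_that("identically expressed orthologs are never flagged and fc -> Inf empties the set", {
  fx <- triad_fixture(66, n_planted = 0)
  res <- species_differential_orthologs(fx$pseudos, fx$singlecopy)
  expect_lte(sum(lengths(res$flagged)), 2)
  fx2 <- triad_fixture(67)
  res2 <- species_differential_orthologs(fx2$pseudos, fx2$singlecopy,
                                         fc_threshold = 1e9)
  expect_equal(sum(lengths(res2$flagged)), 0)
})
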