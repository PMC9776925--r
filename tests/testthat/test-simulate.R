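test_that("identical spec and seed give bit-identical output", {
  spec <- planted_two_species_spec(seed = 5, n_cells_per_type = 40)
  s1 <- simulate_counts(spec)
  s2 <- simulate_counts(spec)
  expect_identical(s1$matrices$spA$counts, s2$matrices$spA$counts)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in c("spA/matrix.mtx", "spB/matrix.mtx", "orthogroups.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 3e6),
                     readBin(file.path(d2, f), "raw", 3e6))
  # and a written simulation reads back into the same counts
  back <- read_cell_matrix(file.path(d1, "spA"))
  expect_equal(as.matrix(back$counts), as.matrix(s1$matrices$spA$counts))
})

test_that("emitted gene-class counts equal the spec counts exactly", {
  spec <- simulation_spec(n_species = 3, n_cells_per_type = 10,
                          n_orthologs_111 = 40, n_orthogroups_other = 15,
                          n_specific_per_species = 30, seed = 9)
  sim <- simulate_counts(spec)
  expect_equal(nrow(sim$truth$ortholog_table), 55)
  for (s in spec$species) {
    cls <- sim$truth$gene_class_of[sim$truth$gene_class_of$species == s, ]
    expect_equal(sum(cls$class == "ortholog_111"), 40)
    expect_equal(sum(cls$class == "species_specific"), 30)
    # every simulated gene is classified exactly once
    expect_setequal(cls$gene, rownames(sim$matrices[[s]]$counts))
    expect_false(anyDuplicated(cls$gene) > 0)
  }
})

test_that("truth classes agree with classify_orthologs on the emitted table", {
  spec <- simulation_spec(n_species = 3, n_cells_per_type = 5,
                          n_orthologs_111 = 25, n_orthogroups_other = 10,
                          n_specific_per_species = 20, seed = 13)
  sim <- simulate_counts(spec)
  universes <- lapply(sim$matrices, function(m) rownames(m$counts))
  cls <- classify_orthologs(sim$truth$ortholog_table, universes)
  key <- function(d) d[order(d$species, d$gene), c("species", "gene", "class")]
  expect_equal(key(cls$classes), key(sim$truth$gene_class_of),
               ignore_attr = TRUE)
  expect_equal(nrow(cls$singlecopy_all), 25)
})

test_that("an inconsistent or malformed homology map is rejected", {
  types <- setNames(rep(list(c("X", "Y")), 2), c("spA", "spB"))
  expect_error(simulation_spec(
    n_species = 2, cell_types = types,
    homology_map = data.frame(species_a = "spA", type_a = c("X", "X"),
                              species_b = "spB", type_b = c("X", "Y"))),
    "inconsistent")
  expect_error(simulation_spec(
    n_species = 2, cell_types = types,
    homology_map = data.frame(species_a = "spA", type_a = "Z",
                              species_b = "spB", type_b = "X")),
    "unknown type")
  expect_error(simulation_spec(
    n_species = 2, cell_types = types,
    homology_map = data.frame(species_a = "spA", type_a = "X",
                              species_b = "spA", type_b = "Y")),
    "itself")
})

test_that("marker_fc = 1 plants no between-type signal", {
  spec <- planted_two_species_spec(seed = 21, n_cells_per_type = 150,
                                   marker_fc = 1)
  spec$specific_stage_decay <- 1
  spec$library_size_cv <- 0  # isolate type exchangeability from library noise
  sim <- simulate_counts(spec)
  counts <- as.matrix(sim$matrices$spA$counts)
  tm <- vapply(paste0("T", 1:5),
               function(t) rowMeans(counts[, sim$matrices$spA$cell_type_of == t]),
               numeric(nrow(counts)))
  grand <- mean(tm)
  for (j in 2:5)
    expect_lt(abs(mean(tm[, j] - tm[, 1])) / grand, 0.05)
})

test_that("the zero-dispersion branch is Poisson (variance tracks the mean)", {
  spec <- simulation_spec(
    n_species = 2, n_cells_per_type = 400,
    cell_types = setNames(rep(list("T1"), 2), c("spA", "spB")),
    n_orthologs_111 = 150, n_orthogroups_other = 0,
    n_specific_per_species = 0, nb_dispersion = 0, library_size_cv = 0,
    base_mean_log_mu = log(1), seed = 31
  )
  sim <- simulate_counts(spec)
  counts <- as.matrix(sim$matrices$spA$counts)
  m <- rowMeans(counts)
  v <- apply(counts, 1, var)
  keep <- m > 0.5
  expect_gt(sum(keep), 50)
  expect_lt(abs(median(v[keep] / m[keep]) - 1), 0.15)
})

test_that("planted markers reach their nominal fold change in their home type", {
  spec <- planted_two_species_spec(seed = 1)
  spec$n_specific_per_species <- 0   # ortholog programs only
  sim <- simulate_counts(spec)
  counts <- as.matrix(sim$matrices$spA$counts)
  type_of <- unname(sim$matrices$spA$cell_type_of)
  fcs <- c()
  for (t in paste0("T", 1:5)) {
    for (g in sim$truth$marker_genes_of$spA[[t]]) {
      home <- mean(counts[g, type_of == t])
      away <- mean(counts[g, type_of != t])
      fcs <- c(fcs, home / away)
    }
  }
  expect_gt(mean(fcs), 3.2)
  expect_lt(mean(fcs), 4.8)
})

test_that("planted homologous pairs have smaller KLD than every non-homologous pair", {
  for (seed in 81:85) {
    sim <- simulate_counts(planted_two_species_spec(seed, n_cells_per_type = 100))
    pairs <- expand_ortholog_pairs(sim$truth$ortholog_table, "spA", "spB")
    pa <- build_profiles(normalize_cells(sim$matrices$spA), pairs, "a")
    pb <- build_profiles(normalize_cells(sim$matrices$spB), pairs, "b")
    kld <- kld_similarity(pa, pb)$kld
    planted <- kld[cbind(c("T1", "T2"), c("T1", "T2"))]
    others <- kld[!(row(kld) == col(kld) & rownames(kld)[row(kld)] %in% c("T1", "T2"))]
    expect_lt(max(planted), min(others))
  }
})
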