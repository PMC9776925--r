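#' Specification for the multi-species single-cell count simulator
#'
#' Bundles and validates every parameter of [simulate_counts()]. The
#' defaults emulate a comparative study of chordate spermatogenesis: three
#' species, six germ-cell stages shared by name (undifferentiated /
#' differentiating / differentiated spermatogonia, early and late primary
#' spermatocytes, sperm) forming the developmental order, a few hundred
#' single-copy orthologs plus 1-many / many-many orthogroups and
#' species-specific genes, negative-binomial UMI noise, and marker programs
#' (fold change 4 on ~10% of genes) that planted homologous types share
#' across species.
#'
#' @param n_species number of species (>= 2).
#' @param species species labels.
#' @param cell_types named list (per species) of cell-type names; default:
#'   the six stage names for every species.
#' @param homology_map data.frame (species_a, type_a, species_b, type_b) of
#'   cell-type pairs declared homologous across species; default: types
#'   with equal names are homologous in every species pair. At most one
#'   partner per (type, species pair).
#' @param n_cells_per_type cells simulated per (species, cell type).
#' @param n_orthologs_111 number of orthogroups with exactly one gene per
#'   species (single-copy orthologs).
#' @param n_orthogroups_other number of 1-many / many-many orthogroups;
#'   per-species copy numbers are drawn in `0..other_copy_max` with at
#'   least two species present and at least one copy number > 1.
#' @param other_copy_max maximum copies per species in "other" orthogroups.
#' @param n_specific_per_species genes with no ortholog annotation.
#' @param marker_fraction fraction of the gene pool up-regulated per
#'   cell-type program (0 < f < 1).
#' @param marker_fc fold-change multiplier of marker programs (>= 1; 1
#'   means no planted signal).
#' @param base_mean_log_mu,base_mean_log_sigma log-normal parameters of
#'   baseline per-gene mean counts; orthogroup members share one baseline
#'   across species.
#' @param nb_dispersion negative-binomial dispersion alpha with variance
#'   `mu + alpha * mu^2`; 0 selects the Poisson limit.
#' @param library_size_cv coefficient of variation of the log-normal
#'   per-cell library-size factor (mean 1).
#' @param specific_stage_decay multiplicative decay of species-specific
#'   genes' baseline per step along `stage_order` (in (0, 1]; 1 = no
#'   decay). Models the declining contribution of species-specific genes
#'   as differentiation progresses.
#' @param stage_order ordered cell-type names forming the developmental
#'   trajectory; defaults to the first species' cell types.
#' @param seed integer RNG seed; identical spec + seed give bit-identical
#'   output.
#' @return validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_species = 3,
                            species = paste0("sp", LETTERS[seq_len(n_species)]),
                            cell_types = NULL,
                            homology_map = NULL,
                            n_cells_per_type = 200,
                            n_orthologs_111 = 300,
                            n_orthogroups_other = 60,
                            other_copy_max = 3,
                            n_specific_per_species = 150,
                            marker_fraction = 0.1,
                            marker_fc = 4,
                            base_mean_log_mu = log(0.3),
                            base_mean_log_sigma = 1,
                            nb_dispersion = 0.4,
                            library_size_cv = 0.3,
                            specific_stage_decay = 0.5,
                            stage_order = NULL,
                            seed = 1L) {
  default_stages <- c("UndiffSPG", "DiffingSPG", "DiffedSPG",
                      "EarlySPC", "LateSPC", "Sperm")
  stopifnot(n_species >= 2, length(species) == n_species,
            !anyDuplicated(species))
  if (is.null(cell_types))
    cell_types <- setNames(rep(list(default_stages), n_species), species)
  if (is.null(names(cell_types)) || !setequal(names(cell_types), species))
    stop("cell_types must be a list named by species")
  cell_types <- cell_types[species]
  for (s in species)
    if (!length(cell_types[[s]]) || anyDuplicated(cell_types[[s]]))
      stop("cell_types for ", s, " must be a non-empty set of unique names")
  if (is.null(stage_order)) stage_order <- cell_types[[1]]
  if (is.null(homology_map)) {
    homology_map <- NULL
    cmb <- utils::combn(species, 2)
    for (j in seq_len(ncol(cmb))) {
      shared <- intersect(cell_types[[cmb[1, j]]], cell_types[[cmb[2, j]]])
      if (length(shared))
        homology_map <- rbind(homology_map, data.frame(
          species_a = cmb[1, j], type_a = shared,
          species_b = cmb[2, j], type_b = shared,
          stringsAsFactors = FALSE))
    }
    homology_map <- homology_map %||% data.frame(
      species_a = character(), type_a = character(),
      species_b = character(), type_b = character(), stringsAsFactors = FALSE)
  }
  need <- c("species_a", "type_a", "species_b", "type_b")
  if (!all(need %in% names(homology_map)))
    stop("homology_map needs columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(homology_map))) {
    sa <- homology_map$species_a[i]; sb <- homology_map$species_b[i]
    if (sa == sb) stop("homology_map row ", i, " pairs a species with itself")
    if (!sa %in% species || !sb %in% species)
      stop("homology_map row ", i, " names unknown species")
    if (!homology_map$type_a[i] %in% cell_types[[sa]])
      stop("homology_map row ", i, ": unknown type ", homology_map$type_a[i],
           " for species ", sa)
    if (!homology_map$type_b[i] %in% cell_types[[sb]])
      stop("homology_map row ", i, ": unknown type ", homology_map$type_b[i],
           " for species ", sb)
  }
  ends <- rbind(
    data.frame(sp = homology_map$species_a, ty = homology_map$type_a,
               pair = paste(pmin(homology_map$species_a, homology_map$species_b),
                            pmax(homology_map$species_a, homology_map$species_b))),
    data.frame(sp = homology_map$species_b, ty = homology_map$type_b,
               pair = paste(pmin(homology_map$species_a, homology_map$species_b),
                            pmax(homology_map$species_a, homology_map$species_b)))
  )
  dup <- duplicated(ends)
  if (any(dup))
    stop("inconsistent homology_map: type named twice for one species pair: ",
         abbrev_ids(paste(ends$sp[dup], ends$ty[dup], sep = ":")))

  stopifnot(n_cells_per_type >= 1, n_orthologs_111 >= 1,
            n_orthogroups_other >= 0, other_copy_max >= 1,
            n_specific_per_species >= 0,
            marker_fraction > 0, marker_fraction < 1,
            marker_fc >= 1, base_mean_log_sigma >= 0,
            nb_dispersion >= 0, library_size_cv >= 0,
            specific_stage_decay > 0, specific_stage_decay <= 1)
  seed <- as.integer(seed)
  if (is.na(seed) || seed + n_species >= 2^31 - 1)
    stop("seed must be an integer with seed + n_species below 2^31")
  structure(
    list(n_species = n_species, species = species, cell_types = cell_types,
         homology_map = homology_map, n_cells_per_type = n_cells_per_type,
         n_orthologs_111 = n_orthologs_111,
         n_orthogroups_other = n_orthogroups_other,
         other_copy_max = other_copy_max,
         n_specific_per_species = n_specific_per_species,
         marker_fraction = marker_fraction, marker_fc = marker_fc,
         base_mean_log_mu = base_mean_log_mu,
         base_mean_log_sigma = base_mean_log_sigma,
         nb_dispersion = nb_dispersion, library_size_cv = library_size_cv,
         specific_stage_decay = specific_stage_decay,
         stage_order = stage_order, seed = seed),
    class = "simulation_spec"
  )
}

# union-find over "species|type" nodes for homology components
homology_components <- function(spec) {
  nodes <- unlist(lapply(spec$species, function(s)
    paste(s, spec$cell_types[[s]], sep = "|")))
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  hm <- spec$homology_map
  for (i in seq_len(nrow(hm))) {
    a <- find(paste(hm$species_a[i], hm$type_a[i], sep = "|"))
    b <- find(paste(hm$species_b[i], hm$type_b[i], sep = "|"))
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  roots <- vapply(nodes, find, character(1))
  comps <- split(nodes, roots)
  comps[order(names(comps))]
}

#' Simulate multi-species single-cell UMI counts with planted homologies
#'
#' Counts for every cell are drawn as
#' `NB(mean = baseline x marker multiplier x stage decay x library factor,
#' dispersion = nb_dispersion)`. Baseline means are log-normal and shared by
#' all members of an orthogroup across species. Every cell type carries a
#' marker program (`marker_fc` on a `marker_fraction`-sized set of
#' orthogroups): cell types planted as homologous share the SAME orthogroups
#' across species, non-homologous types draw disjoint species-private sets,
#' and each type additionally up-regulates a private set of its species'
#' specific genes. Species-specific genes' baselines decay along
#' `stage_order` (factor `specific_stage_decay` per stage), so their share
#' of the expressed transcriptome shrinks as differentiation progresses.
#' Library-size factors are log-normal with mean 1 and CV
#' `library_size_cv`. RNG: one stream (seeded `seed`) lays out the global
#' gene/orthogroup structure; one derived stream per species (`seed` +
#' species index) draws its counts in (cell type, cell, gene) order, so
#' adding a species never perturbs earlier species' draws.
#'
#' @param spec a [simulation_spec()].
#' @return Object of class `ortho_sim`: list with `matrices` (named list of
#'   [cell_matrix()] per species), `truth` (class `synthetic_truth`: the
#'   orthogroup table as written, `gene_class_of`, `marker_genes_of`,
#'   `programs`, the echoed `homology_map` and `stage_order`), and `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  sp <- spec$species
  n_og <- spec$n_orthologs_111 + spec$n_orthogroups_other
  og_ids <- sprintf("OG%05d", seq_len(n_og))
  is_111 <- seq_len(n_og) <= spec$n_orthologs_111

  # --- phase 1: global structure (one stream) -------------------------------
  members <- og_base <- spec_genes <- spec_base <- programs <- priv_programs <- NULL
  with_seed(spec$seed, {
    # orthogroup membership
    members <- setNames(vector("list", length(sp)), sp)   # per species: list per og
    for (s in sp) members[[s]] <- vector("list", n_og)
    for (i in seq_len(spec$n_orthologs_111))
      for (s in sp) members[[s]][[i]] <- sprintf("%s_og%05d", s, i)
    if (spec$n_orthogroups_other > 0) {
      for (j in seq_len(spec$n_orthogroups_other)) {
        i <- spec$n_orthologs_111 + j
        repeat {
          cp <- sample(0:spec$other_copy_max, length(sp), replace = TRUE)
          if (sum(cp > 0) >= 2 && any(cp > 1)) break
        }
        for (k in seq_along(sp))
          if (cp[k] > 0)
            members[[sp[k]]][[i]] <- sprintf("%s_ogo%05d_c%d", sp[k], j, seq_len(cp[k]))
      }
    }
    # baselines: one per orthogroup (shared across members and species),
    # one per species-specific gene
    og_base <- rlnorm(n_og, spec$base_mean_log_mu, spec$base_mean_log_sigma)
    spec_genes <- spec_base <- setNames(vector("list", length(sp)), sp)
    for (s in sp) {
      if (spec$n_specific_per_species > 0) {
        spec_genes[[s]] <- sprintf("%s_sp%05d", s, seq_len(spec$n_specific_per_species))
        spec_base[[s]] <- rlnorm(spec$n_specific_per_species,
                                 spec$base_mean_log_mu, spec$base_mean_log_sigma)
      } else {
        spec_genes[[s]] <- character()
        spec_base[[s]] <- numeric()
      }
    }
    # marker programs over orthogroups: one distinct chunk per homology
    # component (shared by all its member types across species)
    comps <- homology_components(spec)
    m_shared <- max(1L, round(spec$marker_fraction * n_og))
    if (length(comps) * m_shared > n_og)
      stop(sprintf(paste("marker programs need %d x %d orthogroups but only %d exist;",
                         "increase the ortholog counts or lower marker_fraction"),
                   length(comps), m_shared, n_og))
    pool <- sample(og_ids)
    programs <- setNames(vector("list", length(comps)), names(comps))
    for (ci in seq_along(comps)) {
      programs[[ci]] <- sort(pool[seq_len(m_shared)])
      pool <- pool[-seq_len(m_shared)]
    }
    # private programs on species-specific genes, one chunk per type
    priv_programs <- setNames(vector("list", length(sp)), sp)
    for (s in sp) {
      priv_programs[[s]] <- setNames(
        rep(list(character()), length(spec$cell_types[[s]])), spec$cell_types[[s]])
      if (spec$n_specific_per_species > 0) {
        m_priv <- max(1L, round(spec$marker_fraction * spec$n_specific_per_species))
        if (length(spec$cell_types[[s]]) * m_priv > spec$n_specific_per_species)
          stop("not enough species-specific genes for one private program per type")
        perm <- sample(spec_genes[[s]])
        for (ti in seq_along(spec$cell_types[[s]])) {
          t <- spec$cell_types[[s]][ti]
          priv_programs[[s]][[t]] <- sort(perm[seq_len(m_priv)])
          perm <- perm[-seq_len(m_priv)]
        }
      }
    }
  })
  comps <- homology_components(spec)
  comp_of <- setNames(rep(names(comps), lengths(comps)), unlist(comps))

  # --- phase 2: per-species counts (one derived stream each) ----------------
  sln2 <- log(1 + spec$library_size_cv^2)
  matrices <- setNames(vector("list", length(sp)), sp)
  marker_genes_of <- setNames(vector("list", length(sp)), sp)
  for (si in seq_along(sp)) {
    s <- sp[si]
    og_gene <- unlist(members[[s]])
    og_index <- rep(seq_len(n_og), lengths(members[[s]]))
    genes <- c(og_gene, spec_genes[[s]])
    base <- c(og_base[og_index], spec_base[[s]])
    is_specific <- c(rep(FALSE, length(og_gene)), rep(TRUE, length(spec_genes[[s]])))
    members_by_og <- setNames(members[[s]], og_ids)

    types <- spec$cell_types[[s]]
    marker_genes_of[[s]] <- setNames(vector("list", length(types)), types)
    blocks <- list(); bc <- list(); ann_type <- list()
    with_seed(spec$seed + si, {
      for (t in types) {
        comp <- comp_of[[paste(s, t, sep = "|")]]
        prog_og <- programs[[comp]]
        prog_genes <- c(unlist(members_by_og[prog_og], use.names = FALSE),
                        priv_programs[[s]][[t]])
        marker_genes_of[[s]][[t]] <- intersect(genes, prog_genes)
        mult <- ifelse(genes %in% prog_genes, spec$marker_fc, 1)
        stage <- match(t, spec$stage_order)
        if (is.na(stage)) stage <- 1L
        decay <- ifelse(is_specific, spec$specific_stage_decay^(stage - 1), 1)
        mu_gene <- base * mult * decay
        libf <- if (spec$library_size_cv > 0)
          rlnorm(spec$n_cells_per_type, meanlog = -sln2 / 2, sdlog = sqrt(sln2))
        else rep(1, spec$n_cells_per_type)
        mu <- outer(mu_gene, libf)
        cnt <- if (spec$nb_dispersion > 0)
          rnbinom(length(mu), size = 1 / spec$nb_dispersion, mu = as.vector(mu))
        else rpois(length(mu), as.vector(mu))
        blocks[[t]] <- matrix(cnt, nrow = length(genes))
        bc[[t]] <- sprintf("%s|%s|%04d", s, t, seq_len(spec$n_cells_per_type))
        ann_type[[t]] <- rep(t, spec$n_cells_per_type)
      }
    })
    counts <- do.call(cbind, blocks)
    rownames(counts) <- genes
    colnames(counts) <- unlist(bc, use.names = FALSE)
    matrices[[s]] <- cell_matrix(counts, s,
                                 setNames(unlist(ann_type, use.names = FALSE),
                                          unlist(bc, use.names = FALSE)))
  }

  # --- truth ---------------------------------------------------------------
  ortholog_table <- data.frame(orthogroup = og_ids, stringsAsFactors = FALSE)
  for (s in sp)
    ortholog_table[[s]] <- vapply(members[[s]], paste, character(1), collapse = ", ")
  gene_class_of <- do.call(rbind, lapply(sp, function(s) {
    og_gene <- unlist(members[[s]])
    og_index <- rep(seq_len(n_og), lengths(members[[s]]))
    data.frame(
      species = s,
      gene = c(og_gene, spec_genes[[s]]),
      class = c(ifelse(is_111[og_index], "ortholog_111", "ortholog_other"),
                rep("species_specific", length(spec_genes[[s]]))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(gene_class_of) <- NULL
  truth <- structure(
    list(ortholog_table = ortholog_table, gene_class_of = gene_class_of,
         marker_genes_of = marker_genes_of, programs = programs,
         homology_map = spec$homology_map, stage_order = spec$stage_order),
    class = "synthetic_truth"
  )
  structure(list(matrices = matrices, truth = truth, spec = spec),
            class = "ortho_sim")
}

#' @export
print.ortho_sim <- function(x, ...) {
  cat(sprintf("ortho_sim: %d species (%s), %d planted homologous type pairs, seed %d\n",
              length(x$matrices), paste(names(x$matrices), collapse = ", "),
              nrow(x$truth$homology_map), x$spec$seed))
  for (m in x$matrices) print(m)
  invisible(x)
}

#' Write a simulation to disk
#'
#' One 10x-style triplet directory per species (with annotation TSV), the
#' orthogroup table TSV, the gene-class table, the planted homology map,
#' and a provenance sidecar.
#'
#' @param sim an `ortho_sim` from [simulate_counts()].
#' @param dir_path output directory.
#' @export
write_simulation <- function(sim, dir_path) {
  stopifnot(inherits(sim, "ortho_sim"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$matrices))
    write_cell_matrix(sim$matrices[[s]], file.path(dir_path, s))
  write_orthogroups(sim$truth$ortholog_table, file.path(dir_path, "orthogroups.tsv"))
  write.table(sim$truth$gene_class_of, file.path(dir_path, "gene_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$homology_map, file.path(dir_path, "homology_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- setdiff(names(sim$spec), c("cell_types", "homology_map"))
  write_provenance(file.path(dir_path, "provenance.json"), "write_simulation",
                   sim$spec[keep])
  invisible(dir_path)
}
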