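#' Read an orthogroup table (Orthofinder-style wide TSV)
#'
#' First column: orthogroup id. One further column per species, holding a
#' comma(+space)-separated list of that species' member genes; an empty
#' field means the orthogroup has no member in that species.
#'
#' @param path TSV file path.
#' @return data.frame with character columns; first column `orthogroup`.
#' @export
read_orthogroups <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("orthogroup table needs an id column plus >=1 species column")
  names(tab)[1] <- "orthogroup"
  if (anyDuplicated(tab$orthogroup))
    stop("duplicate orthogroup ids: ",
         abbrev_ids(unique(tab$orthogroup[duplicated(tab$orthogroup)])))
  tab
}

#' Write an orthogroup table TSV
#' @param table orthogroup data.frame as from [read_orthogroups()].
#' @param path output TSV path.
#' @export
write_orthogroups <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split a comma(+space)-separated member field into gene ids.
split_members <- function(field) {
  out <- strsplit(field, ",[ ]*")
  lapply(out, function(v) v[nzchar(v)])
}

# orthogroup table -> list (per species) of lists (per orthogroup) of members
og_members <- function(table, species = setdiff(names(table), "orthogroup")) {
  out <- lapply(species, function(s) {
    m <- split_members(table[[s]])
    names(m) <- table$orthogroup
    m
  })
  names(out) <- species
  out
}

#' Classify genes into ortholog classes
#'
#' Partitions each species' gene universe into three classes:
#' * `ortholog_111` - members of orthogroups with exactly one gene in every
#'   classified species (single-copy orthologs; 1-1 for two species, 1-1-1
#'   for three);
#' * `ortholog_other` - genes in some orthogroup that is not single-copy
#'   across all species (1-many / many-many, or present in this species
#'   only);
#' * `species_specific` - genes with no ortholog annotation at all.
#'
#' Genes annotated in the table but absent from their species' universe are
#' retained in the output with a warning (annotation may exceed expressed
#' genes). Genes whose orthogroup is empty in every partner species count as
#' `ortholog_other` (they do have an ortholog annotation) and are flagged in
#' the `subclass` column as `"unpartnered"`.
#'
#' @param table orthogroup data.frame (see [read_orthogroups()]).
#' @param gene_universes named list, one character vector of gene ids per
#'   species (typically the rownames of each species' count matrix). Names
#'   must match species columns of `table`.
#' @return list with:
#'   * `classes`: data.frame (species, gene, class, subclass);
#'   * `pairs_11`: named list per unordered species pair
#'     (`"A|B"`) of data.frames (orthogroup, gene_a, gene_b) with exactly
#'     one member in each of the two species (other species ignored);
#'   * `singlecopy_all`: data.frame of orthogroups single-copy in every
#'     classified species, one gene column per species (the 1-1-1 triads
#'     when three species are classified).
#' @export
classify_orthologs <- function(table, gene_universes) {
  species <- names(gene_universes)
  if (is.null(species) || !all(species %in% names(table)))
    stop("gene_universes must be named by species columns present in the table")
  mem <- og_members(table, species)
  sizes <- vapply(species, function(s) lengths(mem[[s]]), integer(nrow(table)))
  if (nrow(table) == 1L) sizes <- matrix(sizes, nrow = 1, dimnames = list(NULL, species))

  # single-copy across all classified species
  sc_all <- rowSums(sizes == 1L) == length(species)
  singlecopy_all <- data.frame(orthogroup = table$orthogroup[sc_all],
                               stringsAsFactors = FALSE)
  for (s in species)
    singlecopy_all[[s]] <- vapply(mem[[s]][sc_all], `[`, character(1), 1)

  # pairwise 1-1 lists: exactly one member in each of the two species
  pairs_11 <- list()
  if (length(species) >= 2) {
    cmb <- utils::combn(species, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      keep <- sizes[, a] == 1L & sizes[, b] == 1L
      pairs_11[[paste(a, b, sep = "|")]] <- data.frame(
        orthogroup = table$orthogroup[keep],
        gene_a = vapply(mem[[a]][keep], `[`, character(1), 1),
        gene_b = vapply(mem[[b]][keep], `[`, character(1), 1),
        stringsAsFactors = FALSE
      )
    }
  }

  classes <- do.call(rbind, lapply(species, function(s) {
    annotated <- unlist(mem[[s]], use.names = FALSE)
    if (anyDuplicated(annotated))
      stop("gene(s) appear in two orthogroups for species ", s, ": ",
           abbrev_ids(unique(annotated[duplicated(annotated)])))
    partnered <- unlist(mem[[s]][rowSums(sizes[, setdiff(species, s), drop = FALSE]) > 0],
                        use.names = FALSE)
    sc_genes <- unlist(mem[[s]][sc_all], use.names = FALSE)
    universe <- gene_universes[[s]]
    extra <- setdiff(annotated, universe)
    if (length(extra))
      warning(sprintf("species %s: %d annotated gene(s) absent from its universe, retained: %s",
                      s, length(extra), abbrev_ids(extra)))
    genes <- union(universe, annotated)
    cls <- ifelse(genes %in% sc_genes, "ortholog_111",
                  ifelse(genes %in% annotated, "ortholog_other", "species_specific"))
    sub <- ifelse(cls == "ortholog_other" & !(genes %in% partnered),
                  "unpartnered", "")
    data.frame(species = s, gene = genes, class = cls, subclass = sub,
               stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  list(classes = classes, pairs_11 = pairs_11, singlecopy_all = singlecopy_all)
}

#' Expand orthogroups into gene pairs for a species pair
#'
#' For every orthogroup with at least one member in each of the two species,
#' emits the cartesian product of members: 1-many and many-many orthologs are
#' represented by copying the gene entries from one species, so the pair
#' count equals the sum over orthogroups of |members A| x |members B|.
#'
#' @param table orthogroup data.frame (see [read_orthogroups()]).
#' @param species_a,species_b species column names.
#' @return data.frame (orthogroup, gene_a, gene_b), ordered by orthogroup id
#'   then gene ids.
#' @export
expand_ortholog_pairs <- function(table, species_a, species_b) {
  for (s in c(species_a, species_b))
    if (!s %in% names(table)) stop("species not in table: ", s)
  mem <- og_members(table, c(species_a, species_b))
  ma <- mem[[species_a]]; mb <- mem[[species_b]]
  keep <- which(lengths(ma) > 0 & lengths(mb) > 0)
  keep <- keep[order(table$orthogroup[keep])]
  blocks <- lapply(keep, function(i) {
    ga <- sort(ma[[i]]); gb <- sort(mb[[i]])
    data.frame(orthogroup = table$orthogroup[i],
               gene_a = rep(ga, times = length(gb)),
               gene_b = rep(gb, each = length(ga)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(blocks)) do.call(rbind, blocks)
         else data.frame(orthogroup = character(), gene_a = character(),
                         gene_b = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
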