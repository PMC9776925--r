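#' Fraction of expressed genes per ortholog class along a stage order
#'
#' A gene counts as "expressed" in a cell type when it is detected
#' (normalized value > 0) in strictly more than `min_frac_cells` of that
#' type's cells. For every cell type the fraction of each gene class
#' (`ortholog_111`, `ortholog_other`, `species_specific`) among the
#' expressed genes is reported; fractions sum to 1 per type. The
#' `"abundance"` weighting instead apportions the type's total mean
#' expression across classes (restricted to expressed genes).
#'
#' @param x a `normalized_matrix`.
#' @param classes data.frame with columns `species`, `gene`, `class` (see
#'   [classify_orthologs()]); every gene of the matrix must be assigned to
#'   exactly one class for the matrix's species.
#' @param stage_order optional character vector giving the developmental
#'   order of cell types; emitted rows follow it. Defaults to alphabetical.
#' @param min_frac_cells detection fraction threshold (default 0.05).
#' @param weight `"detection"` (count expressed genes, default) or
#'   `"abundance"` (sum their mean expression).
#' @return data.frame (species, cell_type, class, fraction, n_expressed,
#'   n_expressed_total, flagged), cell types ordered by `stage_order`, with
#'   attributes `min_frac_cells` and `weight`. Types with zero expressed
#'   genes get `NA` fractions and `flagged = TRUE`.
#' @export
gene_class_fractions <- function(x, classes, stage_order = NULL,
                                 min_frac_cells = 0.05,
                                 weight = c("detection", "abundance")) {
  stopifnot(inherits(x, "normalized_matrix"))
  weight <- match.arg(weight)
  cls <- classes[classes$species == x$species, , drop = FALSE]
  if (anyDuplicated(cls$gene))
    stop("gene(s) assigned to more than one class: ",
         abbrev_ids(unique(cls$gene[duplicated(cls$gene)])))
  class_of <- setNames(cls$class, cls$gene)
  genes <- rownames(x$values)
  unassigned <- setdiff(genes, names(class_of))
  if (length(unassigned))
    stop("matrix gene(s) with no class assignment: ", abbrev_ids(unassigned))
  gene_class <- unname(class_of[genes])
  class_levels <- c("ortholog_111", "ortholog_other", "species_specific")

  types <- sort(unique(unname(x$cell_type_of)))
  if (!is.null(stage_order)) {
    misordered <- setdiff(types, stage_order)
    if (length(misordered))
      warning("cell type(s) absent from stage_order appended at the end: ",
              abbrev_ids(misordered))
    types <- c(intersect(stage_order, types), misordered)
  }

  rows <- lapply(types, function(t) {
    cells <- which(unname(x$cell_type_of) == t)
    n_cells <- length(cells)
    detected <- Matrix::rowSums(x$values[, cells, drop = FALSE] > 0)
    expressed <- detected > min_frac_cells * n_cells
    n_total <- sum(expressed)
    if (n_total == 0) {
      return(data.frame(species = x$species, cell_type = t,
                        class = class_levels, fraction = NA_real_,
                        n_expressed = 0L, n_expressed_total = 0L,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    n_by_class <- vapply(class_levels,
                         function(cl) sum(expressed & gene_class == cl), numeric(1))
    if (weight == "detection") {
      frac <- n_by_class / n_total
    } else {
      mexpr <- Matrix::rowSums(x$values[, cells, drop = FALSE]) / n_cells
      tot_by_class <- vapply(class_levels,
                             function(cl) sum(mexpr[expressed & gene_class == cl]),
                             numeric(1))
      frac <- tot_by_class / sum(tot_by_class)
    }
    data.frame(species = x$species, cell_type = t, class = class_levels,
               fraction = unname(frac), n_expressed = as.integer(n_by_class),
               n_expressed_total = as.integer(n_total), flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cell_type <- factor(out$cell_type, levels = types)
  rownames(out) <- NULL
  attr(out, "min_frac_cells") <- min_frac_cells
  attr(out, "weight") <- weight
  out
}

#' Write gene-class fractions as long-format TSV
#' @param fractions data.frame from [gene_class_fractions()].
#' @param path output TSV path.
#' @export
write_gene_class_fractions <- function(fractions, path) {
  write.table(fractions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
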