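#' Per-species single-cell UMI count matrix with cell-type labels
#'
#' A `cell_matrix` bundles a sparse genes x cells matrix of non-negative
#' integer UMI counts with a species label and a cell-type assignment for
#' every cell. It is the raw input of the whole pipeline.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts, with unique row (gene) and column (cell) names.
#' @param species single species label.
#' @param cell_types named character vector mapping every cell id (column
#'   name of `counts`) to a cell-type label.
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `species`, and `cell_type_of` (named character vector
#'   aligned with the columns of `counts`).
#' @export
cell_matrix <- function(counts, species, cell_types) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         abbrev_ids(unique(rownames(counts)[duplicated(rownames(counts))])))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids: ",
         abbrev_ids(unique(colnames(counts)[duplicated(colnames(counts))])))
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers")
  stopifnot(is.character(species), length(species) == 1L)
  missing <- setdiff(colnames(counts), names(cell_types))
  if (length(missing))
    stop("cells missing a cell-type label: ", abbrev_ids(missing))
  structure(
    list(
      counts = counts,
      species = species,
      cell_type_of = cell_types[colnames(counts)]
    ),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells, species '%s', %d cell types\n",
              nrow(x$counts), ncol(x$counts), x$species,
              length(unique(x$cell_type_of))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a 10x-style matrix-market directory into a `cell_matrix`
#'
#' The directory must contain `matrix.mtx` (genes x cells, integer counts,
#' 1-based matrix-market coordinates), `features.tsv` (gene ids, first
#' column), `barcodes.tsv` (cell ids), and an annotation TSV with columns
#' `barcode`, `species`, `cell_type`.
#'
#' @param dir_path directory holding the four files.
#' @param annotation path to the annotation TSV; defaults to
#'   `annotation.tsv` inside `dir_path`.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(dir_path, annotation = file.path(dir_path, "annotation.tsv")) {
  mtx_path <- file.path(dir_path, "matrix.mtx")
  feat_path <- file.path(dir_path, "features.tsv")
  bc_path <- file.path(dir_path, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path, annotation))
    if (!file.exists(p)) stop("missing input file: ", p)

  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  features <- read.delim(feat_path, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(bc_path, header = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(features[[1]])
  cells <- as.character(barcodes[[1]])

  if (nrow(counts) != length(genes))
    stop(sprintf("dimension mismatch: matrix has %d rows but features.tsv lists %d genes",
                 nrow(counts), length(genes)))
  if (ncol(counts) != length(cells))
    stop(sprintf("dimension mismatch: matrix has %d columns but barcodes.tsv lists %d cells",
                 ncol(counts), length(cells)))
  dimnames(counts) <- list(genes, cells)

  ann <- read.delim(annotation, header = TRUE, stringsAsFactors = FALSE)
  need <- c("barcode", "species", "cell_type")
  if (!all(need %in% names(ann)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$barcode))
    stop("duplicate barcodes in annotation: ",
         abbrev_ids(unique(ann$barcode[duplicated(ann$barcode)])))
  unannotated <- setdiff(cells, ann$barcode)
  if (length(unannotated))
    stop("cells present in matrix but missing from annotation: ",
         abbrev_ids(unannotated))
  ann <- ann[match(cells, ann$barcode), ]
  sp <- unique(ann$species)
  if (length(sp) != 1L)
    stop("a cell_matrix holds one species; annotation names: ",
         paste(sp, collapse = ", "))

  cell_matrix(counts, sp, setNames(ann$cell_type, ann$barcode))
}

#' Write a `cell_matrix` as a 10x-style matrix-market directory
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `annotation.tsv`
#' and a JSON provenance sidecar.
#'
#' @param x a [cell_matrix()].
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_cell_matrix <- function(x, dir_path) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir_path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir_path, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir_path, "barcodes.tsv"))
  ann <- data.frame(
    barcode = colnames(x$counts),
    species = x$species,
    cell_type = unname(x$cell_type_of),
    stringsAsFactors = FALSE
  )
  write.table(ann, file.path(dir_path, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(
    file.path(dir_path, "provenance.json"), "write_cell_matrix",
    list(species = x$species, n_genes = nrow(x$counts), n_cells = ncol(x$counts))
  )
  invisible(dir_path)
}
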