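#' Normalize UMI counts to counts-per-10k, optionally log1p
#'
#' Per-cell totals are rescaled to 10,000 (counts-per-10k, cp10k); the
#' `log1p_cp10k` scheme then applies `log1p`. Downstream similarity and
#' AUROC steps operate on `log1p_cp10k` values by default. Cells with zero
#' total counts are emitted as all-zero columns with a warning rather than
#' an error.
#'
#' @param x a [cell_matrix()].
#' @param scheme `"log1p_cp10k"` (default) or `"cp10k"`.
#' @param target per-cell total after rescaling (default 1e4).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (sparse genes x cells), `scheme`, `species`, `cell_type_of`.
#' @export
normalize_cells <- function(x, scheme = c("log1p_cp10k", "cp10k"), target = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  scheme <- match.arg(scheme)
  totals <- Matrix::colSums(x$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total counts kept as all-zero: %s",
                    sum(zero), abbrev_ids(colnames(x$counts)[zero])))
  }
  fac <- ifelse(zero, 0, target / totals)
  values <- x$counts %*% Matrix::Diagonal(x = fac)
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(x$counts)
  if (scheme == "log1p_cp10k") values@x <- log1p(values@x)
  structure(
    list(values = values, scheme = scheme, species = x$species,
         cell_type_of = x$cell_type_of),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d cells, species '%s'\n",
              x$scheme, nrow(x$values), ncol(x$values), x$species))
  invisible(x)
}

# Per-gene mean normalized expression within each cell type.
# Returns genes x types dense matrix; used by profiles and gene-class steps.
type_means <- function(values, cell_type_of) {
  types <- sort(unique(unname(cell_type_of)))
  out <- matrix(0, nrow(values), length(types),
                dimnames = list(rownames(values), types))
  for (t in types) {
    idx <- which(unname(cell_type_of) == t)
    out[, t] <- Matrix::rowSums(values[, idx, drop = FALSE]) / length(idx)
  }
  out
}
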