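#' Aggregate cells into pseudocells of size k
#'
#' Within every cell type, cells are randomly permuted (seeded) and chunked
#' into groups of `k`; a nonempty remainder forms a final smaller pseudocell
#' so no cell is dropped. Each pseudocell's value vector is the arithmetic
#' mean of its members' normalized expression. Pseudocells are built per
#' (species, cell type), never across species, which denoises sparse UMI
#' matrices before network-style analyses.
#'
#' @param x a `normalized_matrix` (see [normalize_cells()]).
#' @param k aggregation size (default 20 cells per pseudocell).
#' @param seed integer seed for the within-type permutation. Changing it
#'   changes memberships, never the per-type pseudocell count.
#' @return An object of class `pseudocell_matrix`: list with `values`
#'   (dense genes x pseudocells), `pseudocell_type_of`, `k`, `membership`
#'   (named list of member cell ids) and `species`.
#' @export
build_pseudocells <- function(x, k = 20, seed = 1L) {
  stopifnot(inherits(x, "normalized_matrix"), k >= 1)
  types <- sort(unique(unname(x$cell_type_of)))
  empty <- types[!types %in% x$cell_type_of]
  if (length(empty)) {
    warning("cell type(s) with zero cells excluded: ", abbrev_ids(empty))
    types <- setdiff(types, empty)
  }
  cols <- list(); type_of <- character(); membership <- list()
  with_seed(seed, {
    for (t in types) {
      cells <- colnames(x$values)[unname(x$cell_type_of) == t]
      perm <- cells[sample.int(length(cells))]
      sz <- chunk_sizes(length(cells), k)
      stops <- cumsum(sz)
      starts <- stops - sz + 1
      for (j in seq_along(sz)) {
        members <- perm[starts[j]:stops[j]]
        pc_id <- sprintf("%s|%s|pc%03d", x$species, t, j)
        sub <- as.matrix(x$values[, members, drop = FALSE])
        cols[[pc_id]] <- rowSums(sub) / length(members)
        type_of[pc_id] <- t
        membership[[pc_id]] <- members
      }
    }
  })
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(x$values)
  structure(
    list(values = values, pseudocell_type_of = type_of, k = k,
         membership = membership, species = x$species),
    class = "pseudocell_matrix"
  )
}

#' @export
print.pseudocell_matrix <- function(x, ...) {
  cat(sprintf("pseudocell_matrix: %d genes x %d pseudocells (k = %d), species '%s'\n",
              nrow(x$values), ncol(x$values), x$k, x$species))
  invisible(x)
}

#' Write pseudocell membership and values to disk
#'
#' Membership as TSV (pseudocell id, cell type, size, comma-separated member
#' barcodes); values as matrix-market MTX plus row/column id files.
#'
#' @param x a `pseudocell_matrix`.
#' @param dir_path output directory.
#' @export
write_pseudocells <- function(x, dir_path) {
  stopifnot(inherits(x, "pseudocell_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    pseudocell = colnames(x$values),
    cell_type = unname(x$pseudocell_type_of[colnames(x$values)]),
    size = lengths(x$membership[colnames(x$values)]),
    members = vapply(x$membership[colnames(x$values)],
                     paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(tab, file.path(dir_path, "pseudocells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"),
                  file.path(dir_path, "values.mtx"))
  writeLines(rownames(x$values), file.path(dir_path, "features.tsv"))
  writeLines(colnames(x$values), file.path(dir_path, "pseudocell_ids.tsv"))
  write_provenance(file.path(dir_path, "provenance.json"), "write_pseudocells",
                   list(species = x$species, k = x$k, n_pseudocells = ncol(x$values)))
  invisible(dir_path)
}

#' Select highly variable genes by binned standardized dispersion
#'
#' Genes are ranked by the dispersion (variance / mean) of their normalized
#' expression, standardized within bins of mean expression (default 20
#' quantile bins) so that highly expressed genes do not dominate. Genes with
#' zero variance rank last and are never selected while any variable gene
#' remains.
#'
#' @param x a `normalized_matrix` or `pseudocell_matrix`.
#' @param n number of genes to return.
#' @param n_bins number of mean-expression bins (default 20).
#' @return Character vector of up to `n` gene ids, ordered from most to
#'   least variable. If fewer than `n` genes are expressed, all expressed
#'   genes are returned with a warning.
#' @export
select_hvg <- function(x, n, n_bins = 20) {
  stopifnot(n >= 1)
  values <- x$values
  nc <- ncol(values)
  m <- as.numeric(Matrix::rowMeans(values))
  ex2 <- as.numeric(Matrix::rowSums(values^2)) / nc
  v <- (ex2 - m^2) * nc / max(nc - 1, 1)
  v <- pmax(v, 0)
  disp <- ifelse(m > 0, v / m, 0)

  expressed <- m > 0 & v > 0
  z <- rep(-Inf, length(m))
  if (any(expressed)) {
    br <- unique(quantile(m[expressed], probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(m[expressed], breaks = br, include.lowest = TRUE)
    d <- disp[expressed]
    zb <- stats::ave(d, bins, FUN = function(w) {
      s <- stats::sd(w)
      if (!is.finite(s) || s == 0) rep(0, length(w)) else (w - mean(w)) / s
    })
    z[expressed] <- zb
  }
  ord <- order(-z, -disp, rownames(values))
  ranked <- rownames(values)[ord][seq_len(sum(expressed))]
  if (length(ranked) < n) {
    warning(sprintf("only %d variable gene(s) available, fewer than n = %d",
                    length(ranked), n))
    return(ranked)
  }
  ranked[seq_len(n)]
}
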