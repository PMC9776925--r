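#' Build cell-type expression profiles on ortholog-pair coordinates
#'
#' For every cell type of one species, computes the mean normalized
#' expression of each gene along the expanded ortholog-pair coordinates
#' (see [expand_ortholog_pairs()]). A gene appearing in several pairs (a
#' 1-many / many-many ortholog) is copied to every coordinate it occurs in,
#' so the two species' profiles live on a common coordinate system. Pair
#' genes absent from the matrix are filled with 0 and counted in a warning.
#'
#' @param x a `normalized_matrix`.
#' @param pairs data.frame from [expand_ortholog_pairs()].
#' @param side `"a"` or `"b"`: which side of each pair indexes this matrix.
#' @return Object of class `celltype_profiles`: list with `values`
#'   (n_pairs x n_types matrix), `species`, `n_cells` (named cell counts),
#'   `pairs`, `side`.
#' @export
build_profiles <- function(x, pairs, side = c("a", "b")) {
  stopifnot(inherits(x, "normalized_matrix"))
  side <- match.arg(side)
  genes <- pairs[[paste0("gene_", side)]]
  if (is.null(genes)) stop("pairs must have columns gene_a and gene_b")
  tm <- type_means(x$values, x$cell_type_of)
  hit <- genes %in% rownames(tm)
  if (!all(hit))
    warning(sprintf("%d pair coordinate(s) reference genes absent from the matrix; filled with 0: %s",
                    sum(!hit), abbrev_ids(unique(genes[!hit]))))
  values <- matrix(0, length(genes), ncol(tm),
                   dimnames = list(NULL, colnames(tm)))
  values[hit, ] <- tm[genes[hit], , drop = FALSE]
  n_cells <- vapply(colnames(tm),
                    function(t) sum(unname(x$cell_type_of) == t), integer(1))
  structure(
    list(values = values, species = x$species, n_cells = n_cells,
         pairs = pairs, side = side),
    class = "celltype_profiles"
  )
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D(p || q) = sum_i p_i * ln(p_i / q_i)` in nats. Inputs must be
#' probability vectors; coordinates with `p_i = 0` contribute 0.
#'
#' @param p,q numeric probability vectors of equal length.
#' @return Non-negative scalar (nats).
#' @export
kld_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# profile -> probability vector with pseudocount (fraction of total mass)
profile_to_prob <- function(v, pseudocount) {
  tot <- sum(v)
  if (tot <= 0) {
    warning("all-zero profile treated as uniform")
    return(rep(1 / length(v), length(v)))
  }
  w <- v + pseudocount * tot
  w / sum(w)
}

#' Cell-type similarity by symmetrized Kullback-Leibler divergence
#'
#' Each cell-type profile (plus a small pseudocount, a fraction of its total
#' mass, to keep the divergence finite with zeros) is normalized to a
#' probability vector over the shared ortholog-pair coordinates. The
#' similarity entry for types (a, b) is the symmetrized divergence
#' `(D(p_a || p_b) + D(p_b || p_a)) / 2` in nats; 0 means identical
#' profiles, larger means more divergent. Directional matrices are kept for
#' inspection.
#'
#' @param profiles_a,profiles_b `celltype_profiles` of the two species on
#'   the same pair coordinates.
#' @param pseudocount fraction of each profile's total mass added to every
#'   coordinate before normalization (default 1e-8).
#' @return Object of class `similarity_result`: list with `kld`
#'   (types of A x types of B, symmetrized), `kld_ab`, `kld_ba`
#'   (directional), `species`, `pseudocount`.
#' @export
kld_similarity <- function(profiles_a, profiles_b, pseudocount = 1e-8) {
  stopifnot(inherits(profiles_a, "celltype_profiles"),
            inherits(profiles_b, "celltype_profiles"),
            pseudocount > 0)
  if (nrow(profiles_a$values) != nrow(profiles_b$values))
    stop("profiles have different coordinate lengths")
  if (nrow(profiles_a$values) == 0) stop("zero-length profiles")
  pa <- apply(profiles_a$values, 2, profile_to_prob, pseudocount = pseudocount)
  pb <- apply(profiles_b$values, 2, profile_to_prob, pseudocount = pseudocount)
  ta <- colnames(profiles_a$values); tb <- colnames(profiles_b$values)
  kld_ab <- kld_ba <- matrix(NA_real_, length(ta), length(tb),
                             dimnames = list(ta, tb))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      kld_ab[i, j] <- kld_divergence(pa[, i], pb[, j])
      kld_ba[i, j] <- kld_divergence(pb[, j], pa[, i])
    }
  }
  structure(
    list(kld = (kld_ab + kld_ba) / 2, kld_ab = kld_ab, kld_ba = kld_ba,
         species = c(a = profiles_a$species, b = profiles_b$species),
         pseudocount = pseudocount),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity_result: %d x %d cell types (%s vs %s), symmetrized KLD\n",
              nrow(x$kld), ncol(x$kld), x$species[["a"]], x$species[["b"]]))
  invisible(x)
}

#' Retain the most similar cell-type pairs (smallest KLD)
#'
#' Under the default `"top_fraction"` rule, similarity is `-KLD` and the
#' pairs at or above its `q` quantile are retained: with `q = 0.85` that is
#' the top 15% most similar pairs, i.e. `ceiling((1 - q) * n)` links absent
#' ties. Ties at the threshold are all retained (inclusive), with a warning
#' when every pair ties. The alternative `"kld_quantile"` rule instead
#' retains pairs whose raw KLD is at or below the `q` quantile of the KLD
#' values themselves.
#'
#' @param result a `similarity_result`.
#' @param q quantile (default 0.85).
#' @param rule `"top_fraction"` (default) or `"kld_quantile"`.
#' @return data.frame (type_a, type_b, kld, similarity_rank) with
#'   attributes `threshold`, `q`, `rule`, `species`.
#' @export
link_celltypes <- function(result, q = 0.85, rule = c("top_fraction", "kld_quantile")) {
  stopifnot(inherits(result, "similarity_result"), q > 0, q < 1)
  rule <- match.arg(rule)
  kld <- result$kld
  n <- length(kld)
  if (rule == "top_fraction") {
    s <- -kld
    # rounding guards against e.g. (1 - 0.85) * 100 = 15 + 2e-15
    m <- ceiling(round((1 - q) * n, 9))
    thr_s <- sort(as.numeric(s), decreasing = TRUE)[m]
    keep <- which(s >= thr_s, arr.ind = TRUE)
    threshold <- -thr_s  # on the KLD scale
  } else {
    threshold <- as.numeric(quantile(as.numeric(kld), probs = q, type = 7))
    keep <- which(kld <= threshold, arr.ind = TRUE)
  }
  if (nrow(keep) == n && n > 1 && diff(range(kld)) == 0)
    warning("all cell-type pairs tie at the threshold; all retained")
  out <- data.frame(
    type_a = rownames(kld)[keep[, 1]],
    type_b = colnames(kld)[keep[, 2]],
    kld = kld[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$kld, out$type_a, out$type_b), ]
  out$similarity_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "q") <- q
  attr(out, "rule") <- rule
  attr(out, "species") <- result$species
  out
}

#' Write a similarity result and links as TSV
#'
#' The KLD matrix is written with species-prefixed row/column type labels;
#' links as a circos-ready list (speciesA:type, speciesB:type, kld,
#' similarity_rank).
#'
#' @param result a `similarity_result`.
#' @param links data.frame from [link_celltypes()] (optional).
#' @param dir_path output directory.
#' @export
write_similarity <- function(result, dir_path, links = NULL) {
  stopifnot(inherits(result, "similarity_result"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- result$kld
  rownames(m) <- paste(result$species[["a"]], rownames(m), sep = ":")
  colnames(m) <- paste(result$species[["b"]], colnames(m), sep = ":")
  write.table(data.frame(cell_type = rownames(m), m, check.names = FALSE),
              file.path(dir_path, "kld.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  params <- list(species = as.list(result$species), pseudocount = result$pseudocount)
  if (!is.null(links)) {
    lk <- data.frame(
      type_a = paste(result$species[["a"]], links$type_a, sep = ":"),
      type_b = paste(result$species[["b"]], links$type_b, sep = ":"),
      kld = links$kld,
      similarity_rank = links$similarity_rank,
      stringsAsFactors = FALSE
    )
    write.table(lk, file.path(dir_path, "links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    params$q <- attr(links, "q")
    params$rule <- attr(links, "rule")
    params$threshold <- attr(links, "threshold")
  }
  write_provenance(file.path(dir_path, "provenance.json"), "write_similarity", params)
  invisible(dir_path)
}
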