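#' AUROC from scores via the Mann-Whitney rank identity
#'
#' `AUROC = (R+ - n+(n+1)/2) / (n+ * n-)` where `R+` is the rank-sum of the
#' positive scores (midranks for ties). Equals the probability that a random
#' positive outranks a random negative, counting ties as 1/2, and is
#' invariant to strictly monotone transformations of the scores.
#'
#' @param scores numeric vector.
#' @param positive logical vector, `TRUE` for positives.
#' @return AUROC in `[0, 1]`, or `NA` if either class is empty.
#' @export
auroc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# rank-normalize each column (pseudocell profile) of a matrix; ties -> midranks
rank_columns <- function(m) apply(m, 2, rank)

#' Neighbor-voting AUROC between two pseudocell datasets
#'
#' MetaNeighbor-style cross-dataset cell-type replicability. Pseudocell
#' profiles of both datasets are placed on the shared ortholog-pair
#' coordinates, rank-normalized within dataset, and connected by a Spearman
#' correlation network across all pseudocells. With one dataset as test and
#' the other as training, each test pseudocell's vote for a training type is
#' the sum of its network weights to that type's training pseudocells; the
#' AUROC for (test type c, training type t) asks how well votes for t rank
#' the test pseudocells of type c above the rest, via the Mann-Whitney
#' identity. Both directions (each dataset as test once) are computed and
#' averaged.
#'
#' In `"one_vs_best"` mode, each test type keeps only its two highest-voted
#' candidate training types and reports the AUROC discriminating votes for
#' the best from votes for the second-best over that type's test
#' pseudocells; other entries are `NA`.
#'
#' @param pseudo_a,pseudo_b `pseudocell_matrix` objects (see
#'   [build_pseudocells()]).
#' @param pairs data.frame from [expand_ortholog_pairs()]; `gene_a` indexes
#'   `pseudo_a`, `gene_b` indexes `pseudo_b`.
#' @param mode `"all_vs_all"` (default) or `"one_vs_best"`.
#' @param hvg optional named list of per-species highly variable gene
#'   vectors (names = the two species labels); pair coordinates are kept
#'   when either side's gene is in its species' list.
#' @return Object of class `auroc_result`: list with `auroc` (types of A x
#'   types of B), `mode`, `per_direction` (the two unaveraged matrices),
#'   and for `one_vs_best` a `best_hits` data.frame (direction, test_type,
#'   best, second, auroc).
#' @export
neighbor_voting_auroc <- function(pseudo_a, pseudo_b, pairs,
                                  mode = c("all_vs_all", "one_vs_best"),
                                  hvg = NULL) {
  stopifnot(inherits(pseudo_a, "pseudocell_matrix"),
            inherits(pseudo_b, "pseudocell_matrix"))
  mode <- match.arg(mode)

  if (!is.null(hvg)) {
    ha <- hvg[[pseudo_a$species]] %||% character()
    hb <- hvg[[pseudo_b$species]] %||% character()
    keep <- pairs$gene_a %in% ha | pairs$gene_b %in% hb
    if (!any(keep)) stop("hvg restriction removed every pair coordinate")
    pairs <- pairs[keep, , drop = FALSE]
  }
  xa <- coord_matrix(pseudo_a, pairs$gene_a)
  xb <- coord_matrix(pseudo_b, pairs$gene_b)

  net <- stats::cor(cbind(rank_columns(xa), rank_columns(xb)))
  net[!is.finite(net)] <- 0
  na <- ncol(xa)
  idx_a <- seq_len(na); idx_b <- na + seq_len(ncol(xb))
  lab_a <- unname(pseudo_a$pseudocell_type_of[colnames(pseudo_a$values)])
  lab_b <- unname(pseudo_b$pseudocell_type_of[colnames(pseudo_b$values)])

  dir_ab <- vote_auroc(net[idx_a, idx_b, drop = FALSE], lab_a, lab_b, mode)
  dir_ba <- vote_auroc(t(net[idx_a, idx_b, drop = FALSE]), lab_b, lab_a, mode)

  m1 <- dir_ab$auroc            # test types of A x training types of B
  m2 <- t(dir_ba$auroc)         # -> types of A x types of B
  comb <- array(NA_real_, dim = dim(m1), dimnames = dimnames(m1))
  both <- !is.na(m1) & !is.na(m2)
  comb[both] <- (m1[both] + m2[both]) / 2
  comb[!is.na(m1) & is.na(m2)] <- m1[!is.na(m1) & is.na(m2)]
  comb[is.na(m1) & !is.na(m2)] <- m2[is.na(m1) & !is.na(m2)]

  best_hits <- NULL
  if (mode == "one_vs_best") {
    best_hits <- rbind(
      cbind(direction = sprintf("%s_vs_%s", pseudo_a$species, pseudo_b$species),
            dir_ab$best_hits),
      cbind(direction = sprintf("%s_vs_%s", pseudo_b$species, pseudo_a$species),
            dir_ba$best_hits)
    )
  }
  structure(
    list(auroc = comb, mode = mode,
         per_direction = list(a_as_test = m1, b_as_test = m2),
         best_hits = best_hits,
         species = c(a = pseudo_a$species, b = pseudo_b$species)),
    class = "auroc_result"
  )
}

# profiles of a pseudocell_matrix on pair coordinates (genes may repeat);
# genes absent from the matrix become all-zero coordinates
coord_matrix <- function(pseudo, genes) {
  hit <- genes %in% rownames(pseudo$values)
  out <- matrix(0, length(genes), ncol(pseudo$values),
                dimnames = list(NULL, colnames(pseudo$values)))
  out[hit, ] <- pseudo$values[genes[hit], , drop = FALSE]
  out
}

# One voting direction: rows of `w` are test pseudocells, columns training.
# Returns AUROC matrix (test types x training types) and best-hit table.
vote_auroc <- function(w, test_labels, train_labels, mode) {
  train_types <- sort(unique(train_labels))
  test_types <- sort(unique(test_labels))
  votes <- vapply(train_types, function(t)
    rowSums(w[, train_labels == t, drop = FALSE]),
    numeric(nrow(w)))
  if (nrow(w) == 1L) votes <- matrix(votes, nrow = 1, dimnames = list(NULL, train_types))

  auroc <- matrix(NA_real_, length(test_types), length(train_types),
                  dimnames = list(test_types, train_types))
  singletons <- test_types[vapply(test_types, function(c)
    sum(test_labels == c) < 2L, logical(1))]
  if (length(singletons))
    warning("test type(s) with a single pseudocell, AUROC undefined: ",
            abbrev_ids(singletons))
  best_hits <- NULL
  for (c in setdiff(test_types, singletons)) {
    pos <- test_labels == c
    if (mode == "all_vs_all") {
      for (t in train_types)
        auroc[c, t] <- auroc_score(votes[, t], pos)
    } else {
      mean_votes <- colMeans(votes[pos, , drop = FALSE])
      if (length(train_types) < 2) next
      ord <- order(-mean_votes)
      t1 <- train_types[ord[1]]; t2 <- train_types[ord[2]]
      sc <- c(votes[pos, t1], votes[pos, t2])
      lab <- rep(c(TRUE, FALSE), each = sum(pos))
      auroc[c, t1] <- auroc_score(sc, lab)
      best_hits <- rbind(best_hits, data.frame(
        test_type = c, best = t1, second = t2, auroc = auroc[c, t1],
        stringsAsFactors = FALSE
      ))
    }
  }
  list(auroc = auroc, best_hits = best_hits)
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("auroc_result (%s): %d x %d cell types (%s vs %s)\n",
              x$mode, nrow(x$auroc), ncol(x$auroc),
              x$species[["a"]], x$species[["b"]]))
  invisible(x)
}

#' Write an AUROC matrix as TSV with species-prefixed type labels
#' @param x an `auroc_result`.
#' @param dir_path output directory.
#' @export
write_auroc <- function(x, dir_path) {
  stopifnot(inherits(x, "auroc_result"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- x$auroc
  rownames(m) <- paste(x$species[["a"]], rownames(m), sep = ":")
  colnames(m) <- paste(x$species[["b"]], colnames(m), sep = ":")
  write.table(data.frame(cell_type = rownames(m), m, check.names = FALSE),
              file.path(dir_path, "auroc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$best_hits))
    write.table(x$best_hits, file.path(dir_path, "best_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(file.path(dir_path, "provenance.json"), "write_auroc",
                   list(mode = x$mode, species = as.list(x$species)))
  invisible(dir_path)
}
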