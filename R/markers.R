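#' Paired Wilcoxon signed-rank test
#'
#' Differences `x - y` are computed per pair; zero differences are dropped
#' (standard signed-rank convention) and absolute differences ranked with
#' midranks for ties. The statistic `W` is the rank-sum of positive
#' differences. For `n <= 25` retained pairs the two-sided p-value is exact:
#' the full null distribution over all `2^n` equally likely sign assignments
#' is computed (by convolution over the ranks, identical to literal
#' enumeration and valid with ties). For larger `n` a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param method `"auto"` (exact up to n = 25, else approximate),
#'   `"exact"`, or `"approx"`.
#' @return list with `statistic` (W), `p_value` (two-sided), `n_used`
#'   (pairs retained after zero-difference removal) and `method`.
#' @export
paired_wilcoxon <- function(x, y, method = c("auto", "exact", "approx")) {
  stopifnot(length(x) == length(y))
  method <- match.arg(method)
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (method == "auto") method <- if (n <= 25) "exact" else "approx"
  if (method == "exact") {
    p <- signed_rank_exact_p(r, w)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(statistic = w, p_value = p, n_used = n, method = method)
}

# Exact two-sided p for the signed-rank statistic given the midranks of the
# |differences|. Doubled ranks are integers, so the distribution of 2W over
# the 2^n sign assignments is a polynomial convolution; this is the full
# enumeration computed efficiently.
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  f <- 1  # f[i] = P(2W = i - 1)
  for (ri in r2) {
    g <- c(f, numeric(ri)) / 2
    g[(ri + 1):(ri + length(f))] <- g[(ri + 1):(ri + length(f))] + f / 2
    f <- g
  }
  w2 <- as.integer(round(2 * w))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):length(f)])
  min(1, 2 * min(p_le, p_ge))
}

#' Shared ortholog markers of a linked cross-species cell-type group
#'
#' For a group of linked cell types (>= 1 type per species, not all types of
#' either species), computes for every ortholog-pair coordinate the fold
#' change of mean in-group over mean out-group expression in each species,
#' and retains pairs with FC strictly greater than `fc_threshold` in BOTH
#' species. Each retained ortholog is then tested with a paired Wilcoxon
#' signed-rank test whose pairs are (in-group mean, expression in out-group
#' cell type t) over all out-group types, pooled across the two species;
#' p-values are BH-adjusted across the retained orthologs of the group. A
#' group-level panel test, pooling one (in-group, out-group) pair per
#' retained ortholog and species, is attached as attributes
#' `panel_statistic` / `panel_p`.
#'
#' @param profiles_a,profiles_b `celltype_profiles` of the two species on
#'   the same pair coordinates (see [build_profiles()]).
#' @param group_a,group_b cell types of the group in species A / B.
#' @param fc_threshold fold-change cutoff (strict `>`, default 1.3).
#' @param pseudocount added to numerator and denominator of each fold
#'   change (default 1e-9).
#' @param group_id label written in the output rows.
#' @return data.frame (group, orthogroup, gene_a, gene_b, fc_a, fc_b,
#'   statistic, p_value, p_adj), one row per retained ortholog pair, with
#'   panel-test attributes.
#' @export
shared_markers <- function(profiles_a, profiles_b, group_a, group_b,
                           fc_threshold = 1.3, pseudocount = 1e-9,
                           group_id = "group1") {
  stopifnot(inherits(profiles_a, "celltype_profiles"),
            inherits(profiles_b, "celltype_profiles"))
  pairs <- profiles_a$pairs
  va <- profiles_a$values; vb <- profiles_b$values
  if (!all(group_a %in% colnames(va)))
    stop("unknown cell type(s) in group_a: ",
         abbrev_ids(setdiff(group_a, colnames(va))))
  if (!all(group_b %in% colnames(vb)))
    stop("unknown cell type(s) in group_b: ",
         abbrev_ids(setdiff(group_b, colnames(vb))))
  out_a <- setdiff(colnames(va), group_a)
  out_b <- setdiff(colnames(vb), group_b)
  if (!length(out_a) || !length(out_b))
    stop("group covers every cell type of one species; out-group is empty")

  in_a <- rowMeans(va[, group_a, drop = FALSE])
  in_b <- rowMeans(vb[, group_b, drop = FALSE])
  outm_a <- rowMeans(va[, out_a, drop = FALSE])
  outm_b <- rowMeans(vb[, out_b, drop = FALSE])
  fc_a <- (in_a + pseudocount) / (outm_a + pseudocount)
  fc_b <- (in_b + pseudocount) / (outm_b + pseudocount)
  keep <- which(fc_a > fc_threshold & fc_b > fc_threshold)

  res <- data.frame(
    group = group_id,
    orthogroup = pairs$orthogroup[keep],
    gene_a = pairs$gene_a[keep],
    gene_b = pairs$gene_b[keep],
    fc_a = unname(fc_a[keep]),
    fc_b = unname(fc_b[keep]),
    statistic = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(keep)) {
    co <- keep[i]
    test <- paired_wilcoxon(
      c(rep(in_a[co], length(out_a)), rep(in_b[co], length(out_b))),
      c(va[co, out_a], vb[co, out_b])
    )
    res$statistic[i] <- test$statistic
    res$p_value[i] <- test$p_value
  }
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res <- res[order(-pmin(res$fc_a, res$fc_b)), ]
  rownames(res) <- NULL

  panel <- if (nrow(res) > 0) {
    paired_wilcoxon(c(in_a[keep], in_b[keep]), c(outm_a[keep], outm_b[keep]))
  } else list(statistic = NA_real_, p_value = NA_real_)
  attr(res, "panel_statistic") <- panel$statistic
  attr(res, "panel_p") <- panel$p_value
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "group") <- list(a = group_a, b = group_b)
  res
}

#' Long-format expression table for a marker panel (violin-ready)
#'
#' For each retained ortholog of a marker table and each cell type, one row
#' of mean normalized expression per species side, suitable for violin-style
#' plots of in-group vs out-group expression.
#'
#' @param markers data.frame from [shared_markers()].
#' @param profiles_a,profiles_b the `celltype_profiles` the markers were
#'   computed from.
#' @return data.frame (species, cell_type, orthogroup, gene, expression).
#' @export
marker_expression_long <- function(markers, profiles_a, profiles_b) {
  long_side <- function(profiles, genes, ogs) {
    v <- profiles$values
    idx <- match(paste(ogs, genes), paste(profiles$pairs$orthogroup,
                                          profiles$pairs[[paste0("gene_", profiles$side)]]))
    do.call(rbind, lapply(seq_along(idx), function(i)
      data.frame(species = profiles$species,
                 cell_type = colnames(v),
                 orthogroup = ogs[i],
                 gene = genes[i],
                 expression = v[idx[i], ],
                 stringsAsFactors = FALSE)))
  }
  out <- rbind(long_side(profiles_a, markers$gene_a, markers$orthogroup),
               long_side(profiles_b, markers$gene_b, markers$orthogroup))
  rownames(out) <- NULL
  out
}

#' Flag single-copy orthologs with species-biased expression
#'
#' For every single-copy (1-1(-1)) ortholog, the maximum per-cell-type mean
#' expression is computed within each species. The ortholog is flagged for
#' species `s` when that maximum exceeds `fc_threshold` times the maximum of
#' every other species AND the gene's values across the pseudocells of `s`
#' differ significantly from EACH other species by Wilcoxon rank-sum test
#' (the reported p is the maximum over the pairwise comparisons, an
#' intersection-union test), at BH-adjusted level `alpha`. Requiring every
#' pairwise comparison, rather than a pooled one, keeps compositional
#' normalization shifts in one species from flagging orthologs in the
#' others. This is a documented operational definition of
#' "species-differential orthologs"; no standard procedure exists.
#'
#' @param pseudos named list (by species) of `pseudocell_matrix` objects.
#' @param singlecopy data.frame with one gene column per species (plus an
#'   optional `orthogroup` column), as in the `singlecopy_all` element of
#'   [classify_orthologs()].
#' @param fc_threshold ratio the species' maximum must exceed (default 1.3).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param pseudocount protects the max-ratio against zeros (default 1e-9).
#' @return list with `flagged` (named list per species of orthogroup ids)
#'   and `table` (per candidate: orthogroup, species, fc_min, p_value,
#'   p_adj, flagged).
#' @export
species_differential_orthologs <- function(pseudos, singlecopy,
                                           fc_threshold = 1.3, alpha = 0.05,
                                           pseudocount = 1e-9) {
  species <- names(pseudos)
  stopifnot(length(species) >= 2, all(species %in% names(singlecopy)))
  ogs <- singlecopy$orthogroup %||% paste0("og", seq_len(nrow(singlecopy)))

  vals <- lapply(species, function(s) {
    genes <- singlecopy[[s]]
    v <- matrix(0, length(genes), ncol(pseudos[[s]]$values))
    hit <- genes %in% rownames(pseudos[[s]]$values)
    v[hit, ] <- pseudos[[s]]$values[genes[hit], , drop = FALSE]
    v
  })
  names(vals) <- species
  max_type_mean <- vapply(species, function(s) {
    tm <- vapply(sort(unique(unname(pseudos[[s]]$pseudocell_type_of))), function(t) {
      idx <- unname(pseudos[[s]]$pseudocell_type_of[colnames(pseudos[[s]]$values)]) == t
      rowMeans(vals[[s]][, idx, drop = FALSE])
    }, numeric(nrow(singlecopy)))
    if (nrow(singlecopy) == 1L) tm <- matrix(tm, nrow = 1)
    apply(tm, 1, max)
  }, numeric(nrow(singlecopy)))
  if (nrow(singlecopy) == 1L)
    max_type_mean <- matrix(max_type_mean, nrow = 1, dimnames = list(NULL, species))

  rows <- NULL
  for (s in species) {
    others <- setdiff(species, s)
    ratio <- apply((max_type_mean[, s] + pseudocount) /
                     (max_type_mean[, others, drop = FALSE] + pseudocount), 1, min)
    cand <- which(ratio > fc_threshold)
    for (i in cand) {
      x <- vals[[s]][i, ]
      p <- max(vapply(others, function(o) suppressWarnings(
        wilcox.test(x, vals[[o]][i, ], exact = FALSE)$p.value), numeric(1)))
      rows <- rbind(rows, data.frame(
        orthogroup = ogs[i], species = s, fc_min = ratio[i],
        p_value = p, stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(orthogroup = character(), species = character(),
                       fc_min = numeric(), p_value = numeric(),
                       p_adj = numeric(), flagged = logical(),
                       stringsAsFactors = FALSE)
  } else {
    rows$p_adj <- p.adjust(rows$p_value, method = "BH")
    rows$flagged <- rows$p_adj < alpha
  }
  flagged <- lapply(setNames(species, species),
                    function(s) rows$orthogroup[rows$species == s & rows$flagged])
  list(flagged = flagged, table = rows)
}
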