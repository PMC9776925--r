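og_table <- function(...) {
  rows <- list(...)
  out <- data.frame(orthogroup = vapply(rows, `[[`, character(1), 1),
                    stringsAsFactors = FALSE)
  for (s in names(rows[[1]])[-1])
    out[[s]] <- vapply(rows, `[[`, character(1), s)
  out
}

test_that("single-copy orthogroups yield triads and all pairwise 1-1 pairs", {
  tab <- og_table(
    c(orthogroup = "OG1", A = "a1", B = "b1", C = "c1"),
    c(orthogroup = "OG2", A = "a2, a3", B = "b2", C = ""),
    c(orthogroup = "OG3", A = "", B = "b3", C = "c2")
  )
  uni <- list(A = c("a1", "a2", "a3", "a9"), B = c("b1", "b2", "b3"),
              C = c("c1", "c2"))
  cls <- classify_orthologs(tab, uni)

  expect_equal(cls$singlecopy_all$orthogroup, "OG1")
  expect_equal(cls$singlecopy_all$A, "a1")
  # OG1 gives a 1-1 pair for every species pair; OG3 is 1-1 for (B, C)
  expect_equal(cls$pairs_11[["A|B"]]$orthogroup, "OG1")
  expect_equal(cls$pairs_11[["A|C"]]$orthogroup, "OG1")
  expect_equal(sort(cls$pairs_11[["B|C"]]$orthogroup), c("OG1", "OG3"))

  cA <- cls$classes[cls$classes$species == "A", ]
  expect_equal(cA$class[cA$gene == "a1"], "ortholog_111")
  # 1-many members are other orthologs, never 1-1
  expect_true(all(cA$class[cA$gene %in% c("a2", "a3")] == "ortholog_other"))
  # no ortholog annotation -> species-specific
  expect_equal(cA$class[cA$gene == "a9"], "species_specific")
})

test_that("classes partition each species' universe and ignore row order", {
  tab <- og_table(
    c(orthogroup = "OG1", A = "a1", B = "b1"),
    c(orthogroup = "OG2", A = "a2, a3", B = "b2, b4"),
    c(orthogroup = "OG3", A = "a4", B = "")
  )
  uni <- list(A = c("a1", "a2", "a3", "a4", "a5"), B = c("b1", "b2", "b4", "b9"))
  cls <- classify_orthologs(tab, uni)
  for (s in names(uni)) {
    got <- cls$classes[cls$classes$species == s, ]
    expect_setequal(got$gene, uni[[s]])
    expect_false(anyDuplicated(got$gene) > 0)
  }
  # orthogroup present in one species only: annotated, hence other ortholog,
  # flagged as unpartnered
  a4 <- cls$classes[cls$classes$gene == "a4", ]
  expect_equal(a4$class, "ortholog_other")
  expect_equal(a4$subclass, "unpartnered")

  cls2 <- classify_orthologs(tab[c(3, 1, 2), ], uni)
  reorder <- function(d) d[order(d$species, d$gene), c("species", "gene", "class")]
  expect_equal(reorder(cls2$classes), reorder(cls$classes),
               ignore_attr = TRUE)
})

test_that("annotated genes absent from the universe warn and are retained", {
  tab <- og_table(c(orthogroup = "OG1", A = "a1, a2", B = "b1"))
  expect_warning(
    cls <- classify_orthologs(tab, list(A = "a1", B = "b1")),
    "a2"
  )
  expect_true("a2" %in% cls$classes$gene)
})

test_that("pair expansion is the within-orthogroup cartesian product", {
  tab <- og_table(
    c(orthogroup = "OG1", A = "a1, a2", B = "b1, b2, b3"),
    c(orthogroup = "OG2", A = "a3", B = "b4"),
    c(orthogroup = "OG3", A = "a4", B = "")
  )
  pairs <- expand_ortholog_pairs(tab, "A", "B")
  expect_equal(sum(pairs$orthogroup == "OG1"), 6)  # 2 x 3
  expect_equal(sum(pairs$orthogroup == "OG2"), 1)  # 1-1
  expect_false("OG3" %in% pairs$orthogroup)        # empty in B
  expect_equal(nrow(pairs), 7)
})

test_that("expanded pair counts match brute-force enumeration on random tables", {
  set.seed(11)
  for (rep in 1:60) {
    n_og <- sample(3:8, 1)
    mem <- lapply(seq_len(n_og), function(i) {
      list(A = if ((na <- sample(0:3, 1)) > 0) sprintf("a%d_%d", i, seq_len(na)) else character(),
           B = if ((nb <- sample(0:3, 1)) > 0) sprintf("b%d_%d", i, seq_len(nb)) else character())
    })
    tab <- data.frame(
      orthogroup = sprintf("OG%02d", seq_len(n_og)),
      A = vapply(mem, function(m) paste(m$A, collapse = ", "), character(1)),
      B = vapply(mem, function(m) paste(m$B, collapse = ", "), character(1)),
      stringsAsFactors = FALSE
    )
    pairs <- expand_ortholog_pairs(tab, "A", "B")
    # independent oracle: nested loops over the original member lists
    expected <- NULL
    for (i in seq_len(n_og))
      for (ga in mem[[i]]$A) for (gb in mem[[i]]$B)
        expected <- rbind(expected, data.frame(gene_a = ga, gene_b = gb))
    n_expected <- sum(vapply(mem, function(m) length(m$A) * length(m$B), numeric(1)))
    expect_equal(nrow(pairs), n_expected)
    if (n_expected > 0) {
      key <- function(d) sort(paste(d$gene_a, d$gene_b))
      expect_equal(key(pairs), key(expected))
    }
    # |pairs| >= orthogroups shared by the pair; equal iff all shared are 1-1
    shared <- vapply(mem, function(m) length(m$A) > 0 && length(m$B) > 0, logical(1))
    expect_gte(nrow(pairs), sum(shared))
    if (all(vapply(mem[shared], function(m)
      length(m$A) == 1 && length(m$B) == 1, logical(1))))
      expect_equal(nrow(pairs), sum(shared))
  }
})
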