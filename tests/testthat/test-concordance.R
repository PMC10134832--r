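# chain DAG with IC: root 0 bits, mid 2 bits, leaf ~3.8 bits (bin 3)
chainIC <- function() {
  computeICTable(c("GO:0000001" = 1000, "GO:0000002" = 250,
                   "GO:0000003" = 70), 1000)
}

test_that("IC histogram floors IC into integer bins with an unbinned bucket", {
  dag <- chainDag()
  # a term with IC 3.7 lands in bin 3
  ict <- computeICTable(c("GO:0000001" = 10000, "GO:0000002" = 5000,
                          "GO:0000003" = 770), 10000)
  h <- icHistogram(quickAnnots("g1", "GO:0000003"), ict, dag)
  expect_equal(h$gene_term_pairs[h$bin == "3"], 1L)
  # propagation adds the ancestors' bins
  expect_equal(h$gene_term_pairs[h$bin == "0"], 1L)
  expect_equal(sum(h$gene_term_pairs), 3L)
  # empty annotations -> empty histogram
  expect_equal(nrow(icHistogram(annotationSet(), ict, dag)), 0L)
  # term absent from the IC table lands in "unbinned"
  partial <- computeICTable(c("GO:0000001" = 10000, "GO:0000002" = 5000),
                            10000)
  h2 <- icHistogram(quickAnnots("g1", "GO:0000003"), partial, dag)
  expect_equal(h2$gene_term_pairs[h2$bin == "unbinned"], 1L)
})

test_that("IC histogram matches a brute-force tally on a random fixture", {
  dag <- toyDag20()
  set.seed(61)
  cnt <- propagatedCounts(dag)
  ict <- computeICTable(cnt, max(cnt) * 4)
  rec <- data.frame(gene_id = paste0("g", sample(1:30, 80, TRUE)),
                    term = sample(goIds(dag), 80, TRUE),
                    score = 1, method = "m")
  a <- annotationSet(rec)
  h <- icHistogram(a, ict, dag)
  # oracle: per-gene DFS closure, floor(ic), table
  r <- annotationRecords(a)
  icv <- icValues(ict)
  tally <- c()
  for (g in unique(r$gene_id)) {
    up <- dfsAncestors(goParents(dag), r$term[r$gene_id == g])
    tally <- c(tally, as.character(floor(icv[up])))
  }
  oracle <- table(tally)
  expect_equal(setNames(h$gene_term_pairs, h$bin),
               setNames(as.integer(oracle), names(oracle))[h$bin])
})

test_that("concordance of a set with itself is total in every bin", {
  dag <- chainDag(); ict <- chainIC()
  a <- annotationSet(data.frame(
    gene_id = paste0("g", 1:10),
    term = rep(c("GO:0000003", "GO:0000002"), 5),
    score = 1, method = "m"))
  res <- stratifyConcordance(a, a, ict, dag)
  cc <- concordanceCounts(res)
  expect_true(all(cc$discordant == 0))
  expect_true(all(cc$unique_a == 0))
  expect_true(all(cc$unique_b == 0))
  expect_true(all(cc$concordant > 0))
  tab <- concordanceTable(res)
  expect_true(all(tab$percent[tab$category == "concordant"] == 100))
})

test_that("concordance categories follow the per-bin rules", {
  dag <- new("GoDag",
             terms = c("GO:0000001", "GO:0000002", "GO:0000003"),
             termNames = setNames(c("root", "leafX", "leafY"),
                                  c("GO:0000001", "GO:0000002",
                                    "GO:0000003")),
             namespace = setNames(rep("molecular_function", 3),
                                  c("GO:0000001", "GO:0000002",
                                    "GO:0000003")),
             parents = setNames(list(character(), "GO:0000001",
                                     "GO:0000001"),
                                c("GO:0000001", "GO:0000002",
                                  "GO:0000003")))
  ict <- computeICTable(c("GO:0000001" = 1000, "GO:0000002" = 250,
                          "GO:0000003" = 250), 1000)
  # same bin (2), different terms -> discordant there, concordant at root
  res <- stratifyConcordance(quickAnnots("g1", "GO:0000002"),
                             quickAnnots("g1", "GO:0000003"), ict, dag)
  cc <- concordanceCounts(res)
  expect_equal(cc$discordant[cc$bin == 2], 1L)
  expect_equal(cc$concordant[cc$bin == 0], 1L)
  # under the loose both_present rule the same pair is concordant
  loose <- stratifyConcordance(quickAnnots("g1", "GO:0000002"),
                               quickAnnots("g1", "GO:0000003"), ict, dag,
                               rule = "both_present")
  expect_equal(concordanceCounts(loose)$discordant,
               c(0L, 0L))
  # empty b -> everything unique to a
  res2 <- stratifyConcordance(quickAnnots("g1", "GO:0000002"),
                              annotationSet(), ict, dag)
  cc2 <- concordanceCounts(res2)
  expect_true(all(cc2$unique_a == 1L))
  expect_true(all(cc2$concordant + cc2$discordant + cc2$unique_b == 0L))
})

test_that("concordance is symmetric and partitions each bin's gene universe", {
  dag <- toyDag20()
  set.seed(62)
  cnt <- propagatedCounts(dag)
  ict <- computeICTable(cnt, max(cnt) * 4)
  mkset <- function(n) annotationSet(data.frame(
    gene_id = paste0("g", sample(1:25, n, TRUE)),
    term = sample(goIds(dag), n, TRUE), score = 1, method = "m"))
  a <- mkset(50); b <- mkset(35)
  ab <- concordanceCounts(stratifyConcordance(a, b, ict, dag))
  ba <- concordanceCounts(stratifyConcordance(b, a, ict, dag))
  expect_equal(ab$concordant, ba$concordant)
  expect_equal(ab$discordant, ba$discordant)
  expect_equal(ab$unique_a, ba$unique_b)
  expect_equal(ab$unique_b, ba$unique_a)
  # partition: per-bin category sum equals the count of genes having >= 1
  # term of that bin from either method (computed by brute force)
  icv <- icValues(ict)
  bins_of_gene <- function(set, g) {
    r <- annotationRecords(set)
    t <- r$term[r$gene_id == g]
    if (!length(t)) return(integer())
    unique(floor(icv[dfsAncestors(goParents(dag), t)]))
  }
  genes <- union(annotatedGenes(a), annotatedGenes(b))
  for (i in seq_len(nrow(ab))) {
    L <- ab$bin[i]
    n_genes <- sum(vapply(genes, function(g)
      L %in% c(bins_of_gene(a, g), bins_of_gene(b, g)), logical(1)))
    expect_equal(ab$concordant[i] + ab$discordant[i] + ab$unique_a[i] +
                   ab$unique_b[i], n_genes)
  }
})

test_that("Venn regions are exact and satisfy inclusion-exclusion", {
  v <- annotationVenn(list(A = c("1", "2", "3"), B = c("3", "4")))
  cnt <- setNames(v$count, v$region)
  expect_equal(unname(cnt["A"]), 2L)
  expect_equal(unname(cnt["B"]), 1L)
  expect_equal(unname(cnt["A&B"]), 1L)
  # disjoint sets
  d <- annotationVenn(list(A = "1", B = "2"))
  expect_equal(d$count[d$region == "A&B"], 0L)
  expect_error(annotationVenn(list(1:2, 2:3, 3:4, 4:5)), "2- or 3-way")
})

test_that("3-way Venn matches exhaustive membership enumeration", {
  set.seed(63)
  pool <- paste0("g", 1:60)
  sets <- list(A = sample(pool, 30), B = sample(pool, 25),
               C = sample(pool, 20))
  v <- annotationVenn(sets)
  expect_equal(nrow(v), 7L)
  cnt <- setNames(v$count, v$region)
  # oracle: classify every pool element by its membership pattern
  for (reg in names(cnt)) {
    members <- strsplit(reg, "&", fixed = TRUE)[[1]]
    expected <- sum(vapply(pool, function(g) {
      inside <- vapply(sets, function(s) g %in% s, logical(1))
      setequal(names(sets)[inside], members)
    }, logical(1)))
    expect_equal(unname(cnt[reg]), expected)
  }
  # inclusion-exclusion: each input size is the sum of its regions
  for (lab in names(sets)) {
    regs <- v$region[vapply(strsplit(v$region, "&", fixed = TRUE),
                            function(m) lab %in% m, logical(1))]
    expect_equal(sum(cnt[regs]), length(sets[[lab]]))
  }
})
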