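# Shared fixtures and independent oracles, built in code.

# three-term is_a chain: leaf -> mid -> root
chainDag <- function() {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003")
  new("GoDag", terms = ids,
      termNames = setNames(c("root", "mid", "leaf"), ids),
      namespace = setNames(rep("molecular_function", 3), ids),
      parents = setNames(list(character(), "GO:0000001", "GO:0000002"),
                         ids))
}

# deterministic 20-term DAG: term i picks 1-2 parents among earlier terms
toyDag20 <- function() {
  set.seed(2025)
  ids <- sprintf("GO:%07d", 1:20)
  parents <- vector("list", 20)
  parents[[1]] <- character()
  for (i in 2:20) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[i]] <- ids[sample(i - 1, k)]
  }
  names(parents) <- ids
  new("GoDag", terms = ids,
      termNames = setNames(paste("toy term", 1:20), ids),
      namespace = setNames(rep("molecular_function", 20), ids),
      parents = parents)
}

# exhaustive recursive-DFS ancestor closure, independent of propagateUp
dfsAncestors <- function(parents, terms) {
  seen <- character()
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (p in parents[[t]]) visit(p)
  }
  for (t in terms) visit(t)
  seen
}

# brute-force informative-term rule: test both conditions for every term
bruteInformative <- function(dag, counts, k) {
  cnt <- function(id) ifelse(is.na(counts[id]), 0, counts[id])
  parents <- goParents(dag)
  isAncestor <- function(a, d) a %in% setdiff(dfsAncestors(parents, d), d)
  Filter(function(t) {
    if (cnt(t) <= k) return(FALSE)
    desc <- Filter(function(d) isAncestor(t, d), goIds(dag))
    all(cnt(desc) < k)
  }, goIds(dag))
}

# propagated (max-over-descendants-consistent) random counts for a DAG:
# start from random leaf-ish counts and push maxima upward
propagatedCounts <- function(dag, max_count = 5000) {
  ids <- goIds(dag)
  cnt <- setNames(sample.int(max_count, length(ids), replace = TRUE), ids)
  parents <- goParents(dag)
  # iterate to fixpoint: parent >= child
  repeat {
    changed <- FALSE
    for (id in ids) for (p in parents[[id]]) {
      if (cnt[p] < cnt[id]) { cnt[p] <- cnt[id]; changed <- TRUE }
    }
    if (!changed) break
  }
  cnt
}

quickAnnots <- function(gene, term, score = 1, method = "m") {
  annotationSet(data.frame(gene_id = gene, term = term, score = score,
                           method = method))
}

# small MagSet built directly
makeMagSet <- function(info, contigs) {
  base <- data.frame(mag_id = info$mag_id,
                     sample_id = info$sample_id %||% "S1",
                     completeness = info$completeness,
                     contamination = info$contamination)
  for (r in c("domain", "phylum", "class", "order", "family", "genus",
              "species"))
    base[[r]] <- if (!is.null(info[[r]])) info[[r]] else ""
  new("MagSet", info = base, contigs = contigs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook sum-formula Pearson correlation
pearsonSums <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
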