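# Per-gene propagated, IC-binned term sets: list(gene -> named integer
# vector term -> bin). Terms without an IC value go to the "unbinned"
# bucket and are excluded from binned comparisons.
.binnedTermSets <- function(annots, ic, dag) {
  r <- annotationRecords(annots)
  if (!nrow(r)) return(list(sets = list(), unbinned = character()))
  icv <- icValues(ic)
  per_gene <- split(r$term, r$gene_id)
  unbinned <- character()
  sets <- lapply(per_gene, function(terms) {
    up <- propagateUp(dag, unique(terms))
    known <- up[up %in% names(icv)]
    unbinned <<- union(unbinned, setdiff(up, known))
    stats::setNames(as.integer(floor(icv[known])), known)
  })
  list(sets = sets, unbinned = unbinned)
}

#' Histogram of annotation information content
#'
#' Propagates each gene's terms upward and counts (gene, term) pairs per
#' integer IC bin (bin = floor(IC)). Because the reference presentation
#' does not state whether the unit is genes or gene-term pairs, both
#' tallies are returned; terms lacking an IC value land in the "unbinned"
#' row.
#'
#' @param annots an [AnnotationSet-class].
#' @param ic an [ICTable-class].
#' @param dag a [GoDag-class].
#' @return data.frame with columns `bin` (character; integer bins plus
#'   possibly `"unbinned"`), `gene_term_pairs`, `genes`.
#' @export
icHistogram <- function(annots, ic, dag) {
  r <- annotationRecords(annots)
  empty <- data.frame(bin = character(), gene_term_pairs = integer(),
                      genes = integer())
  if (!nrow(r)) return(empty)
  icv <- icValues(ic)
  per_gene <- split(r$term, r$gene_id)
  pairs_bin <- character(); pairs_gene <- character()
  for (g in names(per_gene)) {
    up <- propagateUp(dag, unique(per_gene[[g]]))
    bin <- ifelse(up %in% names(icv),
                  as.character(floor(icv[up])), "unbinned")
    pairs_bin <- c(pairs_bin, bin)
    pairs_gene <- c(pairs_gene, rep(g, length(bin)))
  }
  tab <- table(pairs_bin)
  genes <- tapply(pairs_gene, pairs_bin, function(x) length(unique(x)))
  out <- data.frame(bin = names(tab),
                    gene_term_pairs = as.integer(tab),
                    genes = as.integer(genes[names(tab)]))
  num <- suppressWarnings(as.numeric(out$bin))
  out <- out[order(is.na(num), num), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify inter-method agreement by information-content level
#'
#' For every gene annotated by either method and every integer IC bin
#' (floor of the term's IC), the two methods' propagated term sets
#' restricted to the bin are compared: with both non-empty the gene is
#' concordant in that bin when the sets share at least one term (default
#' `shared_term` rule) and discordant otherwise; with only one method
#' present the gene is unique to it. Under the looser `both_present` rule
#' any two non-empty sets count as concordant. Terms without IC values are
#' ignored here (see [icHistogram()] for their tally).
#'
#' @param a,b [AnnotationSet-class] objects for the two methods (same GO
#'   branch; terms must live in `dag`, otherwise a branch-mismatch error is
#'   raised by propagation).
#' @param ic an [ICTable-class].
#' @param dag a [GoDag-class].
#' @param labels length-2 character vector of method labels.
#' @param rule `"shared_term"` or `"both_present"`.
#' @return a [ConcordanceResult-class].
#' @export
stratifyConcordance <- function(a, b, ic, dag,
                                labels = c("a", "b"),
                                rule = c("shared_term", "both_present")) {
  rule <- match.arg(rule)
  sa <- .binnedTermSets(a, ic, dag)$sets
  sb <- .binnedTermSets(b, ic, dag)$sets
  genes <- union(names(sa), names(sb))
  acc <- new.env(parent = emptyenv())
  bump <- function(bin, cat) {
    key <- as.character(bin)
    cur <- if (!is.null(acc[[key]])) acc[[key]] else
      c(concordant = 0L, discordant = 0L, unique_a = 0L, unique_b = 0L)
    cur[[cat]] <- cur[[cat]] + 1L
    acc[[key]] <- cur
  }
  for (g in genes) {
    ta <- sa[[g]]; tb <- sb[[g]]
    bins <- union(unique(ta), unique(tb))
    for (L in bins) {
      A <- names(ta)[ta == L]
      B <- names(tb)[tb == L]
      if (length(A) && length(B)) {
        hit <- if (rule == "both_present") TRUE else
          length(intersect(A, B)) > 0L
        bump(L, if (hit) "concordant" else "discordant")
      } else if (length(A)) bump(L, "unique_a")
      else bump(L, "unique_b")
    }
  }
  bins <- sort(as.integer(ls(acc)))
  counts <- do.call(rbind, lapply(as.character(bins), function(k)
    as.data.frame(as.list(acc[[k]]))))
  counts <- if (length(bins)) cbind(data.frame(bin = bins), counts) else
    data.frame(bin = integer(), concordant = integer(),
               discordant = integer(), unique_a = integer(),
               unique_b = integer())
  rownames(counts) <- NULL
  new("ConcordanceResult", counts = counts, labels = labels, rule = rule)
}

#' Tidy concordance table with per-bin percentages
#'
#' @param result a [ConcordanceResult-class].
#' @return data.frame with columns bin, category, count, percent (percent
#'   of the bin's gene total).
#' @export
concordanceTable <- function(result) {
  cc <- concordanceCounts(result)
  cats <- c("concordant", "discordant", "unique_a", "unique_b")
  long <- data.frame(
    bin = rep(cc$bin, each = length(cats)),
    category = rep(cats, times = nrow(cc)),
    count = as.vector(t(as.matrix(cc[cats]))))
  tot <- rowSums(cc[cats])
  long$percent <- 100 * long$count / rep(tot, each = length(cats))
  long
}

#' Mean per-bin concordant percentage
#'
#' The average over occupied IC bins of the concordant share among genes
#' annotated by both methods in the bin (concordant / (concordant +
#' discordant)); bins where no gene is doubly annotated are skipped.
#'
#' @param result a [ConcordanceResult-class].
#' @param bins optional integer vector restricting the bins averaged over.
#' @return a single percentage.
#' @export
meanConcordance <- function(result, bins = NULL) {
  cc <- concordanceCounts(result)
  if (!is.null(bins)) cc <- cc[cc$bin %in% bins, , drop = FALSE]
  both <- cc$concordant + cc$discordant
  cc <- cc[both > 0, , drop = FALSE]
  if (!nrow(cc)) return(NA_real_)
  mean(100 * cc$concordant / (cc$concordant + cc$discordant))
}

#' Venn region counts for 2 or 3 gene sets
#'
#' Exact cardinalities of the disjoint regions of a 2-way (3 regions) or
#' 3-way (7 regions) set comparison. Region names are the participating
#' labels joined by `&`.
#'
#' @param sets list of 2 or 3 character vectors (gene ids).
#' @param labels labels for the sets (default names of `sets` or A/B/C).
#' @return data.frame with columns `region` and `count`; regions are
#'   disjoint and reproduce each input set's size by inclusion-exclusion.
#' @export
annotationVenn <- function(sets, labels = NULL) {
  k <- length(sets)
  if (!k %in% 2:3) stop("only 2- or 3-way comparisons are supported")
  if (is.null(labels))
    labels <- if (!is.null(names(sets)) && all(nzchar(names(sets))))
      names(sets) else LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L)
  pattern <- apply(memb, 1L, function(row)
    paste(labels[row], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&", simplify = FALSE)))
  cnt <- table(factor(pattern, levels = combos))
  data.frame(region = names(cnt), count = as.integer(cnt))
}
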