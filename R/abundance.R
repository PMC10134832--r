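#' Construct a GeneCounts object
#'
#' @param sample_id sample identifier.
#' @param counts named numeric vector of mapped read counts.
#' @param lengths named numeric vector of template lengths (bp), matching
#'   `counts` by name.
#' @param total_reads total quality-controlled reads in the sample; when
#'   NA, the mapped-count sum stands in as denominator for `paper_raw`
#'   normalization (with a message at that point).
#' @return a [GeneCounts-class].
#' @export
geneCounts <- function(sample_id, counts, lengths, total_reads = NA_real_) {
  if (is.null(names(counts))) stop("counts must be named by gene id")
  lengths <- lengths[names(counts)]
  new("GeneCounts", sampleId = sample_id, counts = as.numeric(counts) |>
        stats::setNames(names(counts)),
      lengths = as.numeric(lengths) |> stats::setNames(names(counts)),
      totalReads = as.numeric(total_reads))
}

#' Read a KMA-style per-sample alignment result table
#'
#' Header-driven TSV reader for `.res`-like files: a template (gene) name
#' column, a template length column, and a mapped-read count column. Genes
#' of the catalogue absent from the file get count 0; a duplicated template
#' row is an error naming the gene.
#'
#' @param file path.
#' @param sample_id sample identifier to stamp on the result.
#' @param genes optional character vector of catalogue gene ids to align
#'   the count vector to (absent genes -> 0).
#' @param total_reads optional total read count of the sample.
#' @param template_col,length_col,count_col header names (defaults
#'   `"#Template"`, `"Template_length"`, `"readCount"`).
#' @return a [GeneCounts-class].
#' @export
readAlignmentCounts <- function(file, sample_id, genes = NULL,
                                total_reads = NA_real_,
                                template_col = "#Template",
                                length_col = "Template_length",
                                count_col = "readCount") {
  x <- utils::read.delim(file, check.names = FALSE,
                         comment.char = "")
  for (col in c(template_col, length_col, count_col))
    if (!col %in% names(x))
      stop("column '", col, "' not found in ", file)
  tmpl <- as.character(x[[template_col]])
  if (anyDuplicated(tmpl))
    stop("duplicated template row for gene ", tmpl[duplicated(tmpl)][1])
  cnt <- as.numeric(x[[count_col]])
  if (any(cnt < 0)) stop("negative read count for gene ",
                         tmpl[cnt < 0][1])
  len <- as.numeric(x[[length_col]])
  counts <- stats::setNames(cnt, tmpl)
  lengths <- stats::setNames(len, tmpl)
  if (!is.null(genes)) {
    missing <- setdiff(genes, tmpl)
    counts <- c(counts, stats::setNames(rep(0, length(missing)), missing))
    # unit length placeholder: weight is 0 anyway at count 0
    lengths <- c(lengths, stats::setNames(rep(1, length(missing)), missing))
    counts <- counts[genes]
    lengths <- lengths[genes]
  }
  geneCounts(sample_id, counts, lengths, total_reads)
}

#' Normalize read counts to copies per million
#'
#' Two modes are provided because the reference workflow describes both:
#' \describe{
#'   \item{`length_rescaled` (default)}{counts are first divided by the
#'     template length (copies), then rescaled so each sample sums to
#'     1e6: cpm_g = (c_g/L_g) * 1e6 / sum_h(c_h/L_h). Scale-invariant in
#'     the counts.}
#'   \item{`paper_raw`}{the literal printed formula
#'     cpm_g = c_g * 1e6 / total_reads; the sample row sums to 1e6 times
#'     the mapped fraction.}
#' }
#'
#' @param x a [GeneCounts-class] or a list of them (one per sample); all
#'   samples must cover the same gene universe.
#' @param mode `"length_rescaled"` or `"paper_raw"`.
#' @return an [AbundanceTable-class] (samples x genes).
#' @export
cpmNormalize <- function(x, mode = c("length_rescaled", "paper_raw")) {
  mode <- match.arg(mode)
  if (is(x, "GeneCounts")) x <- list(x)
  genes <- names(readCounts(x[[1]]))
  rows <- lapply(x, function(gc) {
    cnt <- readCounts(gc)
    if (!setequal(names(cnt), genes))
      stop("samples cover different gene universes")
    cnt <- cnt[genes]
    if (mode == "paper_raw") {
      tot <- totalReads(gc)
      if (is.na(tot)) {
        tot <- sum(cnt)
        message("sample ", sampleId(gc),
                ": totalReads unknown, using mapped-count sum")
      }
      if (tot <= 0) stop("sample ", sampleId(gc),
                         ": zero total reads (CPM undefined)")
      cnt * 1e6 / tot
    } else {
      w <- cnt / templateLengths(gc)[genes]
      s <- sum(w)
      if (s <= 0) stop("sample ", sampleId(gc),
                       ": all counts zero (CPM undefined)")
      w * 1e6 / s
    }
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(x, sampleId, ""), genes)
  new("AbundanceTable", cpm = m, mode = mode)
}

#' Aggregate gene abundances per GO term
#'
#' entry(term, sample) = sum of CPM over genes carrying the term. A gene
#' annotated with several terms contributes its full CPM to each of them
#' (no fractional splitting), so the column totals can exceed the
#' annotated-gene CPM total.
#'
#' @param abund an [AbundanceTable-class].
#' @param annots an [AnnotationSet-class]; must carry a single method, or
#'   pass `method` to select one.
#' @param method optional method label to restrict to.
#' @return numeric matrix, terms x samples.
#' @export
functionAbundance <- function(abund, annots, method = NULL) {
  r <- annotationRecords(annots)
  if (!is.null(method)) r <- r[r$method %in% method, , drop = FALSE]
  if (length(unique(r$method)) > 1L)
    stop("annotations span several methods; pass method= to select one")
  cpm <- cpmMatrix(abund)
  r <- unique(r[c("gene_id", "term")])
  r <- r[r$gene_id %in% colnames(cpm), , drop = FALSE]
  terms <- sort(unique(r$term))
  out <- matrix(0, nrow = length(terms), ncol = nrow(cpm),
                dimnames = list(terms, rownames(cpm)))
  if (nrow(r)) {
    sp <- split(r$gene_id, r$term)
    for (t in names(sp))
      out[t, ] <- rowSums(cpm[, sp[[t]], drop = FALSE])
  }
  out
}

#' Percent of sample abundance carried by annotated genes
#'
#' For each sample, 100 * (CPM on annotated genes) / (total CPM). With a
#' zero total the value is undefined and reported as NA.
#'
#' @param abund an [AbundanceTable-class].
#' @param annotated_genes character vector of annotated gene ids, or a
#'   named list of such vectors (one per method).
#' @return named numeric vector (percent per sample), or a matrix
#'   methods x samples when a list is given.
#' @export
annotatedFraction <- function(abund, annotated_genes) {
  if (is.list(annotated_genes)) {
    rows <- lapply(annotated_genes, function(g)
      annotatedFraction(abund, g))
    m <- do.call(rbind, rows)
    rownames(m) <- names(annotated_genes)
    return(m)
  }
  cpm <- cpmMatrix(abund)
  tot <- rowSums(cpm)
  ann <- rowSums(cpm[, intersect(annotated_genes, colnames(cpm)),
                     drop = FALSE])
  out <- ifelse(tot > 0, 100 * ann / tot, NA_real_)
  stats::setNames(out, rownames(cpm))
}

#' Write an abundance table as wide and long TSV
#'
#' @param abund an [AbundanceTable-class].
#' @param wide_file,long_file output paths (NULL to skip either).
#' @return invisibly, the paths written.
#' @export
writeAbundanceTable <- function(abund, wide_file = NULL, long_file = NULL) {
  cpm <- cpmMatrix(abund)
  if (!is.null(wide_file)) {
    wide <- data.frame(gene_id = colnames(cpm), t(cpm), check.names = FALSE)
    utils::write.table(wide, wide_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(long_file)) {
    long <- data.frame(
      sample_id = rep(rownames(cpm), times = ncol(cpm)),
      gene_id = rep(colnames(cpm), each = nrow(cpm)),
      cpm = as.vector(cpm))
    utils::write.table(long, long_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(wide_file, long_file))
}
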