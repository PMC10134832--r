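#' Construct an AnnotationSet
#'
#' @param records data.frame with columns gene_id, term, score, method.
#'   Duplicate (gene, term, method) rows are collapsed keeping the maximum
#'   score.
#' @param descriptions named character vector (gene_id -> free text).
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(records = data.frame(gene_id = character(),
                                               term = character(),
                                               score = numeric(),
                                               method = character()),
                          descriptions = character()) {
  records <- as.data.frame(records)[c("gene_id", "term", "score", "method")]
  if (nrow(records)) {
    o <- order(records$gene_id, records$term, records$method, -records$score)
    records <- records[o, , drop = FALSE]
    dup <- duplicated(records[c("gene_id", "term", "method")])
    records <- records[!dup, , drop = FALSE]
    rownames(records) <- NULL
  }
  if (length(descriptions))
    descriptions <- descriptions[nzchar(descriptions)]
  new("AnnotationSet", records = records, descriptions = descriptions)
}

# Guess the field separator of a small delimited file: tab wins if present
# in the first data line, else comma.
.sniffDelim <- function(lines) {
  if (!length(lines)) return("\t")
  if (grepl("\t", lines[1], fixed = TRUE)) "\t"
  else if (grepl(",", lines[1], fixed = TRUE)) ","
  else stop("cannot determine delimiter (neither tab nor comma found)")
}

#' Read a structure-based per-gene GO prediction table
#'
#' Consumes DeepFRI-style prediction tables: columns gene id, GO term,
#' confidence score and (optionally) term name, comma- or tab-delimited,
#' with or without a header. Rows at or above the active score threshold
#' are retained (score >= threshold); the reference thresholds are 0.2
#' (standard quality) and 0.5 (high quality). The number of sub-threshold
#' rows dropped is reported via a message.
#'
#' @param file path, or character vector of lines.
#' @param threshold active score cutoff in [0,1] (default 0.2).
#' @param method method label stamped on the records.
#' @return an [AnnotationSet-class].
#' @export
readStructurePredictionTable <- function(file, threshold = 0.2,
                                         method = "deepfri") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(annotationSet())
  delim <- .sniffDelim(lines)
  cells <- strsplit(lines, delim, fixed = TRUE)
  # header detection: third field of the first row not parseable as number
  first_score <- suppressWarnings(as.numeric(cells[[1]][3]))
  has_header <- is.na(first_score)
  if (has_header) { cells <- cells[-1]; lines <- lines[-1] }
  if (!length(cells)) return(annotationSet())
  nf <- lengths(cells)
  if (any(nf < 3))
    stop("row ", which(nf < 3)[1] + has_header, ": expected >= 3 fields")
  gene <- vapply(cells, `[`, "", 1L)
  term <- vapply(cells, `[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(cells, `[`, "", 3L)))
  if (anyNA(score))
    stop("row ", which(is.na(score))[1] + has_header,
         ": unparseable score '", vapply(cells, `[`, "", 3L)[is.na(score)][1],
         "'")
  keep <- score >= threshold
  if (any(!keep))
    message(sum(!keep), " prediction(s) below score threshold ", threshold,
            " dropped")
  annotationSet(data.frame(gene_id = gene[keep], term = term[keep],
                           score = score[keep], method = method))
}

#' Read an orthology-mapper annotation table
#'
#' Consumes eggNOG-mapper style `.annotations` TSVs: lines starting with
#' `#` are comments (the last such line may carry the column header, e.g.
#' `#query_name ... GOs ... Description`). The GO column holds
#' comma-separated accessions which are exploded into one record per term
#' with score 1.0; `-` or an empty field means no GO annotation. The
#' free-text description column is captured per gene; a gene with a
#' description but no GO terms is retained as description-annotated.
#'
#' @param file path, or character vector of lines.
#' @param go_col GO column, by header name (default `"GOs"`) or 1-based
#'   index when no header is present.
#' @param desc_col description column name or index (default
#'   `"Description"`).
#' @param method method label stamped on the records.
#' @return an [AnnotationSet-class].
#' @export
readOrthologyTable <- function(file, go_col = "GOs",
                               desc_col = "Description",
                               method = "eggnog") {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file, warn = FALSE) else file
  comment <- startsWith(lines, "#")
  header <- NULL
  if (any(comment)) {
    hline <- lines[comment][sum(comment)]
    header <- strsplit(sub("^#", "", hline), "\t", fixed = TRUE)[[1]]
  }
  body <- lines[!comment & nzchar(trimws(lines))]
  resolve <- function(col, what) {
    if (is.numeric(col)) return(as.integer(col))
    if (is.null(header) || !col %in% header)
      stop("missing ", what, " column '", col,
           "' (expected in a '#'-prefixed header line)")
    match(col, header)
  }
  gi <- resolve(go_col, "GO")
  di <- resolve(desc_col, "description")
  if (!length(body)) return(annotationSet())
  cells <- strsplit(body, "\t", fixed = TRUE)
  gene <- vapply(cells, `[`, "", 1L)
  gos <- vapply(cells, function(x) if (gi <= length(x)) x[gi] else "", "")
  desc <- vapply(cells, function(x) if (di <= length(x)) x[di] else "", "")
  absent <- gos %in% c("", "-")
  golist <- strsplit(ifelse(absent, "", gos), ",", fixed = TRUE)
  rec <- data.frame(
    gene_id = rep.int(gene, lengths(golist)),
    term = unlist(golist, use.names = FALSE),
    score = 1.0, method = method)
  desc[desc == "-"] <- ""
  dd <- stats::setNames(desc, gene)
  annotationSet(rec, descriptions = dd[nzchar(dd)])
}

#' Write / read the canonical long-format annotation table
#'
#' Long TSV with columns gene_id, term, score, method; descriptions are
#' not carried by this format.
#'
#' @param annots an [AnnotationSet-class].
#' @param file path.
#' @return `writeAnnotationTable` returns the path invisibly;
#'   `readAnnotationTable` returns an [AnnotationSet-class].
#' @export
writeAnnotationTable <- function(annots, file) {
  utils::write.table(annotationRecords(annots), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAnnotationTable
#' @export
readAnnotationTable <- function(file) {
  x <- utils::read.delim(file, sep = "\t",
                         colClasses = c(gene_id = "character",
                                        term = "character",
                                        score = "numeric",
                                        method = "character"))
  annotationSet(x)
}

#' Restrict annotations to an informative term set
#'
#' Each gene's term set is propagated upward through the DAG and
#' intersected with the informative set; the gene's records are replaced by
#' the informative ancestors reached (annotation of a specific term is
#' projected onto the informative antichain). Genes whose closure misses
#' the informative set entirely are dropped. Each projected record carries
#' the maximum score among the gene's records whose closure reaches that
#' informative term, per method.
#'
#' @param annots an [AnnotationSet-class].
#' @param informative character vector of informative term ids (an
#'   antichain over `dag`).
#' @param dag a [GoDag-class].
#' @return an [AnnotationSet-class] whose terms are all informative.
#' @export
filterInformative <- function(annots, informative, dag) {
  r <- annotationRecords(annots)
  if (!nrow(r))
    return(annotationSet(descriptions = annotationDescriptions(annots)))
  up <- lapply(unique(r$term), function(t)
    intersect(propagateUp(dag, t), informative))
  names(up) <- unique(r$term)
  hits <- up[r$term]
  n <- lengths(hits)
  out <- data.frame(
    gene_id = as.character(rep.int(r$gene_id, n)),
    term = as.character(unlist(hits, use.names = FALSE)),
    score = as.numeric(rep.int(r$score, n)),
    method = as.character(rep.int(r$method, n)))
  annotationSet(out, descriptions = annotationDescriptions(annots))
}

#' Subset an AnnotationSet by method
#'
#' @param annots an [AnnotationSet-class].
#' @param method method label(s) to keep.
#' @return an [AnnotationSet-class].
#' @export
subsetByMethod <- function(annots, method) {
  r <- annotationRecords(annots)
  annotationSet(r[r$method %in% method, , drop = FALSE],
                descriptions = annotationDescriptions(annots))
}
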