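#' Parse an OBO-format ontology into a GoDag
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and builds the GO DAG over `is_a`
#' edges. Obsolete terms are dropped, as are terms outside the requested
#' namespace(s); `part_of` and every other relationship type are ignored.
#' Parent references pointing outside the retained term set (dangling
#' edges, e.g. into another namespace) are pruned with a warning.
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @param namespace NULL to keep all three GO branches, or a character
#'   vector of namespaces to retain (e.g. `"molecular_function"`).
#' @return a [GoDag-class] object.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: molecular_function",
#'          "[Term]", "id: GO:0000002", "name: leaf",
#'          "namespace: molecular_function", "is_a: GO:0000001 ! root")
#' dag <- parseOBO(obo)
#' @export
parseOBO <- function(file, namespace = NULL) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- sub("\r$", "", lines)

  ids <- character(); nms <- character(); nss <- character()
  pars <- list(); obs <- logical()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id) || !nzchar(cur$id))
      stop("malformed OBO stanza: [Term] without an id")
    ids[[length(ids) + 1L]] <<- cur$id
    nms[[length(nms) + 1L]] <<- cur$name
    nss[[length(nss) + 1L]] <<- cur$namespace
    pars[[length(pars) + 1L]] <<- cur$parents
    obs[[length(obs) + 1L]] <<- cur$obsolete
  }
  in_term <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      if (in_term) { flush(); cur <- NULL }
      in_term <- identical(trimws(ln), "[Term]")
      if (in_term)
        cur <- list(id = NA_character_, name = "", namespace = "",
                    parents = character(), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(trimws(ln))) next
    colon <- regexpr(": ", ln, fixed = TRUE)
    if (colon < 0) next
    tag <- substr(ln, 1L, colon - 1L)
    val <- substr(ln, colon + 2L, nchar(ln))
    val <- trimws(sub("!.*$", "", val))
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  if (in_term) flush()

  keep <- !obs
  if (!is.null(namespace)) keep <- keep & nss %in% namespace
  ids <- ids[keep]; nms <- nms[keep]; nss <- nss[keep]; pars <- pars[keep]
  pars <- lapply(pars, unique)
  names(pars) <- ids

  dangling <- setdiff(unlist(pars, use.names = FALSE), ids)
  if (length(dangling)) {
    warning(length(dangling), " dangling is_a reference(s) pruned (e.g. ",
            dangling[1], ")")
    pars <- lapply(pars, function(p) p[p %in% ids])
  }
  new("GoDag", terms = ids,
      termNames = stats::setNames(nms, ids),
      namespace = stats::setNames(nss, ids),
      parents = pars)
}

#' Write a GoDag back to OBO format
#'
#' Emits one `[Term]` stanza per term with id, name, namespace and `is_a`
#' lines; parsing the result reproduces an isomorphic DAG.
#'
#' @param dag a [GoDag-class].
#' @param file output path.
#' @return invisibly, the path written.
#' @export
writeOBO <- function(dag, file) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in goIds(dag)) {
    p <- dag@parents[[id]]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag@termNames[[id]]),
                 paste0("namespace: ", dag@namespace[[id]]),
                 if (length(p)) paste0("is_a: ", p) else character(),
                 ""), con)
  }
  invisible(file)
}

#' Propagate GO terms upward through the DAG
#'
#' Returns the ancestor closure of a term set: the input terms plus every
#' term reachable through `is_a` parent edges. This makes annotations from
#' methods of different specificity comparable. The operation is idempotent
#' and its result is always a superset of the input.
#'
#' @param dag a [GoDag-class].
#' @param terms character vector of GO ids.
#' @param strict unknown ids raise an error (default); when FALSE they are
#'   dropped with a warning.
#' @return character vector: the closed term set.
#' @export
propagateUp <- function(dag, terms, strict = TRUE) {
  terms <- unique(terms)
  unknown <- setdiff(terms, dag@terms)
  if (length(unknown)) {
    if (strict)
      stop("unknown GO id(s): ", paste(utils::head(unknown, 3), collapse = ", "))
    warning(length(unknown), " unknown GO id(s) dropped")
    terms <- setdiff(terms, unknown)
  }
  out <- terms
  frontier <- terms
  while (length(frontier)) {
    up <- unique(unlist(dag@parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, out)
    out <- c(out, frontier)
  }
  out
}

# Descendant closure (proper descendants) of one term.
.descendants <- function(children, term) {
  out <- character()
  frontier <- children[[term]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(unique(unlist(children[frontier], use.names = FALSE)),
                        out)
  }
  unique(out)
}

#' Shannon information content of a GO term
#'
#' IC = -log2(n_i / n), where n_i is the number of proteins annotated with
#' the term (after upward propagation) and n the total number of annotated
#' proteins in the reference corpus. A term annotating the whole corpus has
#' IC 0; rarer terms carry more bits.
#'
#' @param n_i annotation count(s) of the term(s), each in [1, n].
#' @param n total annotated proteins, positive.
#' @return numeric, bits.
#' @examples
#' informationContent(512, 1024)  # 1 bit
#' @export
informationContent <- function(n_i, n) {
  if (any(n <= 0)) stop("corpus size n must be positive")
  if (any(n_i <= 0)) stop("term unobserved in corpus (n_i must be >= 1)")
  if (any(n_i > n)) stop("n_i exceeds corpus size n")
  -log2(n_i / n)
}

#' Build an ICTable from a propagated annotation-count corpus
#'
#' @param counts named numeric vector of propagated per-term annotation
#'   counts (terms with count 0 must be absent).
#' @param n total annotated proteins in the corpus.
#' @return an [ICTable-class].
#' @export
computeICTable <- function(counts, n) {
  if (is.null(names(counts))) stop("counts must be named by GO id")
  new("ICTable", ic = informationContent(counts, n),
      counts = counts, n = as.numeric(n))
}

#' Read a precomputed information-content table
#'
#' Two-column headerless TSV: GO id, IC in bits.
#'
#' @param file path.
#' @return an [ICTable-class] with empty counts.
#' @export
readICTable <- function(file) {
  x <- utils::read.delim(file, header = FALSE, sep = "\t",
                         col.names = c("term", "ic"),
                         colClasses = c("character", "numeric"))
  new("ICTable", ic = stats::setNames(x$ic, x$term),
      counts = stats::setNames(numeric(0), character(0)), n = NA_real_)
}

#' Read a per-term annotation-count table
#'
#' Two-column headerless TSV: GO id, propagated protein count.
#'
#' @param file path.
#' @return named numeric vector of counts.
#' @export
readTermCounts <- function(file) {
  x <- utils::read.delim(file, header = FALSE, sep = "\t",
                         col.names = c("term", "count"),
                         colClasses = c("character", "numeric"))
  stats::setNames(x$count, x$term)
}

#' Select informative GO terms by the protein-count threshold rule
#'
#' A term is informative when (i) it is associated with more than `k`
#' proteins and (ii) every proper descendant is associated with fewer than
#' `k` proteins (a missing count is 0). With the default k = 2000 this
#' picks the antichain of maximally specific, still well-populated terms.
#' A count exactly equal to `k` fails condition (i) for the term itself and
#' fails condition (ii) for the ancestor (strict inequalities both ways).
#'
#' @param dag a [GoDag-class].
#' @param counts named numeric vector of upward-propagated protein counts.
#'   Counts must be consistent with propagation (no child exceeding its
#'   parent), otherwise a validation error is raised.
#' @param k protein-count threshold (default 2000).
#' @return character vector of informative term ids (an antichain).
#' @export
informativeTerms <- function(dag, counts, k = 2000) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(names(counts))) stop("counts must be named by GO id")
  cnt <- function(id) {
    v <- counts[id]
    v[is.na(v)] <- 0
    unname(v)
  }
  for (id in dag@terms) {
    p <- dag@parents[[id]]
    if (length(p) && any(cnt(id) > cnt(p)))
      stop("counts are not propagated: ", id, " exceeds its parent ",
           p[cnt(p) < cnt(id)][1])
  }
  children <- .invertParents(dag@parents)
  candidates <- dag@terms[cnt(dag@terms) > k]
  keep <- vapply(candidates, function(id) {
    d <- .descendants(children, id)
    !length(d) || all(cnt(d) < k)
  }, logical(1))
  candidates[keep]
}
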