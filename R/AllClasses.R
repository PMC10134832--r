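#' @import methods
NULL

GO_ACCESSION_RE <- "^GO:[0-9]{7}$"
GO_NAMESPACES <- c("molecular_function", "biological_process",
                   "cellular_component")
GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
GTDB_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' GoDag: a Gene Ontology directed acyclic graph
#'
#' Holds non-obsolete GO terms of one or more namespaces with their
#' \code{is_a} parent relations. The edge relation is validated to be
#' acyclic at construction and every referenced parent must exist in the
#' term set (dangling references are pruned by [parseOBO()]).
#'
#' @slot terms character vector of GO accessions ("GO:" + 7 digits).
#' @slot termNames character vector of term names, named by accession.
#' @slot namespace character vector of namespaces, named by accession; each
#'   is one of \code{molecular_function}, \code{biological_process},
#'   \code{cellular_component}.
#' @slot parents named list mapping each accession to the character vector
#'   of its direct \code{is_a} parents (possibly empty).
#'
#' @seealso [parseOBO()], [propagateUp()], [informativeTerms()]
#' @export
setClass("GoDag", representation(
  terms = "character",
  termNames = "character",
  namespace = "character",
  parents = "list"
))

setValidity("GoDag", function(object) {
  t <- object@terms
  msgs <- character()
  if (anyDuplicated(t)) msgs <- c(msgs, "duplicated term ids")
  bad <- t[!grepl(GO_ACCESSION_RE, t)]
  if (length(bad))
    msgs <- c(msgs, paste0("malformed GO accession: ", bad[1]))
  if (!setequal(names(object@parents), t) ||
      !setequal(names(object@namespace), t) ||
      !setequal(names(object@termNames), t))
    msgs <- c(msgs, "termNames/namespace/parents must be named by terms")
  if (length(msgs)) return(msgs)
  if (!all(object@namespace %in% GO_NAMESPACES))
    msgs <- c(msgs, "namespace outside the three GO branches")
  allp <- unlist(object@parents, use.names = FALSE)
  if (length(allp) && !all(allp %in% t))
    msgs <- c(msgs, "parent referenced outside the term set")
  selfp <- vapply(t, function(x) x %in% object@parents[[x]], logical(1))
  if (any(selfp))
    msgs <- c(msgs, paste0("term is its own parent: ", t[selfp][1]))
  cyc <- .findCycleMember(object@parents)
  if (!is.null(cyc))
    msgs <- c(msgs, paste0("is_a relation is cyclic (e.g. involving ", cyc, ")"))
  if (length(msgs)) msgs else TRUE
})

# Kahn's algorithm on the child->parents relation; returns NULL when acyclic,
# otherwise one member of a cycle.
.findCycleMember <- function(parents) {
  n <- length(parents)
  if (!n) return(NULL)
  ids <- names(parents)
  outdeg <- lengths(parents)
  children <- .invertParents(parents)
  queue <- ids[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < n) ids[outdeg > 0L][1] else NULL
}

.invertParents <- function(parents) {
  children <- vector("list", length(parents))
  names(children) <- names(parents)
  child <- rep.int(names(parents), lengths(parents))
  par <- unlist(parents, use.names = FALSE)
  if (length(par)) {
    sp <- split(child, factor(par, levels = names(parents)))
    children[names(sp)] <- sp
  }
  children[vapply(children, is.null, logical(1))] <- list(character())
  children
}

#' ICTable: information content of GO terms
#'
#' Information content (IC) of term i is -log2(n_i / n): the Shannon
#' self-information of observing the term in a reference annotation corpus,
#' where n_i is the (upward-propagated) number of proteins annotated with
#' the term and n the total number of annotated proteins. High IC marks a
#' specific term; IC 0 marks a term annotating the whole corpus.
#'
#' A table may be computed from a counts corpus ([computeICTable()]) or
#' loaded precomputed ([readICTable()]), in which case \code{counts} is
#' empty and \code{n} is \code{NA}.
#'
#' @slot ic named numeric vector, bits, non-negative.
#' @slot counts named numeric vector of propagated annotation counts
#'   (possibly empty for precomputed tables).
#' @slot n total annotated proteins in the corpus (NA when unknown).
#' @export
setClass("ICTable", representation(
  ic = "numeric",
  counts = "numeric",
  n = "numeric"
))

setValidity("ICTable", function(object) {
  msgs <- character()
  if (is.null(names(object@ic)) && length(object@ic))
    msgs <- c(msgs, "ic must be named by GO id")
  if (any(object@ic < -1e-9))
    msgs <- c(msgs, "information content must be non-negative")
  if (length(object@counts)) {
    if (is.na(object@n)) msgs <- c(msgs, "counts present but n missing")
    else if (any(object@counts > object@n))
      msgs <- c(msgs, "counts exceed corpus size n")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: per-gene GO annotations from one or more methods
#'
#' @slot records data.frame with columns \code{gene_id}, \code{term},
#'   \code{score} (in [0,1]; 1.0 for orthology calls without scores) and
#'   \code{method}. (gene, term, method) triples are unique.
#' @slot descriptions named character vector of free-text functional
#'   descriptions (gene_id -> text); a gene may carry a description with no
#'   GO records.
#' @export
setClass("AnnotationSet", representation(
  records = "data.frame",
  descriptions = "character"
))

setValidity("AnnotationSet", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("gene_id", "term", "score", "method")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(r$score < 0 | r$score > 1))
      msgs <- c(msgs, "scores outside [0,1]")
    if (!all(grepl(GO_ACCESSION_RE, r$term)))
      msgs <- c(msgs, "term not matching the GO accession pattern")
    if (anyDuplicated(r[c("gene_id", "term", "method")]))
      msgs <- c(msgs, "duplicate (gene, term, method) records")
  }
  if (length(object@descriptions) && is.null(names(object@descriptions)))
    msgs <- c(msgs, "descriptions must be named by gene_id")
  if (length(msgs)) msgs else TRUE
})

#' GeneCatalogue: nonredundant gene catalogue from identity clustering
#'
#' Models the output of clustering all predicted genes at a sequence
#' identity threshold (95\% in the reference workflow): a partition of the
#' gene universe into clusters, each represented by a centroid.
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{cluster_id},
#'   \code{is_centroid} (logical) and \code{length} (amino acids; NA when
#'   unknown). Gene ids are Prodigal-style \code{<contig>_<ordinal>}.
#' @slot identityThreshold clustering identity fraction (metadata only).
#' @export
setClass("GeneCatalogue", representation(
  genes = "data.frame",
  identityThreshold = "numeric"
))

setValidity("GeneCatalogue", function(object) {
  g <- object@genes
  need <- c("gene_id", "cluster_id", "is_centroid", "length")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(g$gene_id))
    msgs <- c(msgs, paste0("gene assigned to more than one cluster: ",
                           g$gene_id[duplicated(g$gene_id)][1]))
  ncent <- tapply(g$is_centroid, g$cluster_id, sum)
  if (length(ncent) && any(ncent != 1L)) {
    badc <- names(ncent)[ncent != 1L][1]
    msgs <- c(msgs, paste0("cluster ", badc, " has ", ncent[[badc]],
                           " centroids (expected exactly 1)"))
  }
  if (any(!is.na(g$length) & g$length <= 0))
    msgs <- c(msgs, "gene length must be positive")
  if (length(msgs)) msgs else TRUE
})

#' MagSet: metagenome-assembled genomes with quality and taxonomy
#'
#' @slot info data.frame with columns \code{mag_id}, \code{sample_id},
#'   \code{completeness}, \code{contamination} and the seven GTDB ranks
#'   (\code{domain} .. \code{species}, empty string = unassigned).
#' @slot contigs named list (mag_id -> character vector of contig ids).
#'   Contig sets of distinct MAGs are disjoint.
#' @export
setClass("MagSet", representation(
  info = "data.frame",
  contigs = "list"
))

setValidity("MagSet", function(object) {
  info <- object@info
  need <- c("mag_id", "sample_id", "completeness", "contamination",
            GTDB_RANKS)
  if (!all(need %in% names(info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(info$mag_id)) msgs <- c(msgs, "duplicated mag_id")
  if (!setequal(names(object@contigs), info$mag_id))
    msgs <- c(msgs, "contigs list must be named by mag_id")
  if (any(info$completeness < 0 | info$completeness > 100, na.rm = TRUE))
    msgs <- c(msgs, "completeness outside [0,100]")
  if (any(info$contamination < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative contamination")
  if (any(lengths(object@contigs) == 0L))
    msgs <- c(msgs, "MAG with empty contig set")
  allc <- unlist(object@contigs, use.names = FALSE)
  if (anyDuplicated(allc))
    msgs <- c(msgs, paste0("contig claimed by two MAGs: ",
                           allc[duplicated(allc)][1]))
  if (length(msgs)) msgs else TRUE
})

#' GeneCounts: per-sample mapped read counts against the gene catalogue
#'
#' @slot sampleId sample identifier.
#' @slot counts named numeric vector of mapped read counts per gene.
#' @slot lengths named numeric vector of template lengths (bp), parallel
#'   to counts.
#' @slot totalReads total quality-controlled reads in the sample (NA when
#'   unknown; then the mapped sum is used as denominator with a caveat).
#' @export
setClass("GeneCounts", representation(
  sampleId = "character",
  counts = "numeric",
  lengths = "numeric",
  totalReads = "numeric"
))

setValidity("GeneCounts", function(object) {
  msgs <- character()
  if (any(object@counts < 0)) msgs <- c(msgs, "negative read count")
  if (!identical(names(object@counts), names(object@lengths)))
    msgs <- c(msgs, "counts and lengths must share gene names")
  if (any(object@lengths <= 0, na.rm = TRUE))
    msgs <- c(msgs, "non-positive template length")
  if (!is.na(object@totalReads) &&
      sum(object@counts) > object@totalReads + 1e-6)
    msgs <- c(msgs, "mapped counts exceed totalReads")
  if (length(msgs)) msgs else TRUE
})

#' AbundanceTable: CPM abundances, samples x genes
#'
#' @slot cpm numeric matrix, rows = samples, columns = genes, copies per
#'   million.
#' @slot mode normalization mode: \code{"length_rescaled"} (counts divided
#'   by template length, rescaled to sum to 1e6 per sample) or
#'   \code{"paper_raw"} (count * 1e6 / total reads).
#' @export
setClass("AbundanceTable", representation(
  cpm = "matrix",
  mode = "character"
))

setValidity("AbundanceTable", function(object) {
  msgs <- character()
  if (any(object@cpm < 0)) msgs <- c(msgs, "negative CPM")
  if (!object@mode %in% c("length_rescaled", "paper_raw"))
    msgs <- c(msgs, "unknown normalization mode")
  if (length(msgs)) msgs else TRUE
})

#' ConcordanceResult: per-IC-bin agreement between two annotation methods
#'
#' For every gene and integer information-content bin, the two methods'
#' propagated term sets restricted to the bin are compared: concordant
#' (both non-empty, sharing a term under the default rule), discordant
#' (both non-empty, disjoint), or unique to one method.
#'
#' @slot counts data.frame with columns \code{bin}, \code{concordant},
#'   \code{discordant}, \code{unique_a}, \code{unique_b}.
#' @slot labels length-2 character vector naming methods a and b.
#' @slot rule agreement rule used: \code{"shared_term"} or
#'   \code{"both_present"}.
#' @export
setClass("ConcordanceResult", representation(
  counts = "data.frame",
  labels = "character",
  rule = "character"
))

setValidity("ConcordanceResult", function(object) {
  need <- c("bin", "concordant", "discordant", "unique_a", "unique_b")
  if (!all(need %in% names(object@counts)))
    return(paste("counts must have columns", paste(need, collapse = ", ")))
  cnt <- as.matrix(object@counts[setdiff(need, "bin")])
  if (nrow(cnt) && any(cnt < 0)) return("negative category count")
  if (length(object@labels) != 2L) return("labels must name two methods")
  TRUE
})

#' PresenceMatrix: gene-cluster presence across a species' MAGs
#'
#' @slot species GTDB species label.
#' @slot presence logical matrix, rows = gene cluster ids, columns = MAG
#'   ids; TRUE when the cluster has at least one member gene in the MAG.
#'   Every row is touched by at least one MAG.
#' @export
setClass("PresenceMatrix", representation(
  species = "character",
  presence = "matrix"
))

setValidity("PresenceMatrix", function(object) {
  p <- object@presence
  if (!is.logical(p)) return("presence must be logical")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("presence must have cluster rownames and MAG colnames")
  if (nrow(p) && any(rowSums(p) == 0L))
    return("all-false presence row (cluster in no MAG)")
  TRUE
})

#' Pangenome: core/accessory partition of a species' gene clusters
#'
#' Core clusters are present in at least the core fraction (default 90\%)
#' of the species' nearly complete MAGs; the rest of the observed clusters
#' are accessory. Core and accessory together are the pangenome.
#'
#' @slot species GTDB species label.
#' @slot core character vector of core cluster ids.
#' @slot accessory character vector of accessory cluster ids.
#' @slot nMags number of MAGs the classification was computed over.
#' @export
setClass("Pangenome", representation(
  species = "character",
  core = "character",
  accessory = "character",
  nMags = "integer"
))

setValidity("Pangenome", function(object) {
  if (length(intersect(object@core, object@accessory)))
    return("core and accessory overlap")
  if (object@nMags < 1L) return("nMags must be positive")
  TRUE
})
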