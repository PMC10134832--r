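# Prodigal-style gene ids embed their contig id: "<contig>_<ordinal>".
# Contig names may themselves contain underscores, so split on the LAST one.

#' Contig id of a Prodigal-style gene id
#'
#' @param gene_id character vector of gene ids `"<contig>_<ordinal>"`.
#' @return character vector of contig ids.
#' @export
geneContig <- function(gene_id) sub("_[^_]*$", "", gene_id)

#' Parse a CD-HIT .clstr file into a GeneCatalogue
#'
#' Cluster stanzas start with `>Cluster N`; member lines look like
#' `0\t382aa, >gene_id... *` (representative) or
#' `1\t367aa, >gene_id... at 97.33%`. Gene ids are stored truncated exactly
#' as the tool truncates them (everything before the first `...`). Each
#' cluster must contain exactly one `*` representative, which becomes the
#' centroid.
#'
#' @param file path, or character vector of `.clstr` lines.
#' @param identity_threshold clustering identity carried as metadata
#'   (default 0.95).
#' @return a [GeneCatalogue-class].
#' @export
parseClstr <- function(file, identity_threshold = 0.95) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">Cluster")
  if (length(lines) && !is_hdr[1])
    stop("malformed .clstr: first line is not a '>Cluster' header")
  cluster_no <- cumsum(is_hdr) - 1L
  hdr_num <- sub("^>Cluster\\s+", "", lines[is_hdr])
  body <- lines[!is_hdr]
  body_cluster <- cluster_no[!is_hdr]

  m <- regmatches(body, regexec(
    "^[0-9]+\t([0-9]+)(aa|nt), >(.*?)\\.\\.\\.\\s*(\\*|at .*)$", body))
  bad <- which(lengths(m) == 0L)
  if (length(bad))
    stop("malformed .clstr member line in cluster ", hdr_num[body_cluster[bad[1]] + 1L],
         ": '", body[bad[1]], "'")
  len <- as.numeric(vapply(m, `[`, "", 2L))
  gid <- vapply(m, `[`, "", 4L)
  is_rep <- vapply(m, `[`, "", 5L) == "*"

  nrep <- tapply(is_rep, body_cluster, sum)
  nbad <- names(nrep)[nrep != 1L]
  if (length(nbad))
    stop("cluster ", hdr_num[as.integer(nbad[1]) + 1L], " has ",
         nrep[[nbad[1]]], " representative ('*') lines, expected exactly 1")
  if (anyDuplicated(gid))
    stop("gene id appears in more than one cluster: ",
         gid[duplicated(gid)][1])

  genes <- data.frame(
    gene_id = gid,
    cluster_id = paste0("Cluster_", hdr_num[body_cluster + 1L]),
    is_centroid = is_rep,
    length = len)
  new("GeneCatalogue", genes = genes,
      identityThreshold = identity_threshold)
}

#' Write a GeneCatalogue as a CD-HIT style .clstr file
#'
#' @param cat a [GeneCatalogue-class].
#' @param file output path.
#' @return invisibly, the path written.
#' @export
writeClstr <- function(cat, file) {
  g <- catalogueGenes(cat)
  con <- base::file(file, "w")
  on.exit(close(con))
  ids <- unique(g$cluster_id)
  for (i in seq_along(ids)) {
    writeLines(paste0(">Cluster ", sub("^Cluster_", "", ids[i])), con)
    memb <- g[g$cluster_id == ids[i], ]
    memb <- memb[order(!memb$is_centroid, memb$gene_id), ]
    len <- ifelse(is.na(memb$length), 100, memb$length)
    tail_ <- ifelse(memb$is_centroid, "*", "at 97.50%")
    writeLines(sprintf("%d\t%daa, >%s... %s",
                       seq_len(nrow(memb)) - 1L, len, memb$gene_id, tail_),
               con)
  }
  invisible(file)
}

#' Read gene ids and lengths from a gene FASTA
#'
#' Ids are truncated at the first whitespace (matching how clustering tools
#' truncate them, so joins against the `.clstr` never fail). Returns amino
#' acid lengths for protein FASTA and nucleotide lengths otherwise.
#'
#' @param file FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return named numeric vector of sequence lengths (names = gene ids).
#' @export
readGeneFasta <- function(file, type = c("DNA", "AA")) {
  type <- match.arg(type)
  seqs <- if (type == "AA") Biostrings::readAAStringSet(file)
          else Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(seqs))
  stats::setNames(Biostrings::width(seqs), ids)
}

#' Propagate centroid annotations to all cluster members
#'
#' Annotation methods are run on cluster centroids only; within each
#' cluster (sequences >= 95\% identical) the centroid's records are copied
#' to every member, so all genes of an annotated cluster carry exactly its
#' centroid's annotation. Annotations keyed by non-centroid genes are
#' ignored with a warning (or an error in strict mode); genes of
#' unannotated clusters are absent from the result.
#'
#' @param cat a [GeneCatalogue-class].
#' @param centroid_annots an [AnnotationSet-class] keyed by centroid ids.
#' @param strict error (rather than warn) on annotations for genes outside
#'   the catalogue's centroid set.
#' @return an [AnnotationSet-class] covering all members of annotated
#'   clusters.
#' @export
propagateClusterAnnotations <- function(cat, centroid_annots,
                                        strict = FALSE) {
  r <- annotationRecords(centroid_annots)
  cents <- clusterCentroids(cat)           # cluster_id -> centroid gene
  stray <- setdiff(unique(r$gene_id), unname(cents))
  if (length(stray)) {
    msg <- paste0(length(stray), " annotated gene(s) are not catalogue ",
                  "centroids (e.g. ", stray[1], "); ignored")
    if (strict) stop(msg) else warning(msg)
    r <- r[!r$gene_id %in% stray, , drop = FALSE]
  }
  members <- clusterMembers(cat)
  cent2cluster <- stats::setNames(names(cents), unname(cents))
  memb_of <- members[cent2cluster[r$gene_id]]
  n <- lengths(memb_of)
  out <- data.frame(
    gene_id = as.character(unlist(memb_of, use.names = FALSE)),
    term = as.character(rep.int(r$term, n)),
    score = as.numeric(rep.int(r$score, n)),
    method = as.character(rep.int(r$method, n)))
  # descriptions propagate the same way
  d <- annotationDescriptions(centroid_annots)
  d <- d[names(d) %in% unname(cents)]
  dm <- members[cent2cluster[names(d)]]
  dd <- stats::setNames(rep.int(unname(d), lengths(dm)),
                        unlist(dm, use.names = FALSE))
  annotationSet(out, descriptions = dd)
}

#' Annotation rate as a function of cluster size
#'
#' For each observed cluster size s, the fraction of clusters of that size
#' whose centroid carries at least one annotation.
#'
#' @param cat a [GeneCatalogue-class].
#' @param annots an [AnnotationSet-class] (centroid-level).
#' @return data.frame with columns `size`, `n_clusters`, `fraction_annotated`.
#' @export
annotationRateByClusterSize <- function(cat, annots) {
  g <- catalogueGenes(cat)
  size <- table(g$cluster_id)
  cents <- clusterCentroids(cat)
  annotated <- cents %in% annotatedGenes(annots)
  names(annotated) <- names(cents)
  df <- data.frame(cluster_id = names(size),
                   size = as.integer(size),
                   annotated = annotated[names(size)])
  agg <- aggregate(annotated ~ size, df, function(x)
    c(n = length(x), frac = mean(x)))
  data.frame(size = agg$size,
             n_clusters = as.integer(agg$annotated[, "n"]),
             fraction_annotated = agg$annotated[, "frac"])
}

#' Write / read the catalogue membership table
#'
#' TSV with columns gene_id, cluster_id, is_centroid, length, contig_id.
#'
#' @param cat a [GeneCatalogue-class].
#' @param file path.
#' @return `writeCatalogueTable` returns the path invisibly;
#'   `readCatalogueTable` a [GeneCatalogue-class].
#' @export
writeCatalogueTable <- function(cat, file) {
  g <- catalogueGenes(cat)
  g$contig_id <- geneContig(g$gene_id)
  utils::write.table(g, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCatalogueTable
#' @param identity_threshold metadata for the rebuilt catalogue.
#' @export
readCatalogueTable <- function(file, identity_threshold = 0.95) {
  x <- utils::read.delim(file, sep = "\t",
                         colClasses = c(gene_id = "character",
                                        cluster_id = "character",
                                        is_centroid = "logical",
                                        length = "numeric",
                                        contig_id = "character"))
  new("GeneCatalogue",
      genes = x[c("gene_id", "cluster_id", "is_centroid", "length")],
      identityThreshold = identity_threshold)
}
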