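#' MAG quality-filter configuration
#'
#' The reference workflow calls a MAG "nearly complete" when completeness
#' is at least 90\% (inclusive) and contamination is below 5\% (exclusive).
#'
#' @param min_completeness inclusive completeness floor, percent.
#' @param max_contamination exclusive contamination ceiling, percent.
#' @return a list of class `MagFilterConfig`.
#' @export
magFilterConfig <- function(min_completeness = 90, max_contamination = 5) {
  if (min_completeness < 0 || min_completeness > 100 ||
      max_contamination < 0 || max_contamination > 100)
    stop("thresholds must be within [0,100]")
  structure(list(min_completeness = min_completeness,
                 max_contamination = max_contamination),
            class = "MagFilterConfig")
}

#' Parse GTDB-style taxonomy strings
#'
#' Splits `d__Bacteria;p__...;s__Genus species` classifications into the
#' seven ranks, stripping the rank prefixes. Missing or empty ranks become
#' empty strings.
#'
#' @param x character vector of classification strings.
#' @return data.frame with columns domain..species.
#' @export
parseGtdbTaxonomy <- function(x) {
  out <- matrix("", nrow = length(x), ncol = 7,
                dimnames = list(NULL, GTDB_RANKS))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) next
    parts <- trimws(strsplit(x[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      hit <- which(startsWith(p, GTDB_PREFIXES))
      if (length(hit) == 1L)
        out[i, hit] <- substring(p, nchar(GTDB_PREFIXES[hit]) + 1L)
    }
  }
  as.data.frame(out)
}

.taxonomyString <- function(info_row) {
  vals <- unlist(info_row[GTDB_RANKS], use.names = FALSE)
  paste0(GTDB_PREFIXES, vals, collapse = ";")
}

#' Assemble MAG records from CheckM-style QC, GTDB-style taxonomy, and
#' bin membership
#'
#' @param checkm path to (or data.frame of) a CheckM-style TSV with columns
#'   `Bin Id`, `Completeness`, `Contamination` and optionally `Sample Id`.
#' @param gtdb path to (or data.frame of) a GTDB-Tk summary TSV with
#'   columns `user_genome` and `classification`; bins absent from it get an
#'   empty taxonomy (with a message).
#' @param bins bin membership: a named list (mag_id -> contig ids) or a
#'   path to / data.frame of a two-column TSV (contig_id, mag_id).
#' @param strict error when a bin in `bins` has no QC row (default: warn
#'   and drop).
#' @return a [MagSet-class].
#' @export
readMagMetadata <- function(checkm, gtdb, bins, strict = FALSE) {
  cm <- if (is.character(checkm))
    utils::read.delim(checkm, check.names = FALSE,
                      colClasses = c("Bin Id" = "character")) else checkm
  gt <- if (is.character(gtdb))
    utils::read.delim(gtdb, check.names = FALSE,
                      colClasses = "character") else gtdb
  if (!all(c("Bin Id", "Completeness", "Contamination") %in% names(cm)))
    stop("CheckM table must have columns 'Bin Id', 'Completeness', ",
         "'Contamination'")
  if (!all(c("user_genome", "classification") %in% names(gt)))
    stop("GTDB table must have columns 'user_genome', 'classification'")
  if (is.character(bins) && length(bins) == 1L) {
    b <- utils::read.delim(bins, colClasses = "character")
    if (!all(c("contig_id", "mag_id") %in% names(b)))
      stop("bin membership TSV must have columns contig_id, mag_id")
    bins <- split(b$contig_id, b$mag_id)
  } else if (is.data.frame(bins)) {
    bins <- split(bins$contig_id, bins$mag_id)
  }

  ids <- names(bins)
  noqc <- setdiff(ids, cm[["Bin Id"]])
  if (length(noqc)) {
    msg <- paste0(length(noqc), " bin(s) lack QC rows (e.g. ", noqc[1], ")")
    if (strict) stop(msg)
    warning(msg, "; dropped")
    ids <- setdiff(ids, noqc)
    bins <- bins[ids]
  }
  i <- match(ids, cm[["Bin Id"]])
  comp <- as.numeric(cm$Completeness[i])
  cont <- as.numeric(cm$Contamination[i])
  if (any(comp < 0 | comp > 100, na.rm = TRUE))
    stop("completeness outside [0,100]")
  if (any(cont < 0, na.rm = TRUE)) stop("negative contamination")
  sample_id <- if ("Sample Id" %in% names(cm))
    as.character(cm[["Sample Id"]][i]) else rep("", length(ids))

  j <- match(ids, gt$user_genome)
  missing_tax <- is.na(j)
  if (any(missing_tax))
    message(sum(missing_tax), " bin(s) without taxonomy assignment")
  cls <- ifelse(missing_tax, "", gt$classification[j])
  tax <- parseGtdbTaxonomy(cls)

  info <- cbind(data.frame(mag_id = ids, sample_id = sample_id,
                           completeness = comp, contamination = cont),
                tax)
  rownames(info) <- NULL
  new("MagSet", info = info, contigs = bins)
}

#' Keep nearly complete MAGs
#'
#' Retains MAGs with completeness >= `min_completeness` (inclusive) and
#' contamination < `max_contamination` (exclusive): the 90/5 rule by
#' default. Loosening either threshold never removes a MAG.
#'
#' @param mags a [MagSet-class].
#' @param config a [magFilterConfig()].
#' @return the filtered [MagSet-class].
#' @export
filterNearComplete <- function(mags, config = magFilterConfig()) {
  info <- magInfo(mags)
  keep <- info$completeness >= config$min_completeness &
          info$contamination < config$max_contamination
  keep[is.na(keep)] <- FALSE
  new("MagSet", info = { x <- info[keep, , drop = FALSE]
                         rownames(x) <- NULL; x },
      contigs = magContigs(mags)[info$mag_id[keep]])
}

#' Map genes to MAGs through contig membership
#'
#' A gene belongs to the MAG containing its contig; genes on unbinned
#' contigs map to NA (binning leaves contigs out by design). A contig
#' claimed by two MAGs raises a validation error (MagSet validity enforces
#' this too).
#'
#' @param gene_ids character vector of Prodigal-style gene ids, or a
#'   data.frame with columns `gene_id` and `contig_id`.
#' @param mags a [MagSet-class].
#' @return named character vector gene_id -> mag_id (NA when unbinned).
#' @export
mapGenesToMags <- function(gene_ids, mags) {
  if (is.data.frame(gene_ids)) {
    contig <- gene_ids$contig_id
    gene <- gene_ids$gene_id
  } else {
    gene <- gene_ids
    contig <- geneContig(gene)
  }
  cl <- magContigs(mags)
  lut <- stats::setNames(rep.int(names(cl), lengths(cl)),
                         unlist(cl, use.names = FALSE))
  if (anyDuplicated(names(lut)))
    stop("contig claimed by two MAGs: ",
         names(lut)[duplicated(names(lut))][1])
  stats::setNames(unname(lut[contig]), gene)
}

#' Count distinct taxonomies per gene cluster
#'
#' For each cluster, the number of distinct non-empty labels at the given
#' rank among MAGs (contamination < `max_contamination`) containing any
#' member gene. This quantifies gene families shared across taxa; clusters
#' with no qualifying binned member count 0 (could not be assigned to any
#' taxonomy). Only the contamination filter applies here, not completeness.
#'
#' @param cat a [GeneCatalogue-class].
#' @param gene2mag named vector from [mapGenesToMags()].
#' @param mags a [MagSet-class].
#' @param rank one of `"family"`, `"genus"`, `"species"`.
#' @param max_contamination exclusive ceiling, percent (default 5).
#' @return named integer vector cluster_id -> distinct label count.
#' @export
clusterTaxonomySharing <- function(cat, gene2mag, mags, rank,
                                   max_contamination = 5) {
  if (!rank %in% c("family", "genus", "species"))
    stop("rank must be one of family, genus, species")
  info <- magInfo(mags)
  ok_mags <- info$mag_id[info$contamination < max_contamination]
  labels <- stats::setNames(info[[rank]], info$mag_id)

  g <- catalogueGenes(cat)
  mag <- unname(gene2mag[g$gene_id])
  lab <- ifelse(!is.na(mag) & mag %in% ok_mags, labels[mag], NA_character_)
  lab[!is.na(lab) & !nzchar(lab)] <- NA_character_
  counts <- tapply(lab, g$cluster_id, function(x)
    length(unique(x[!is.na(x)])))
  stats::setNames(as.integer(counts), names(counts))
}

#' Build the integrated gene mapper table
#'
#' One row per catalogue gene: cluster membership, centroid flag, MAG
#' assignment, taxonomy string, and a semicolon-joined GO term summary per
#' annotation method.
#'
#' @param cat a [GeneCatalogue-class].
#' @param gene2mag named vector from [mapGenesToMags()].
#' @param mags a [MagSet-class].
#' @param annots_by_method named list of [AnnotationSet-class] objects
#'   (gene-level, i.e. after cluster propagation).
#' @return data.frame, one row per gene.
#' @export
buildGeneMapperTable <- function(cat, gene2mag, mags,
                                 annots_by_method = list()) {
  g <- catalogueGenes(cat)
  info <- magInfo(mags)
  tax <- vapply(seq_len(nrow(info)), function(i)
    .taxonomyString(info[i, ]), "")
  names(tax) <- info$mag_id
  mag <- unname(gene2mag[g$gene_id])
  out <- data.frame(
    gene_id = g$gene_id,
    cluster_id = g$cluster_id,
    is_centroid = g$is_centroid,
    mag_id = ifelse(is.na(mag), "", mag),
    taxonomy = ifelse(is.na(mag), "", tax[mag]))
  for (m in names(annots_by_method)) {
    r <- annotationRecords(annots_by_method[[m]])
    terms <- vapply(split(r$term, r$gene_id), function(x)
      paste(sort(unique(x)), collapse = ";"), "")
    col <- as.vector(terms[g$gene_id])
    out[[paste0(m, "_terms")]] <- ifelse(is.na(col), "", col)
  }
  rownames(out) <- NULL
  out
}

#' Write / read the gene mapper table
#'
#' @param table data.frame from [buildGeneMapperTable()].
#' @param file path.
#' @return `writeGeneMapperTable` returns the path invisibly;
#'   `readGeneMapperTable` the table (write -> read is the identity).
#' @export
writeGeneMapperTable <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeGeneMapperTable
#' @export
readGeneMapperTable <- function(file) {
  hdr <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1]]
  cls <- stats::setNames(rep("character", length(hdr)), hdr)
  cls["is_centroid"] <- "logical"
  utils::read.delim(file, sep = "\t", colClasses = cls, na.strings = NULL)
}
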