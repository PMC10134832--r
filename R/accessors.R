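# Accessor generics and methods; slot access stays internal to the package.

#' @rdname GoDag-class
#' @param x a GoDag
#' @export
setGeneric("goIds", function(x) standardGeneric("goIds"))
#' @rdname GoDag-class
#' @export
setMethod("goIds", "GoDag", function(x) x@terms)

#' @rdname GoDag-class
#' @export
setGeneric("goParents", function(x) standardGeneric("goParents"))
#' @rdname GoDag-class
#' @export
setMethod("goParents", "GoDag", function(x) x@parents)

#' @rdname GoDag-class
#' @export
setGeneric("goChildren", function(x) standardGeneric("goChildren"))
#' @rdname GoDag-class
#' @export
setMethod("goChildren", "GoDag", function(x) .invertParents(x@parents))

#' @rdname GoDag-class
#' @export
setGeneric("goNamespace", function(x) standardGeneric("goNamespace"))
#' @rdname GoDag-class
#' @export
setMethod("goNamespace", "GoDag", function(x) x@namespace)

#' @rdname GoDag-class
#' @export
setGeneric("goNames", function(x) standardGeneric("goNames"))
#' @rdname GoDag-class
#' @export
setMethod("goNames", "GoDag", function(x) x@termNames)

setMethod("show", "GoDag", function(object) {
  cat("GoDag with", length(object@terms), "terms,",
      sum(lengths(object@parents)), "is_a edges\n")
  ns <- table(object@namespace)
  cat("  namespaces:", paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
})

#' @rdname ICTable-class
#' @param x an ICTable
#' @export
setGeneric("icValues", function(x) standardGeneric("icValues"))
#' @rdname ICTable-class
#' @export
setMethod("icValues", "ICTable", function(x) x@ic)

#' @rdname ICTable-class
#' @export
setGeneric("termCounts", function(x) standardGeneric("termCounts"))
#' @rdname ICTable-class
#' @export
setMethod("termCounts", "ICTable", function(x) x@counts)

#' @rdname ICTable-class
#' @export
setGeneric("corpusSize", function(x) standardGeneric("corpusSize"))
#' @rdname ICTable-class
#' @export
setMethod("corpusSize", "ICTable", function(x) x@n)

setMethod("show", "ICTable", function(object) {
  cat("ICTable for", length(object@ic), "GO terms")
  if (!is.na(object@n)) cat(" (corpus n =", object@n, ")")
  cat("\n  IC range:", if (length(object@ic))
    paste(signif(range(object@ic), 4), collapse = " .. ") else "-", "bits\n")
})

#' @rdname AnnotationSet-class
#' @param x an AnnotationSet
#' @export
setGeneric("annotationRecords", function(x) standardGeneric("annotationRecords"))
#' @rdname AnnotationSet-class
#' @export
setMethod("annotationRecords", "AnnotationSet", function(x) x@records)

#' @rdname AnnotationSet-class
#' @export
setGeneric("annotationDescriptions",
           function(x) standardGeneric("annotationDescriptions"))
#' @rdname AnnotationSet-class
#' @export
setMethod("annotationDescriptions", "AnnotationSet",
          function(x) x@descriptions)

#' @rdname AnnotationSet-class
#' @param method optional method label to restrict to
#' @export
setGeneric("annotatedGenes", function(x, method = NULL)
  standardGeneric("annotatedGenes"))
#' @rdname AnnotationSet-class
#' @export
setMethod("annotatedGenes", "AnnotationSet", function(x, method = NULL) {
  r <- x@records
  if (!is.null(method)) r <- r[r$method %in% method, , drop = FALSE]
  unique(r$gene_id)
})

#' @rdname AnnotationSet-class
#' @export
setGeneric("annotationMethods", function(x) standardGeneric("annotationMethods"))
#' @rdname AnnotationSet-class
#' @export
setMethod("annotationMethods", "AnnotationSet",
          function(x) unique(x@records$method))

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", nrow(object@records), "records,",
      length(unique(object@records$gene_id)), "annotated genes,",
      length(object@descriptions), "descriptions\n")
  if (nrow(object@records)) {
    m <- table(object@records$method)
    cat("  methods:", paste(names(m), m, sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname GeneCatalogue-class
#' @param x a GeneCatalogue
#' @export
setGeneric("catalogueGenes", function(x) standardGeneric("catalogueGenes"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("catalogueGenes", "GeneCatalogue", function(x) x@genes)

#' @rdname GeneCatalogue-class
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("geneIndex", "GeneCatalogue", function(x) {
  stats::setNames(x@genes$cluster_id, x@genes$gene_id)
})

#' @rdname GeneCatalogue-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("clusterMembers", "GeneCatalogue", function(x) {
  split(x@genes$gene_id, x@genes$cluster_id)
})

#' @rdname GeneCatalogue-class
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("clusterCentroids", "GeneCatalogue", function(x) {
  g <- x@genes[x@genes$is_centroid, ]
  stats::setNames(g$gene_id, g$cluster_id)
})

#' @rdname GeneCatalogue-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("nClusters", "GeneCatalogue",
          function(x) length(unique(x@genes$cluster_id)))

#' @rdname GeneCatalogue-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("nGenes", "GeneCatalogue", function(x) nrow(x@genes))

#' @rdname GeneCatalogue-class
#' @export
setGeneric("identityThreshold", function(x) standardGeneric("identityThreshold"))
#' @rdname GeneCatalogue-class
#' @export
setMethod("identityThreshold", "GeneCatalogue",
          function(x) x@identityThreshold)

setMethod("show", "GeneCatalogue", function(object) {
  cat("GeneCatalogue:", nGenes(object), "genes in", nClusters(object),
      "clusters (identity threshold", object@identityThreshold, ")\n")
})

#' @rdname MagSet-class
#' @param x a MagSet
#' @export
setGeneric("magInfo", function(x) standardGeneric("magInfo"))
#' @rdname MagSet-class
#' @export
setMethod("magInfo", "MagSet", function(x) x@info)

#' @rdname MagSet-class
#' @export
setGeneric("magContigs", function(x) standardGeneric("magContigs"))
#' @rdname MagSet-class
#' @export
setMethod("magContigs", "MagSet", function(x) x@contigs)

#' @rdname MagSet-class
#' @export
setGeneric("magIds", function(x) standardGeneric("magIds"))
#' @rdname MagSet-class
#' @export
setMethod("magIds", "MagSet", function(x) x@info$mag_id)

setMethod("show", "MagSet", function(object) {
  cat("MagSet:", nrow(object@info), "MAGs,",
      sum(lengths(object@contigs)), "binned contigs\n")
  sp <- object@info$species
  cat("  species assigned:", sum(nzchar(sp)), "of", length(sp), "\n")
})

#' @rdname GeneCounts-class
#' @param x a GeneCounts
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname GeneCounts-class
#' @export
setMethod("readCounts", "GeneCounts", function(x) x@counts)

#' @rdname GeneCounts-class
#' @export
setGeneric("templateLengths", function(x) standardGeneric("templateLengths"))
#' @rdname GeneCounts-class
#' @export
setMethod("templateLengths", "GeneCounts", function(x) x@lengths)

#' @rdname GeneCounts-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname GeneCounts-class
#' @export
setMethod("sampleId", "GeneCounts", function(x) x@sampleId)

#' @rdname GeneCounts-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname GeneCounts-class
#' @export
setMethod("totalReads", "GeneCounts", function(x) x@totalReads)

setMethod("show", "GeneCounts", function(object) {
  cat("GeneCounts for sample", object@sampleId, ":",
      length(object@counts), "genes,", sum(object@counts), "mapped reads")
  if (!is.na(object@totalReads)) cat(" of", object@totalReads, "total")
  cat("\n")
})

#' @rdname AbundanceTable-class
#' @param x an AbundanceTable
#' @export
setGeneric("cpmMatrix", function(x) standardGeneric("cpmMatrix"))
#' @rdname AbundanceTable-class
#' @export
setMethod("cpmMatrix", "AbundanceTable", function(x) x@cpm)

#' @rdname AbundanceTable-class
#' @export
setGeneric("normalizationMode", function(x) standardGeneric("normalizationMode"))
#' @rdname AbundanceTable-class
#' @export
setMethod("normalizationMode", "AbundanceTable", function(x) x@mode)

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable (", object@mode, "): ", nrow(object@cpm),
      " samples x ", ncol(object@cpm), " genes\n", sep = "")
})

#' @rdname ConcordanceResult-class
#' @param x a ConcordanceResult
#' @export
setGeneric("concordanceCounts", function(x) standardGeneric("concordanceCounts"))
#' @rdname ConcordanceResult-class
#' @export
setMethod("concordanceCounts", "ConcordanceResult", function(x) x@counts)

#' @rdname ConcordanceResult-class
#' @export
setGeneric("concordanceLabels", function(x) standardGeneric("concordanceLabels"))
#' @rdname ConcordanceResult-class
#' @export
setMethod("concordanceLabels", "ConcordanceResult", function(x) x@labels)

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult (", object@labels[1], " vs ", object@labels[2],
      ", rule = ", object@rule, "): ", nrow(object@counts),
      " IC bins\n", sep = "")
})

#' @rdname PresenceMatrix-class
#' @param x a PresenceMatrix
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname PresenceMatrix-class
#' @export
setMethod("presenceMatrix", "PresenceMatrix", function(x) x@presence)

#' @rdname PresenceMatrix-class
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname PresenceMatrix-class
#' @export
setMethod("speciesLabel", "PresenceMatrix", function(x) x@species)
#' @rdname Pangenome-class
#' @export
setMethod("speciesLabel", "Pangenome", function(x) x@species)

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix for", object@species, ":", nrow(object@presence),
      "clusters x", ncol(object@presence), "MAGs\n")
})

#' @rdname Pangenome-class
#' @param x a Pangenome
#' @export
setGeneric("coreClusters", function(x) standardGeneric("coreClusters"))
#' @rdname Pangenome-class
#' @export
setMethod("coreClusters", "Pangenome", function(x) x@core)

#' @rdname Pangenome-class
#' @export
setGeneric("accessoryClusters", function(x) standardGeneric("accessoryClusters"))
#' @rdname Pangenome-class
#' @export
setMethod("accessoryClusters", "Pangenome", function(x) x@accessory)

#' @rdname Pangenome-class
#' @export
setGeneric("nMags", function(x) standardGeneric("nMags"))
#' @rdname Pangenome-class
#' @export
setMethod("nMags", "Pangenome", function(x) x@nMags)

#' @rdname Pangenome-class
#' @export
setGeneric("pangenomeSize", function(x) standardGeneric("pangenomeSize"))
#' @rdname Pangenome-class
#' @export
setMethod("pangenomeSize", "Pangenome",
          function(x) length(x@core) + length(x@accessory))

setMethod("show", "Pangenome", function(object) {
  cat("Pangenome of", object@species, ":", length(object@core), "core +",
      length(object@accessory), "accessory clusters over", object@nMags,
      "MAGs\n")
})
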