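#' Pangenome construction configuration
#'
#' Defaults follow the reference rules: species need at least 10
#' independent nearly complete MAGs; clusters present in >= 90\% of the
#' species' MAGs are core (inclusive boundary), the rest accessory; "nearly
#' complete" is the 90/5 MAG filter.
#'
#' @param min_mags minimum qualifying MAGs per species.
#' @param core_fraction inclusive presence fraction for core calls.
#' @param mag_filter a [magFilterConfig()].
#' @return a list of class `PangenomeConfig`.
#' @export
pangenomeConfig <- function(min_mags = 10, core_fraction = 0.90,
                            mag_filter = magFilterConfig()) {
  if (core_fraction <= 0 || core_fraction > 1)
    stop("core_fraction must be in (0,1]")
  if (min_mags < 1) stop("min_mags must be >= 1")
  structure(list(min_mags = as.integer(min_mags),
                 core_fraction = core_fraction,
                 mag_filter = mag_filter),
            class = "PangenomeConfig")
}

#' Select species eligible for pangenome construction
#'
#' Keeps species whose count of nearly complete MAGs (per the config's MAG
#' filter) reaches `min_mags`; MAGs without a species assignment never
#' enter pangenomes.
#'
#' @param mags a [MagSet-class] (taxonomy-annotated).
#' @param config a [pangenomeConfig()].
#' @return named list: species label -> character vector of MAG ids.
#' @export
selectPangenomeSpecies <- function(mags, config = pangenomeConfig()) {
  nc <- filterNearComplete(mags, config$mag_filter)
  info <- magInfo(nc)
  info <- info[nzchar(info$species), , drop = FALSE]
  sp <- split(info$mag_id, info$species)
  sp[lengths(sp) >= config$min_mags]
}

#' Build a cluster x MAG presence matrix for one species
#'
#' presence(cluster, MAG) is TRUE when at least one member gene of the
#' cluster maps to that MAG (boolean: multiple member genes in one MAG
#' still give one TRUE cell).
#'
#' @param mag_ids the species' qualifying MAG ids (matrix columns).
#' @param cat a [GeneCatalogue-class].
#' @param gene2mag named vector from [mapGenesToMags()].
#' @param species species label carried on the result.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(mag_ids, cat, gene2mag, species = "") {
  g <- catalogueGenes(cat)
  mag <- unname(gene2mag[g$gene_id])
  keep <- !is.na(mag) & mag %in% mag_ids
  cl <- g$cluster_id[keep]
  mg <- mag[keep]
  clusters <- sort(unique(cl))
  m <- matrix(FALSE, nrow = length(clusters), ncol = length(mag_ids),
              dimnames = list(clusters, mag_ids))
  m[cbind(match(cl, clusters), match(mg, mag_ids))] <- TRUE
  new("PresenceMatrix", species = species, presence = m)
}

#' Classify clusters as core or accessory
#'
#' A cluster is core when its presence fraction (MAGs containing it over
#' the species' qualifying MAG count, the matrix columns) is at least
#' `core_fraction` -- so 9 of 10 MAGs is core at the default 0.90 -- and
#' accessory otherwise. Raising `core_fraction` never grows the core.
#'
#' @param pm a [PresenceMatrix-class] with at least `min_mags` columns.
#' @param config a [pangenomeConfig()].
#' @return a [Pangenome-class].
#' @export
classifyCoreAccessory <- function(pm, config = pangenomeConfig()) {
  p <- presenceMatrix(pm)
  if (ncol(p) < config$min_mags)
    stop("species has ", ncol(p), " MAGs, fewer than min_mags = ",
         config$min_mags)
  frac <- rowSums(p) / ncol(p)
  core <- rownames(p)[frac >= config$core_fraction]
  new("Pangenome", species = speciesLabel(pm),
      core = core, accessory = setdiff(rownames(p), core),
      nMags = ncol(p))
}

#' Shared and unique accessory genes across pangenomes
#'
#' An accessory cluster of species S is "shared" when it is observed in
#' another species' pangenome, and "unique" otherwise; shared + unique
#' equals the accessory size for every species. In the default
#' `"pangenome"` mode the other species' entire pangenome (core and
#' accessory) counts as an observation; `"accessory_only"` restricts the
#' check to other species' accessory sets.
#'
#' @param pangenomes list of [Pangenome-class] objects (>= 2 for "shared"
#'   to be meaningful).
#' @param mode `"pangenome"` (default) or `"accessory_only"`.
#' @return data.frame with columns species, shared, unique, accessory.
#' @export
sharedUniqueAccessory <- function(pangenomes,
                                  mode = c("pangenome", "accessory_only")) {
  mode <- match.arg(mode)
  pool <- function(p) if (mode == "pangenome")
    c(coreClusters(p), accessoryClusters(p)) else accessoryClusters(p)
  out <- lapply(seq_along(pangenomes), function(i) {
    acc <- accessoryClusters(pangenomes[[i]])
    others <- unique(unlist(lapply(pangenomes[-i], pool),
                            use.names = FALSE))
    shared <- sum(acc %in% others)
    data.frame(species = speciesLabel(pangenomes[[i]]),
               shared = shared,
               unique = length(acc) - shared,
               accessory = length(acc))
  })
  do.call(rbind, out)
}

#' Cluster ids carrying at least one annotated member gene
#'
#' Convenience bridge from gene-level annotations to cluster-level
#' "known function" status, used to stratify pangenome gene classes.
#'
#' @param cat a [GeneCatalogue-class].
#' @param annots an [AnnotationSet-class].
#' @return character vector of cluster ids.
#' @export
annotatedClusters <- function(cat, annots) {
  idx <- geneIndex(cat)
  unique(unname(idx[intersect(annotatedGenes(annots), names(idx))]))
}

#' Pangenome summary table and size-vs-MAG-count correlation
#'
#' Per species: core, accessory and pangenome sizes, MAG count, and (per
#' annotation method) the number of core and accessory clusters with known
#' function. Also reports the Pearson correlation between pangenome size
#' and MAG count (NA, with a message, when fewer than 3 pangenomes or zero
#' variance in either variable).
#'
#' @param pangenomes list of [Pangenome-class] objects.
#' @param annotated_clusters optional named list: method -> character
#'   vector of annotated cluster ids (see [annotatedClusters()]; pass
#'   informative-filtered annotations for the "known function" convention).
#' @return list with elements `summary` (data.frame) and `pearson_r`.
#' @export
pangenomeSummary <- function(pangenomes, annotated_clusters = NULL) {
  rows <- lapply(pangenomes, function(p) {
    row <- data.frame(species = speciesLabel(p),
                      n_mags = nMags(p),
                      core = length(coreClusters(p)),
                      accessory = length(accessoryClusters(p)),
                      pangenome = pangenomeSize(p))
    for (m in names(annotated_clusters)) {
      ann <- annotated_clusters[[m]]
      row[[paste0(m, "_core_known")]] <- sum(coreClusters(p) %in% ann)
      row[[paste0(m, "_accessory_known")]] <-
        sum(accessoryClusters(p) %in% ann)
    }
    row
  })
  summary <- do.call(rbind, rows)
  r <- NA_real_
  if (nrow(summary) >= 3 &&
      stats::var(summary$pangenome) > 0 && stats::var(summary$n_mags) > 0) {
    r <- stats::cor(summary$pangenome, summary$n_mags)
  } else {
    message("Pearson correlation undefined (need >= 3 pangenomes and ",
            "non-zero variance); reported as NA")
  }
  list(summary = summary, pearson_r = r)
}

#' Write pangenome membership as TSV
#'
#' Columns: species, cluster_id, class (core|accessory), sharing
#' (shared|unique for accessory clusters, empty for core).
#'
#' @param pangenomes list of [Pangenome-class] objects.
#' @param file path.
#' @param mode sharing mode forwarded to [sharedUniqueAccessory()].
#' @return invisibly, the path written.
#' @export
writePangenomeTable <- function(pangenomes, file, mode = "pangenome") {
  rows <- lapply(seq_along(pangenomes), function(i) {
    p <- pangenomes[[i]]
    others <- unique(unlist(lapply(pangenomes[-i], function(q)
      if (mode == "pangenome") c(coreClusters(q), accessoryClusters(q))
      else accessoryClusters(q)), use.names = FALSE))
    acc <- accessoryClusters(p)
    data.frame(
      species = speciesLabel(p),
      cluster_id = c(coreClusters(p), acc),
      class = c(rep("core", length(coreClusters(p))),
                rep("accessory", length(acc))),
      sharing = c(rep("", length(coreClusters(p))),
                  ifelse(acc %in% others, "shared", "unique")))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a presence matrix as 0/1 TSV (clusters x MAGs)
#'
#' @param pm a [PresenceMatrix-class].
#' @param file path.
#' @return invisibly, the path written.
#' @export
writePresenceMatrix <- function(pm, file) {
  p <- presenceMatrix(pm)
  out <- data.frame(cluster_id = rownames(p), 0L + p, check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
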