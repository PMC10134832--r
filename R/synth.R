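#' Configuration for the synthetic community generator
#'
#' The defaults state the simulated world: per-gene-per-MAG dropout of 0.05
#' (MAG incompleteness), a structure-based annotation method covering 99\%
#' of clusters at its standard 0.2 score threshold, an orthology method
#' covering 12\% with GO terms and 72\% with free-text descriptions, and an
#' inter-method term agreement probability of 0.7 -- the coverages and
#' concordance reported for the reference infant-gut dataset. Community
#' sizes (species, MAGs, cluster pools, samples) are desk-scale choices.
#'
#' @param seed mandatory RNG seed (no unseeded runs).
#' @param n_species number of planted species.
#' @param mags_per_species length-2 integer range of nearly complete MAGs
#'   per species.
#' @param core_pool planted core clusters per species.
#' @param accessory_pool planted accessory clusters per species.
#' @param shared_accessory_fraction fraction of the accessory pool drawn
#'   from a cross-species shared pool.
#' @param dropout per-gene per-MAG loss probability d (incompleteness).
#' @param contamination_rate per-gene probability of a foreign-cluster
#'   injection into a MAG (what contamination percentages stand for).
#' @param n_lowq_mags extra MAGs failing the 90/5 quality rule.
#' @param n_unbinned singleton clusters on unbinned contigs.
#' @param n_samples metagenome samples.
#' @param mean_depth mean read depth driving the negative-binomial counts.
#' @param mapped_fraction fraction of a sample's total reads that map.
#' @param p_struct probability a cluster is annotated by the
#'   structure-based method at the 0.2 threshold.
#' @param p_midlevel probability such an annotation is mid-level only
#'   (less specific), not leaf-level.
#' @param p_ortho probability a cluster gets orthology GO terms.
#' @param p_desc probability a cluster gets a free-text description.
#' @param p_agree probability the orthology term equals the
#'   structure-based method's leaf term (vs a different leaf of the same
#'   IC bin).
#' @param k_informative protein-count threshold for informative terms.
#' @param genes_per_contig genes placed per contig.
#' @param sequences generate decorative nucleotide sequences (FALSE speeds
#'   up replicate simulations; file fixtures then get placeholder FASTA).
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed,
                             n_species = 3L,
                             mags_per_species = c(10L, 14L),
                             core_pool = 60L,
                             accessory_pool = 80L,
                             shared_accessory_fraction = 0.15,
                             dropout = 0.05,
                             contamination_rate = 0.02,
                             n_lowq_mags = 2L,
                             n_unbinned = 15L,
                             n_samples = 4L,
                             mean_depth = 40,
                             mapped_fraction = 0.8,
                             p_struct = 0.99,
                             p_midlevel = 0.25,
                             p_ortho = 0.12,
                             p_desc = 0.72,
                             p_agree = 0.7,
                             k_informative = 2000,
                             genes_per_contig = 5L,
                             sequences = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(shared_accessory_fraction, dropout, contamination_rate,
             mapped_fraction, p_struct, p_midlevel, p_ortho, p_desc,
             p_agree)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0,1]")
  if (length(mags_per_species) == 1L)
    mags_per_species <- rep(mags_per_species, 2L)
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    mags_per_species = as.integer(mags_per_species),
    core_pool = as.integer(core_pool),
    accessory_pool = as.integer(accessory_pool),
    shared_accessory_fraction = shared_accessory_fraction,
    dropout = dropout, contamination_rate = contamination_rate,
    n_lowq_mags = as.integer(n_lowq_mags),
    n_unbinned = as.integer(n_unbinned),
    n_samples = as.integer(n_samples), mean_depth = mean_depth,
    mapped_fraction = mapped_fraction, p_struct = p_struct,
    p_midlevel = p_midlevel, p_ortho = p_ortho, p_desc = p_desc,
    p_agree = p_agree, k_informative = k_informative,
    genes_per_contig = as.integer(genes_per_contig),
    sequences = isTRUE(sequences)), class = "SimulationConfig")
}

# Fixed toy molecular-function ontology: a root, 5 mid-level terms, 3
# leaves per mid. Planted corpus counts make mids 1-4 informative at
# k = 2000 (count > 2000, all leaf descendants < 2000) while the root fails
# on its descendants and mid 5 (count 1800) fails the count condition.
# Leaf counts 1200/300/75 put leaves in IC bins 3, 5 and 7; mids sit in
# bins 1-2 and the root at 0.
.toyOntology <- function() {
  root <- "GO:0003674"
  mids <- sprintf("GO:%07d", 1000001:1000005)
  mid_counts <- c(4800, 3600, 2600, 2200, 1800)
  leaves <- character(); leaf_parent <- character(); leaf_counts <- numeric()
  for (i in seq_along(mids)) {
    l <- sprintf("GO:%07d", 2000000 + 10 * i + 1:3)
    leaves <- c(leaves, l)
    leaf_parent <- c(leaf_parent, rep(mids[i], 3))
    leaf_counts <- c(leaf_counts, c(1200, 300, 75))
  }
  ids <- c(root, mids, leaves)
  parents <- c(list(character()),
               rep(list(root), length(mids)),
               as.list(leaf_parent))
  names(parents) <- ids
  nms <- c("molecular_function",
           sprintf("synthetic mid-level activity %d", seq_along(mids)),
           sprintf("synthetic specific activity %d", seq_along(leaves)))
  dag <- new("GoDag", terms = ids,
             termNames = stats::setNames(nms, ids),
             namespace = stats::setNames(
               rep("molecular_function", length(ids)), ids),
             parents = parents)
  n <- 10000
  counts <- stats::setNames(c(n, mid_counts, leaf_counts), ids)
  list(dag = dag, counts = counts, n = n,
       informative = mids[mid_counts > 2000],
       mids = mids, leaves = leaves,
       leaf_parent = stats::setNames(leaf_parent, leaves),
       leaf_bins = stats::setNames(
         floor(-log2(leaf_counts / n)), leaves))
}

.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a synthetic metagenome community with ground truth
#'
#' Generates, deterministically under the config seed, a complete fixture
#' bundle emulating the upstream tool outputs the pipeline consumes: a toy
#' GO ontology with planted corpus counts (known informative set), a gene
#' catalogue over planted species with core/accessory structure, MAGs with
#' dropout-driven incompleteness and foreign-cluster contamination plus
#' quality/taxonomy metadata, two annotation channels (score-carrying
#' structure-based and orthology-style with descriptions) with a planted
#' agreement probability, and per-sample read-count tables. The truth
#' manifest fully determines the expected output of every downstream step.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `bundle` (in-memory objects: dag, ic,
#'   term_counts, catalogue, mags, annotations, counts, sequences, raw
#'   tables) and `manifest` (plain-list ground truth).
#' @export
simulateCommunity <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must come from simulationConfig()")
  set.seed(config$seed)
  onto <- .toyOntology()
  ic <- computeICTable(onto$counts, onto$n)

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  n_shared <- max(0L, round(config$shared_accessory_fraction *
                              config$accessory_pool))
  shared_keys <- if (n_shared && config$n_species > 1L)
    sprintf("shared_acc_%03d", seq_len(n_shared)) else character()

  # species taxonomy: first two species share a genus when possible
  sp_names <- sprintf("Syngenus%02d sp%02d",
                      c(1L, 1L, seq_len(max(0L, config$n_species - 2L)) + 1L)[
                        seq_len(config$n_species)],
                      seq_len(config$n_species))
  sp_genus <- sub(" .*$", "", sp_names)
  sp_family <- ifelse(seq_len(config$n_species) <= 2L,
                      "Synfamily01", sprintf("Synfamily%02d",
                                             seq_len(config$n_species)))
  taxonomy_of <- function(i) paste0(
    "d__Bacteria;p__Synphyla;c__Synclassia;o__Synorderales;",
    "f__", sp_family[i], ";g__", sp_genus[i], ";s__", sp_names[i])

  # cluster registry: key -> species/type, filled in planting order
  ckey <- character(); ctype <- character(); cspecies <- character()
  addClusters <- function(keys, type, species) {
    ckey <<- c(ckey, keys)
    ctype <<- c(ctype, rep(type, length(keys)))
    cspecies <<- c(cspecies, rep(species, length(keys)))
  }
  if (length(shared_keys)) addClusters(shared_keys, "accessory_shared", "")
  core_keys <- acc_keys <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    core_keys[[i]] <- sprintf("sp%d_core_%03d", i, seq_len(config$core_pool))
    n_unique_acc <- config$accessory_pool - length(shared_keys)
    acc_unique <- if (n_unique_acc > 0)
      sprintf("sp%d_acc_%03d", i, seq_len(n_unique_acc)) else character()
    acc_keys[[i]] <- c(acc_unique, shared_keys)
    addClusters(core_keys[[i]], "core", sp_names[i])
    addClusters(acc_unique, "accessory_unique", sp_names[i])
  }
  unbinned_keys <- if (config$n_unbinned > 0)
    sprintf("unbinned_%03d", seq_len(config$n_unbinned)) else character()
  addClusters(unbinned_keys, "unbinned", "")
  len_aa <- stats::setNames(
    as.numeric(sample(100:500, length(ckey), replace = TRUE)), ckey)

  # --- MAG construction -----------------------------------------------
  mag_rows <- list(); mag_contigs <- list(); mag_genes <- list()
  contig_counter <- 0L; mag_counter <- 0L
  placeGenes <- function(keys, sample_id) {
    # lay `keys` onto fresh contigs, genes_per_contig at a time
    n <- length(keys)
    if (!n) return(list(contigs = character(),
                        genes = data.frame(gene_id = character(),
                                           key = character())))
    nctg <- ceiling(n / config$genes_per_contig)
    ctgs <- sprintf("%s_k141_%d", sample_id,
                    contig_counter + seq_len(nctg))
    contig_counter <<- contig_counter + nctg
    idx <- rep(seq_len(nctg), each = config$genes_per_contig)[seq_len(n)]
    ord <- stats::ave(seq_len(n), idx, FUN = seq_along)
    list(contigs = ctgs,
         genes = data.frame(gene_id = paste0(ctgs[idx], "_", ord),
                            key = keys))
  }
  sp_mag_ids <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    n_mags <- if (config$mags_per_species[1] == config$mags_per_species[2])
      config$mags_per_species[1] else
        sample(config$mags_per_species[1]:config$mags_per_species[2], 1L)
    # accessory presence: each accessory cluster in at most 89% of MAGs
    acc_presence <- lapply(acc_keys[[i]], function(k) {
      m <- sample.int(max(1L, floor(0.89 * n_mags)), 1L)
      sample.int(n_mags, m)
    })
    names(acc_presence) <- acc_keys[[i]]
    ids <- character(n_mags)
    for (m in seq_len(n_mags)) {
      mag_counter <- mag_counter + 1L
      mag_id <- sprintf("bin_%04d", mag_counter)
      ids[m] <- mag_id
      sample_id <- samples[(mag_counter - 1L) %% length(samples) + 1L]
      keep_core <- core_keys[[i]][
        stats::runif(config$core_pool) > config$dropout]
      acc_here <- names(acc_presence)[vapply(acc_presence, function(x)
        m %in% x, logical(1))]
      keep_acc <- acc_here[stats::runif(length(acc_here)) > config$dropout]
      keys <- c(keep_core, keep_acc)
      n_foreign <- stats::rbinom(1L, length(keys), config$contamination_rate)
      if (n_foreign > 0L && config$n_species > 1L) {
        foreign_pool <- unlist(core_keys[-i], use.names = FALSE)
        keys <- c(keys, sample(foreign_pool, n_foreign))
      }
      placed <- placeGenes(keys, sample_id)
      mag_contigs[[mag_id]] <- placed$contigs
      mag_genes[[mag_id]] <- placed$genes
      mag_rows[[mag_id]] <- data.frame(
        mag_id = mag_id, sample_id = sample_id,
        completeness = round(100 * (1 - config$dropout), 2),
        contamination = round(100 * n_foreign /
                                max(1L, length(keys)), 2),
        classification = taxonomy_of(i), species = sp_names[i],
        lowq = FALSE)
    }
    sp_mag_ids[[i]] <- ids
  }
  # low-quality MAGs: alternately failing completeness and contamination
  for (j in seq_len(config$n_lowq_mags)) {
    mag_counter <- mag_counter + 1L
    mag_id <- sprintf("bin_%04d", mag_counter)
    sample_id <- samples[(mag_counter - 1L) %% length(samples) + 1L]
    i <- (j - 1L) %% config$n_species + 1L
    keys <- sample(core_keys[[i]], min(20L, config$core_pool))
    placed <- placeGenes(keys, sample_id)
    fail_completeness <- j %% 2L == 1L
    mag_contigs[[mag_id]] <- placed$contigs
    mag_genes[[mag_id]] <- placed$genes
    mag_rows[[mag_id]] <- data.frame(
      mag_id = mag_id, sample_id = sample_id,
      completeness = round(if (fail_completeness)
        stats::runif(1, 55, 89.4) else stats::runif(1, 90, 99), 2),
      contamination = round(if (fail_completeness)
        stats::runif(1, 0, 4) else stats::runif(1, 5.5, 15), 2),
      classification = taxonomy_of(i), species = sp_names[i],
      lowq = TRUE)
  }
  # unbinned singleton clusters
  unb_genes <- list()
  for (j in seq_along(unbinned_keys)) {
    sample_id <- samples[(j - 1L) %% length(samples) + 1L]
    placed <- placeGenes(unbinned_keys[j], sample_id)
    unb_genes[[j]] <- placed$genes
  }

  # --- gene catalogue --------------------------------------------------
  all_genes <- do.call(rbind, c(mag_genes, unb_genes))
  if (is.null(all_genes) || !nrow(all_genes))
    stop("empty simulated community")
  # realized clusters in planting order; id Cluster_<k> by that order
  realized <- ckey[ckey %in% unique(all_genes$key)]
  cluster_id_of <- stats::setNames(
    paste0("Cluster_", seq_along(realized) - 1L), realized)
  genes <- data.frame(
    gene_id = all_genes$gene_id,
    cluster_id = unname(cluster_id_of[all_genes$key]),
    key = all_genes$key,
    length = unname(len_aa[all_genes$key]))
  # centroid = first generated gene of the cluster; then order rows the
  # way the .clstr writer/parser round-trips them
  first <- !duplicated(genes$cluster_id)
  centroid_of <- stats::setNames(genes$gene_id[first],
                                 genes$cluster_id[first])
  genes$is_centroid <- genes$gene_id == centroid_of[genes$cluster_id]
  ord <- order(match(genes$cluster_id, unname(cluster_id_of)),
               !genes$is_centroid, genes$gene_id)
  genes <- genes[ord, ]
  rownames(genes) <- NULL
  catalogue <- new("GeneCatalogue",
                   genes = genes[c("gene_id", "cluster_id", "is_centroid",
                                   "length")],
                   identityThreshold = 0.95)

  # --- MAG metadata object --------------------------------------------
  mag_info_raw <- do.call(rbind, mag_rows)
  mag_ids_sorted <- sort(names(mag_contigs))
  mag_info_raw <- mag_info_raw[match(mag_ids_sorted, mag_info_raw$mag_id), ]
  tax <- parseGtdbTaxonomy(mag_info_raw$classification)
  mags <- new("MagSet",
              info = {
                x <- cbind(mag_info_raw[c("mag_id", "sample_id",
                                          "completeness", "contamination")],
                           tax)
                rownames(x) <- NULL
                x
              },
              contigs = mag_contigs[mag_ids_sorted])

  # --- annotations (centroid-level) -----------------------------------
  centroids <- clusterCentroids(catalogue)     # cluster_id -> gene
  key_of_cluster <- stats::setNames(realized, unname(cluster_id_of))
  true_leaf <- stats::setNames(
    sample(onto$leaves, length(realized), replace = TRUE), realized)
  struct_rows <- list(); ortho_rows <- list(); desc_map <- character()
  bins_of <- onto$leaf_bins
  for (cl in names(centroids)) {
    key <- key_of_cluster[[cl]]
    gene <- centroids[[cl]]
    leaf <- true_leaf[[key]]
    # structure-based channel
    if (stats::runif(1) < config$p_struct) {
      s <- stats::runif(1, 0.2, 1)
      term <- if (stats::runif(1) < config$p_midlevel)
        onto$leaf_parent[[leaf]] else leaf
      struct_rows[[length(struct_rows) + 1L]] <-
        data.frame(gene_id = gene, term = term, score = round(s, 4))
    } else if (stats::runif(1) < 0.5) {
      struct_rows[[length(struct_rows) + 1L]] <-
        data.frame(gene_id = gene, term = leaf,
                   score = round(stats::runif(1, 0.01, 0.19), 4))
    }
    # orthology channel
    if (stats::runif(1) < config$p_ortho) {
      term_b <- if (stats::runif(1) < config$p_agree) leaf else {
        pool <- setdiff(names(bins_of)[bins_of == bins_of[[leaf]]], leaf)
        sample(pool, 1L)
      }
      ortho_rows[[length(ortho_rows) + 1L]] <-
        data.frame(gene_id = gene, term = term_b)
    }
    if (stats::runif(1) < config$p_desc)
      desc_map[gene] <- paste("synthetic functional description of", key)
  }
  struct_tab <- if (length(struct_rows)) do.call(rbind, struct_rows) else
    data.frame(gene_id = character(), term = character(), score = numeric())
  struct_tab$name <- unname(goNames(onto$dag)[struct_tab$term])
  ortho_tab <- if (length(ortho_rows)) do.call(rbind, ortho_rows) else
    data.frame(gene_id = character(), term = character())

  struct02 <- annotationSet(data.frame(
    gene_id = struct_tab$gene_id[struct_tab$score >= 0.2],
    term = struct_tab$term[struct_tab$score >= 0.2],
    score = struct_tab$score[struct_tab$score >= 0.2],
    method = "deepfri"))
  # orthology set mirrors what the table reader reconstructs: a gene row
  # exists when it has GO terms and/or a description
  ortho_gene_ids <- sort(unique(c(ortho_tab$gene_id, names(desc_map))))
  ortho_set <- annotationSet(
    if (nrow(ortho_tab)) data.frame(gene_id = ortho_tab$gene_id,
                                    term = ortho_tab$term,
                                    score = 1.0, method = "eggnog")
    else data.frame(gene_id = character(), term = character(),
                    score = numeric(), method = character()),
    descriptions = desc_map)

  # --- per-sample counts over the catalogue centroids ------------------
  cent_genes <- unname(centroids)
  cent_len_nt <- 3 * catalogueGenes(catalogue)$length[
    match(cent_genes, catalogueGenes(catalogue)$gene_id)]
  counts <- lapply(samples, function(s) {
    cnt <- stats::rnbinom(length(cent_genes),
                          mu = config$mean_depth * cent_len_nt / 1000,
                          size = 5)
    geneCounts(s, stats::setNames(cnt, cent_genes),
               stats::setNames(cent_len_nt, cent_genes),
               total_reads = ceiling(sum(cnt) / config$mapped_fraction))
  })
  names(counts) <- samples

  sequences <- if (config$sequences) {
    g <- catalogueGenes(catalogue)
    stats::setNames(vapply(3 * g$length, .randomSeq, ""), g$gene_id)
  } else NULL

  # independent longhand annotated-abundance truth (length-rescaled CPM)
  annotated_truth <- list(
    deepfri = unique(struct02@records$gene_id),
    eggnog = unique(ortho_set@records$gene_id))
  frac_truth <- lapply(annotated_truth, function(gset) {
    vapply(counts, function(gc) {
      w <- readCounts(gc) / templateLengths(gc)
      100 * sum(w[names(w) %in% gset]) / sum(w)
    }, numeric(1))
  })

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    ontology = list(informative = onto$informative,
                    leaves = onto$leaves,
                    leaf_bins = as.list(onto$leaf_bins),
                    n = onto$n),
    clusters = data.frame(cluster_id = unname(cluster_id_of),
                          key = realized,
                          species = cspecies[match(realized, ckey)],
                          type = ctype[match(realized, ckey)],
                          true_leaf = unname(true_leaf[realized]),
                          centroid = unname(centroids[
                            unname(cluster_id_of)])),
    species = lapply(seq_len(config$n_species), function(i) list(
      name = sp_names[i],
      taxonomy = taxonomy_of(i),
      mags = sp_mag_ids[[i]],
      core = unname(cluster_id_of[intersect(core_keys[[i]], realized)]),
      accessory = unname(cluster_id_of[intersect(acc_keys[[i]],
                                                 realized)]))),
    p_agree = config$p_agree,
    annotated_genes = annotated_truth,
    annotated_fraction = frac_truth)
  names(manifest$species) <- sp_names

  list(bundle = list(config = config,
                     dag = onto$dag, ic = ic,
                     term_counts = onto$counts,
                     informative = onto$informative,
                     catalogue = catalogue,
                     mags = mags,
                     annotations = list(structure = struct02,
                                        orthology = ortho_set),
                     raw = list(structure_table = struct_tab,
                                ortho_table = ortho_tab,
                                descriptions = desc_map),
                     counts = counts,
                     sequences = sequences),
       manifest = manifest)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits every file dialect the module readers consume: mini-OBO ontology,
#' IC and term-count TSVs, gene FASTA, CD-HIT style `.clstr`, contig-to-MAG
#' TSV, CheckM-style and GTDB-style TSVs, a structure-prediction CSV with
#' scores, an orthology-mapper `.annotations` TSV with GO column and
#' descriptions, per-sample KMA-style `.res` count tables, a sample table
#' with total read counts, the truth manifest (JSON) and an md5 checksum
#' manifest. Writing is deterministic: the same bundle produces
#' byte-identical files.
#'
#' @param sim result of [simulateCommunity()] (or its `bundle`/`manifest`
#'   as a list with those names).
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
writeFixtures <- function(sim, dir) {
  bundle <- sim$bundle; manifest <- sim$manifest
  if (is.null(bundle)) stop("sim must carry a $bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- c(
    obo = p("ontology.obo"), ic = p("ic_table.tsv"),
    counts = p("term_counts.tsv"), fasta = p("genes.fna"),
    clstr = p("catalogue.clstr"), bins = p("contig2mag.tsv"),
    checkm = p("checkm.tsv"), gtdb = p("gtdbtk.tsv"),
    structure = p("structure_predictions.csv"),
    ortho = p("orthology.annotations.tsv"),
    samples = p("samples.tsv"), manifest = p("manifest.json"),
    checksums = p("checksums.tsv"))

  writeOBO(bundle$dag, paths[["obo"]])
  ic <- icValues(bundle$ic)
  utils::write.table(data.frame(names(ic), unname(ic)), paths[["ic"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tc <- bundle$term_counts
  utils::write.table(data.frame(names(tc), unname(tc)), paths[["counts"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  if (!is.null(bundle$sequences)) {
    seqs <- Biostrings::DNAStringSet(bundle$sequences)
  } else {
    g <- catalogueGenes(bundle$catalogue)
    seqs <- Biostrings::DNAStringSet(
      stats::setNames(strrep("ACGT", ceiling(3 * g$length / 4)),
                      g$gene_id))
  }
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])

  writeClstr(bundle$catalogue, paths[["clstr"]])

  contigs <- magContigs(bundle$mags)
  utils::write.table(
    data.frame(contig_id = unlist(contigs, use.names = FALSE),
               mag_id = rep.int(names(contigs), lengths(contigs))),
    paths[["bins"]], sep = "\t", quote = FALSE, row.names = FALSE)

  info <- magInfo(bundle$mags)
  checkm <- data.frame(info$mag_id, info$completeness, info$contamination,
                       info$sample_id, check.names = FALSE)
  names(checkm) <- c("Bin Id", "Completeness", "Contamination", "Sample Id")
  utils::write.table(checkm, paths[["checkm"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cls <- vapply(seq_len(nrow(info)), function(i)
    .taxonomyString(info[i, ]), "")
  utils::write.table(data.frame(user_genome = info$mag_id,
                                classification = cls),
                     paths[["gtdb"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  st <- bundle$raw$structure_table
  utils::write.table(
    data.frame(gene = st$gene_id, term = st$term, score = st$score,
               name = st$name),
    paths[["structure"]], sep = ",", quote = FALSE, row.names = FALSE)

  ot <- bundle$raw$ortho_table
  desc <- bundle$raw$descriptions
  gos_by_gene <- if (nrow(ot)) tapply(ot$term, ot$gene_id, paste,
                                      collapse = ",") else
    stats::setNames(character(), character())
  gene_ids <- sort(unique(c(names(gos_by_gene), names(desc))))
  gos <- ifelse(gene_ids %in% names(gos_by_gene),
                gos_by_gene[gene_ids], "-")
  dd <- ifelse(gene_ids %in% names(desc), desc[gene_ids], "-")
  con <- base::file(paths[["ortho"]], "w")
  writeLines(c("## synthetic orthology-mapper style annotations",
               paste("#query_name", "seed_eggNOG_ortholog", "GOs",
                     "Description", sep = "\t")), con)
  if (length(gene_ids))
    writeLines(paste(gene_ids, "synthOG", gos, dd, sep = "\t"), con)
  close(con)

  res_paths <- character()
  for (s in names(bundle$counts)) {
    gc <- bundle$counts[[s]]
    f <- p(paste0(s, ".res"))
    res <- data.frame(names(readCounts(gc)),
                      unname(templateLengths(gc)),
                      unname(readCounts(gc)),
                      round(unname(readCounts(gc) * 150 /
                                     templateLengths(gc)), 2),
                      check.names = FALSE)
    names(res) <- c("#Template", "Template_length", "readCount", "Depth")
    utils::write.table(res, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res_paths[paste0("res_", s)] <- f
  }
  utils::write.table(
    data.frame(sample_id = names(bundle$counts),
               total_reads = vapply(bundle$counts, totalReads,
                                    numeric(1))),
    paths[["samples"]], sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths <- c(paths, res_paths)
  files <- setdiff(paths, paths[["checksums"]])
  sums <- tools::md5sum(files)
  utils::write.table(data.frame(file = basename(names(sums)),
                                md5 = unname(sums)),
                     paths[["checksums"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
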