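checkm3 <- data.frame(
  `Bin Id` = c("bin1", "bin2", "bin3"),
  Completeness = c(98.5, 91.2, 75.0),
  Contamination = c(1.2, 4.9, 9.8),
  `Sample Id` = c("S1", "S1", "S2"),
  check.names = FALSE)
gtdb3 <- data.frame(
  user_genome = c("bin1", "bin2"),
  classification = c(
    "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__Bacteroides dorei",
    "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__Bacteroides ovatus"))
bins3 <- list(bin1 = c("S1_k141_1", "S1_k141_2"),
              bin2 = c("S1_k141_5"),
              bin3 = c("S2_k141_3"))

test_that("MAG metadata assembles QC, taxonomy and bin membership", {
  mags <- suppressMessages(readMagMetadata(checkm3, gtdb3, bins3))
  info <- magInfo(mags)
  expect_equal(nrow(info), 3L)
  expect_equal(info$completeness[info$mag_id == "bin1"], 98.5)
  expect_equal(info$species[info$mag_id == "bin1"], "Bacteroides dorei")
  expect_equal(info$genus[info$mag_id == "bin2"], "Bacteroides")
  # bin without taxonomy gets empty ranks
  expect_equal(info$species[info$mag_id == "bin3"], "")
  # QC validation
  bad <- checkm3; bad$Completeness[1] <- 105
  expect_error(suppressMessages(readMagMetadata(bad, gtdb3, bins3)),
               "completeness")
  # strict mode errors on bins without QC
  bins4 <- c(bins3, list(bin9 = "S9_k141_1"))
  expect_error(suppressMessages(
    readMagMetadata(checkm3, gtdb3, bins4, strict = TRUE)), "lack QC")
})

test_that("GTDB taxonomy strings parse with prefixes stripped", {
  tax <- parseGtdbTaxonomy("d__Bacteria;p__Firmicutes;c__;o__;f__;g__;s__")
  expect_equal(tax$domain, "Bacteria")
  expect_equal(tax$phylum, "Firmicutes")
  expect_equal(tax$class, "")
  expect_equal(parseGtdbTaxonomy("")$species, "")
})

test_that("near-complete filter applies the 90/5 boundaries literally", {
  info <- data.frame(mag_id = paste0("m", 1:4), sample_id = "S1",
                     completeness = c(90.0, 89.9, 98.0, 99.0),
                     contamination = c(4.9, 1.0, 5.0, 0.0))
  mags <- makeMagSet(info, setNames(as.list(paste0("c", 1:4)), info$mag_id))
  kept <- magIds(filterNearComplete(mags))
  expect_setequal(kept, c("m1", "m4"))   # 90.0/4.9 kept; 89.9 and 5.0 out
  # empty input -> empty output
  empty <- filterNearComplete(mags, magFilterConfig(100, 0))
  expect_length(magIds(empty), 0L)
  # monotone: loosening thresholds never removes a MAG
  loose <- magIds(filterNearComplete(mags, magFilterConfig(80, 10)))
  expect_true(all(kept %in% loose))
})

test_that("genes map to MAGs through contig membership", {
  mags <- suppressMessages(readMagMetadata(checkm3, gtdb3, bins3))
  g2m <- mapGenesToMags(c("S1_k141_1_1", "S1_k141_5_2", "S3_k141_9_1"),
                        mags)
  expect_equal(unname(g2m["S1_k141_1_1"]), "bin1")
  expect_equal(unname(g2m["S1_k141_5_2"]), "bin2")
  expect_true(is.na(g2m["S3_k141_9_1"]))
})

test_that("a 200-gene mapping equals a brute-force join over contig sets", {
  set.seed(41)
  contigs <- sprintf("S%d_k141_%d", sample(1:3, 40, TRUE), 1:40)
  bins <- split(contigs[1:30], rep(paste0("bin", 1:6), each = 5))
  info <- data.frame(mag_id = names(bins), sample_id = "S1",
                     completeness = 95, contamination = 1)
  mags <- makeMagSet(info, bins)
  genes <- paste0(sample(contigs, 200, TRUE), "_", sample(1:9, 200, TRUE))
  g2m <- mapGenesToMags(genes, mags)
  for (i in seq_along(genes)) {
    ctg <- geneContig(genes[i])
    hit <- names(bins)[vapply(bins, function(cs) ctg %in% cs, logical(1))]
    expect_identical(unname(g2m[[i]]),
                     if (length(hit)) hit else NA_character_)
  }
})

test_that("taxonomy sharing counts distinct non-empty rank labels", {
  cat <- parseClstr(c(
    ">Cluster 0",
    "0\t100aa, >S1_k141_1_1... *",
    "1\t100aa, >S1_k141_5_1... at 96.00%",
    ">Cluster 1",
    "0\t100aa, >S9_k141_9_1... *"))
  mags <- suppressMessages(readMagMetadata(checkm3, gtdb3, bins3))
  g2m <- mapGenesToMags(catalogueGenes(cat)$gene_id, mags)
  # two species, one genus across the two MAGs touching Cluster_0
  sp <- clusterTaxonomySharing(cat, g2m, mags, "species")
  ge <- clusterTaxonomySharing(cat, g2m, mags, "genus")
  expect_equal(unname(sp["Cluster_0"]), 2L)
  expect_equal(unname(ge["Cluster_0"]), 1L)
  # unbinned cluster counts zero taxonomies
  expect_equal(unname(sp["Cluster_1"]), 0L)
  expect_error(clusterTaxonomySharing(cat, g2m, mags, "phylum"), "rank")
  # contamination gate: tightening it to 1% drops bin2 (4.9%)
  sp1 <- clusterTaxonomySharing(cat, g2m, mags, "species",
                                max_contamination = 1.21)
  expect_equal(unname(sp1["Cluster_0"]), 1L)
})

test_that("sharing counts match an oracle on a synthetic community", {
  sim <- simulateCommunity(simulationConfig(seed = 5, n_species = 3,
                                            sequences = FALSE))
  b <- sim$bundle
  g <- catalogueGenes(b$catalogue)
  g2m <- mapGenesToMags(g$gene_id, b$mags)
  got <- clusterTaxonomySharing(b$catalogue, g2m, b$mags, "species")
  info <- magInfo(b$mags)
  ok <- info$mag_id[info$contamination < 5]
  labels <- setNames(info$species, info$mag_id)
  for (cl in sample(unique(g$cluster_id), 40)) {
    mg <- g2m[g$gene_id[g$cluster_id == cl]]
    mg <- mg[!is.na(mg) & mg %in% ok]
    lab <- labels[mg]
    expect_identical(unname(got[cl]), length(unique(lab[nzchar(lab)])))
  }
  # clusters with >= 1 qualifying binned member are exactly those counting > 0
  n_touched <- sum(vapply(split(g$gene_id, g$cluster_id), function(gs) {
    mg <- g2m[gs]
    any(!is.na(mg) & mg %in% ok & nzchar(labels[mg[!is.na(mg)]]))
  }, logical(1)))
  expect_equal(sum(got >= 1L), n_touched)
})

test_that("gene mapper table has one row per gene and round-trips", {
  sim <- simulateCommunity(simulationConfig(seed = 6, n_species = 2,
                                            core_pool = 10,
                                            accessory_pool = 10,
                                            mags_per_species = c(3, 3),
                                            n_unbinned = 2, n_lowq_mags = 0,
                                            sequences = FALSE))
  b <- sim$bundle
  g <- catalogueGenes(b$catalogue)
  g2m <- mapGenesToMags(g$gene_id, b$mags)
  gene_annots <- propagateClusterAnnotations(b$catalogue,
                                             b$annotations$structure)
  tab <- buildGeneMapperTable(b$catalogue, g2m, b$mags,
                              list(deepfri = gene_annots))
  expect_equal(nrow(tab), nGenes(b$catalogue))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneMapperTable(tab, f)
  expect_identical(readGeneMapperTable(f), tab)
  # annotation column equals an independent join
  r <- annotationRecords(gene_annots)
  for (i in sample(nrow(tab), 25)) {
    terms <- sort(unique(r$term[r$gene_id == tab$gene_id[i]]))
    expect_identical(tab$deepfri_terms[i], paste(terms, collapse = ";"))
  }
  # taxonomy column: binned genes carry their MAG's species string
  info <- magInfo(b$mags)
  binned <- which(tab$mag_id != "")
  i <- binned[1]
  sp <- info$species[info$mag_id == tab$mag_id[i]]
  expect_match(tab$taxonomy[i], paste0("s__", sp), fixed = TRUE)
})
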