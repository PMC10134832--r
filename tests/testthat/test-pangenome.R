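# MagSet with three species: sp A has 10 qualifying MAGs, sp B has 9
# qualifying + 1 failing completeness, sp C unassigned
pangMagSet <- function() {
  n <- 21
  ids <- sprintf("m%02d", 1:n)
  species <- c(rep("Species alpha", 10), rep("Species beta", 10), "")
  completeness <- c(rep(95, 10), rep(95, 9), 89, 95)
  info <- data.frame(mag_id = ids, sample_id = "S1",
                     completeness = completeness,
                     contamination = 1, species = species)
  makeMagSet(info, setNames(as.list(paste0("ctg_", ids)), ids))
}

test_that("species selection needs min_mags nearly complete MAGs", {
  mags <- pangMagSet()
  sel <- selectPangenomeSpecies(mags, pangenomeConfig(min_mags = 10))
  # exactly 10 qualifying -> included; 9 (one at 89% completeness) -> out
  expect_setequal(names(sel), "Species alpha")
  expect_length(sel[["Species alpha"]], 10L)
  sel9 <- selectPangenomeSpecies(mags, pangenomeConfig(min_mags = 9))
  expect_setequal(names(sel9), c("Species alpha", "Species beta"))
  # unassigned species never enters
  expect_false("" %in% names(sel9))
})

test_that("presence matrix is boolean per (cluster, MAG)", {
  mags <- pangMagSet()
  # two genes of Cluster_0 on the same MAG's contig, one on another
  cat <- parseClstr(c(
    ">Cluster 0",
    "0\t100aa, >ctg_m01_1... *",
    "1\t100aa, >ctg_m01_2... at 96.00%",
    "2\t100aa, >ctg_m02_1... at 96.00%",
    ">Cluster 1",
    "0\t100aa, >ctg_m03_1... *"))
  g2m <- mapGenesToMags(catalogueGenes(cat)$gene_id, mags)
  pm <- buildPresenceMatrix(sprintf("m%02d", 1:10), cat, g2m,
                            species = "Species alpha")
  p <- presenceMatrix(pm)
  expect_true(p["Cluster_0", "m01"])       # two member genes, one cell
  expect_true(p["Cluster_0", "m02"])
  expect_equal(sum(p["Cluster_0", ]), 2L)
  expect_equal(sum(p["Cluster_1", ]), 1L)
})

test_that("presence matrix equals a brute-force membership scan", {
  sim <- simulateCommunity(simulationConfig(seed = 8, n_species = 2,
                                            mags_per_species = c(6, 6),
                                            core_pool = 25,
                                            accessory_pool = 25,
                                            sequences = FALSE))
  b <- sim$bundle
  g <- catalogueGenes(b$catalogue)
  g2m <- mapGenesToMags(g$gene_id, b$mags)
  sp <- sim$manifest$species[[1]]
  pm <- presenceMatrix(buildPresenceMatrix(sp$mags, b$catalogue, g2m,
                                           sp$name))
  for (cl in rownames(pm)) for (m in colnames(pm)) {
    genes <- g$gene_id[g$cluster_id == cl]
    expect_identical(unname(pm[cl, m]),
                     any(!is.na(g2m[genes]) & g2m[genes] == m))
  }
})

test_that("core calls use the inclusive >= 90% presence boundary", {
  mk <- function(n_present, n_mags = 10) {
    p <- matrix(FALSE, 1, n_mags,
                dimnames = list("Cluster_0", paste0("m", 1:n_mags)))
    p[1, seq_len(n_present)] <- TRUE
    new("PresenceMatrix", species = "sp", presence = p)
  }
  expect_equal(coreClusters(classifyCoreAccessory(mk(9))), "Cluster_0")
  expect_equal(accessoryClusters(classifyCoreAccessory(mk(8))),
               "Cluster_0")
  expect_equal(coreClusters(classifyCoreAccessory(mk(10))), "Cluster_0")
  expect_error(classifyCoreAccessory(mk(3, 5)), "min_mags")
  # raising core_fraction never grows the core
  pg90 <- classifyCoreAccessory(mk(9), pangenomeConfig(core_fraction = .9))
  pg95 <- classifyCoreAccessory(mk(9), pangenomeConfig(core_fraction = .95))
  expect_true(all(coreClusters(pg95) %in% coreClusters(pg90)))
})

test_that("core and accessory partition the observed clusters", {
  set.seed(71)
  p <- matrix(runif(200) < 0.6, nrow = 20,
              dimnames = list(paste0("Cluster_", 1:20), paste0("m", 1:10)))
  p[rowSums(p) == 0, 1] <- TRUE
  pg <- classifyCoreAccessory(new("PresenceMatrix", species = "sp",
                                  presence = p))
  expect_setequal(c(coreClusters(pg), accessoryClusters(pg)), rownames(p))
  expect_length(intersect(coreClusters(pg), accessoryClusters(pg)), 0L)
})

test_that("shared/unique accessory split follows the pangenome rule", {
  mkpg <- function(sp, core, acc) new("Pangenome", species = sp,
                                      core = core, accessory = acc,
                                      nMags = 10L)
  p1 <- mkpg("sp1", "c_core1", c("a1", "a2", "a_shared"))
  p2 <- mkpg("sp2", "c_core2", c("a_shared", "b1"))
  p3 <- mkpg("sp3", c("a2"), c("b2"))
  su <- sharedUniqueAccessory(list(p1, p2, p3))
  row1 <- su[su$species == "sp1", ]
  # a_shared is accessory in sp2; a2 is core in sp3 and still counts
  expect_equal(row1$shared, 2L)
  expect_equal(row1$unique, 1L)
  expect_equal(row1$shared + row1$unique, row1$accessory)
  # strict accessory-vs-accessory mode ignores sp3's core copy of a2
  strict <- sharedUniqueAccessory(list(p1, p2, p3),
                                  mode = "accessory_only")
  expect_equal(strict$shared[strict$species == "sp1"], 1L)
})

test_that("shared/unique matches a set-operation oracle on 4 species", {
  set.seed(72)
  pool <- paste0("cl", 1:120)
  pgs <- lapply(1:4, function(i) {
    draw <- sample(pool, 50)
    new("Pangenome", species = paste0("sp", i),
        core = draw[1:20], accessory = draw[21:50], nMags = 10L)
  })
  su <- sharedUniqueAccessory(pgs)
  for (i in 1:4) {
    acc <- accessoryClusters(pgs[[i]])
    others <- unique(unlist(lapply(pgs[-i], function(q)
      union(coreClusters(q), accessoryClusters(q)))))
    expect_equal(su$shared[i], length(intersect(acc, others)))
    expect_equal(su$unique[i], length(setdiff(acc, others)))
    expect_equal(su$shared[i] + su$unique[i], length(acc))
  }
})

test_that("pangenome summary reports sizes, known-function splits and r", {
  mkpg <- function(i, n_clusters) new(
    "Pangenome", species = paste0("sp", i),
    core = paste0("sp", i, "_c", seq_len(n_clusters %/% 2)),
    accessory = paste0("sp", i, "_a", seq_len(n_clusters - n_clusters %/% 2)),
    nMags = as.integer(10 * i))
  # exactly linear: size = 100 x n_mags -> r = 1
  pgs <- lapply(1:4, function(i) mkpg(i, 1000 * i))
  out <- pangenomeSummary(pgs)
  expect_equal(out$pearson_r, 1.0)
  expect_equal(out$summary$pangenome, c(1000, 2000, 3000, 4000))
  # annotated stratification
  ann <- list(m1 = c("sp1_c1", "sp1_c2", "sp1_a1"))
  out2 <- pangenomeSummary(pgs, ann)
  expect_equal(out2$summary$m1_core_known[1], 2L)
  expect_equal(out2$summary$m1_accessory_known[1], 1L)
  # duplicated sizes and MAG counts -> zero variance -> r undefined
  same <- list(mkpg(1, 100), mkpg(1, 100), mkpg(1, 100))
  expect_message(out3 <- pangenomeSummary(same), "undefined")
  expect_true(is.na(out3$pearson_r))
})

test_that("pangenome size-vs-MAGs correlation matches the sum formula", {
  set.seed(73)
  pgs <- lapply(1:8, function(i) {
    n <- sample(10:40, 1)
    new("Pangenome", species = paste0("sp", i),
        core = paste0("s", i, "c", seq_len(sample(50:200, 1))),
        accessory = paste0("s", i, "a", seq_len(sample(100:400, 1))),
        nMags = as.integer(n))
  })
  out <- pangenomeSummary(pgs)
  expect_equal(out$pearson_r,
               pearsonSums(out$summary$pangenome, out$summary$n_mags))
})

test_that("pangenome membership and presence tables serialize", {
  p <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
              dimnames = list(c("Cluster_0", "Cluster_1"), c("m1", "m2")))
  pm <- new("PresenceMatrix", species = "sp", presence = p)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePresenceMatrix(pm, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(as.logical(as.matrix(back[-1])), as.logical(p))
  pgs <- list(new("Pangenome", species = "sp1", core = "c1",
                  accessory = c("a1", "a2"), nMags = 10L),
              new("Pangenome", species = "sp2", core = "a1",
                  accessory = "b1", nMags = 12L))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePangenomeTable(pgs, f2)
  tab <- read.delim(f2, na.strings = NULL)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$sharing[tab$cluster_id == "a1" & tab$species == "sp1"],
               "shared")
})
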