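test_that("loocv is deterministic under a seed and records sane ranks", {
  syn <- smallSynth(seed = 13)
  spec <- weightingSpec(k = 4)
  r1 <- suppressMessages(loocv(syn$dataset, "aspA", spec, seed = 5))
  r2 <- suppressMessages(loocv(syn$dataset, "aspA", spec, seed = 5))
  expect_identical(cvRanks(r1), cvRanks(r2))
  expect_identical(cvMedians(r1), cvMedians(r2))
  expect_true(all(cvRanks(r1)$rank >= 1))
  expect_true(all(cvRanks(r1)$rank <= cvRanks(r1)$pool_size))
  expect_equal(nrow(cvRanks(r1)), nrow(cvMedians(r1)) * 3L)
  r3 <- suppressMessages(loocv(syn$dataset, "aspA", spec, seed = 6))
  expect_false(identical(cvRanks(r1)$hidden_gene, cvRanks(r3)$hidden_gene))
})

test_that("hiding a gene also hides every orthogroup containing it", {
  # target phenotype in A: a1, a2 (paralogs in G1) and a3 (G2); the B
  # neighbour covers both orthogroups. Hiding a1 must drop all of G1 from
  # the target column, leaving overlap v = 1 (G2 only).
  rows <- orthoRows("G1", "A", "a1", "G1", "A", "a2", "G1", "B", "b1",
                    "G2", "A", "a3", "G2", "B", "b2",
                    "G3", "A", "a4", "G3", "B", "b3")
  om <- OrthologyMap(rows, "A", "B")
  assoc <- rbind(assocSet("A", "target", "t", c("a1", "a2", "a3")),
                 assocSet("B", "nb", "n", c("b1", "b2", "b3")))
  ds <- phenologDataset(assoc, list(om), minGenes = 1L)
  pl <- phenologPredict(ds, "target", "A",
                        weightingSpec(k = 1, distanceMeasure = "hypergeom"),
                        maskGenes = "a1")
  nb <- neighbors(pl)
  expect_equal(nb$v, 1)          # G1 fully masked despite a2 being annotated
  expect_equal(nb$m, 1)          # masked target column holds only G2
  plFull <- phenologPredict(ds, "target", "A",
                            weightingSpec(k = 1,
                                          distanceMeasure = "hypergeom"))
  expect_equal(neighbors(plFull)$v, 2)
})

test_that("the leakage audit passes during loocv", {
  syn <- smallSynth(seed = 21, expansionMean = 2, retention = 0.9)
  rep <- suppressMessages(loocv(syn$dataset, "aspB", weightingSpec(k = 3),
                                seed = 2, audit = TRUE))
  expect_true(rep@audit)
})

test_that("recoveryCurve counts phenotypes at or below each rank", {
  mk <- function(med) data.frame(median_rank = med)
  flat <- recoveryCurve(mk(rep(1, 7)), maxRank = 5)
  expect_equal(flat$count, rep(7, 5))
  zero <- recoveryCurve(mk(numeric()), maxRank = 4)
  expect_equal(zero$count, rep(0, 4))
  step <- recoveryCurve(mk(10), maxRank = 12)
  expect_equal(step$count, c(rep(0, 9), rep(1, 3)))
  expect_true(all(diff(recoveryCurve(mk(c(3, 8, 2, 90)), 100)$count) >= 0))
})

test_that("randomizeMatrix preserves column cardinalities deterministically", {
  tab <- rbind(assocSet("m", "p1", "x", c("g1", "g2", "g3")),
               assocSet("m", "p2", "x", c("g2", "g4")))
  pm <- buildMatrix(tab, "genes", universe = paste0("g", 1:10))
  r1 <- randomizeMatrix(pm, seed = 4)
  r2 <- randomizeMatrix(pm, seed = 4)
  expect_equal(Matrix::colSums(incidence(r1)), Matrix::colSums(incidence(pm)))
  expect_identical(as.matrix(incidence(r1)), as.matrix(incidence(r2)))
  # a column covering the whole universe is forced to stay itself
  full <- buildMatrix(assocSet("m", "p", "x", c("g1", "g2")), "genes",
                      universe = c("g1", "g2"))
  expect_equal(as.matrix(incidence(randomizeMatrix(full, 1))),
               as.matrix(incidence(full)))
})

test_that("randomizeAssociations keeps per-phenotype sizes", {
  syn <- smallSynth(seed = 8)
  rnd <- randomizeAssociations(syn$dataset, seed = 9)
  a0 <- associations(syn$dataset); a1 <- associations(rnd)
  k0 <- paste(a0$species, a0$phenotype_id)
  k1 <- paste(a1$species, a1$phenotype_id)
  expect_equal(sort(unique(k0)), sort(unique(k1)))
  keys <- sort(unique(k0))
  expect_equal(as.integer(table(k1)[keys]), as.integer(table(k0)[keys]))
})

test_that("nfoldCv yields perfect AUROC for a planted perfect signal", {
  # 1:1 orthology where the B neighbour phenotype equals the target exactly:
  # every withheld gene is recovered at the top
  rows <- orthoRows()
  for (i in 1:20)
    rows <- rbind(rows, orthoRows(paste0("G", i), "A", paste0("a", i),
                                  paste0("G", i), "B", paste0("b", i)))
  om <- OrthologyMap(rows, "A", "B")
  assoc <- rbind(assocSet("A", "target", "t", paste0("a", 1:6)),
                 assocSet("B", "mirror", "m", paste0("b", 1:6)))
  ds <- phenologDataset(assoc, list(om), minGenes = 1L)
  res <- nfoldCv(ds, "A", weightingSpec(k = 1, includeWithinSpecies = FALSE,
                                        distanceMeasure = "hypergeom"),
                 folds = 3, seed = 3)
  expect_equal(res$perPhenotype$auroc, 1.0)
  expect_equal(res$perPhenotype$n_pos, 6L)
  pr <- res$curves[[1]]$pr
  expect_equal(pr$precision[which(pr$recall == 1)[1]], 1.0)
})

test_that("AUROC and average precision agree with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (rep in 1:5) {
    scores <- sample(c(0, runif(8)), 60, replace = TRUE)
    labels <- runif(60) < 0.3
    if (!any(labels) || all(labels)) next
    got <- phenologr:::.aurocScores(scores, labels)
    want <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                          direction = "<"))))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("random scores give near-0.5 AUROC", {
  set.seed(10)
  aucs <- replicate(200, {
    scores <- runif(100)
    labels <- seq_len(100) <= 10
    phenologr:::.aurocScores(scores, labels)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("speciesAblation restricts the neighbour pool per subset", {
  syn <- smallSynth(seed = 17)
  spec <- weightingSpec(k = 4, includeWithinSpecies = TRUE)
  ab <- suppressMessages(speciesAblation(
    syn$dataset, "aspA", spec,
    subsets = list(all = c("aspA", "aspB", "aspC"), bOnly = "aspB"),
    repeats = 2, seed = 3, maxRank = 50))
  expect_named(ab$reports, c("all", "bOnly"))
  # same evaluation set for both subsets
  expect_identical(cvMedians(ab$reports$all)$phenotype_id,
                   cvMedians(ab$reports$bOnly)$phenotype_id)
  expect_true(all(diff(ab$curves$all$count) >= 0))
  expect_error(
    speciesAblation(syn$dataset, "aspA", spec, subsets = list("nosuch")),
    "unknown species")
  expect_error(
    speciesAblation(syn$dataset, "aspA", spec, subsets = list(character())),
    "empty species subset")
})
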