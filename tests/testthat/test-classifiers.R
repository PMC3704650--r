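test_that("fractionF and weightFromMeasure follow their definitions", {
  expect_equal(fractionF(2, 4), 0.5)
  expect_equal(fractionF(0, 5), 0)
  expect_equal(fractionF(3, 3), 1)
  expect_error(fractionF(1, 0), "domain error")
  expect_error(fractionF(4, 3), "domain error")

  expect_equal(weightFromMeasure(0.01, "hypergeom"), 0.99)
  expect_equal(weightFromMeasure(-0.3, "pearson"), 0)
  expect_equal(weightFromMeasure(0.4, "tanimoto"), 0.4)
  expect_equal(weightFromMeasure(0.4, "cosine"), 0.4)
  expect_equal(weightFromMeasure(3, "manhattan"), 0.25)
  expect_equal(weightFromMeasure(1, "euclidean"), 0.5)
  expect_error(weightFromMeasure(0.5, "nope"), "configuration error")
})

test_that("scoreAdditive matches the hand-worked example and edge cases", {
  nb <- list(list(elements = c("g1", "g2"), weight = 0.5),
             list(elements = c("g2", "g3"), weight = 0.25))
  s <- scoreAdditive(nb)
  expect_equal(s[["g1"]], 0.5)
  expect_equal(s[["g2"]], 0.75)
  expect_equal(s[["g3"]], 0.25)

  zero <- scoreAdditive(lapply(nb, function(x) { x$weight <- 0; x }))
  expect_true(all(zero == 0))

  single <- scoreAdditive(nb[1], elements = c("g1", "g2", "g9"))
  expect_equal(unname(single[c("g1", "g2", "g9")]), c(0.5, 0.5, 0))
})

test_that("additive scoring equals a double-loop oracle and is linear", {
  set.seed(23)
  for (rep in 1:10) {
    elems <- paste0("g", 1:30)
    nb <- lapply(seq_len(sample(2:8, 1)), function(i)
      list(elements = sample(elems, sample(1:10, 1)),
           weight = runif(1, 0, 2)))
    got <- scoreAdditive(nb, elements = elems)
    want <- setNames(numeric(length(elems)), elems)
    for (x in nb) for (e in unique(x$elements))
      want[e] <- want[e] + x$weight
    expect_equal(got, want, tolerance = 1e-12)
    # linearity: doubling all weights doubles all scores
    nb2 <- lapply(nb, function(x) { x$weight <- 2 * x$weight; x })
    expect_equal(scoreAdditive(nb2, elements = elems), 2 * got,
                 tolerance = 1e-12)
  }
})

test_that("naive Bayes scoring follows 1 - prod(1 - f w)", {
  one <- scoreNaiveBayes(list(list(elements = "g", f = 0.5, weight = 0.4)))
  expect_equal(one[["g"]], 0.2, tolerance = 1e-12)     # single term = f w

  two <- scoreNaiveBayes(list(
    list(elements = "g", f = 0.5, weight = 0.4),
    list(elements = "g", f = 0.4, weight = 0.5)))
  expect_equal(two[["g"]], 1 - 0.8^2, tolerance = 1e-12)

  none <- scoreNaiveBayes(list(list(elements = "a", f = 0.5, weight = 0.5)),
                          elements = c("a", "b"))
  expect_equal(none[["b"]], 0)

  # a certain phenolog saturates the score
  sat <- scoreNaiveBayes(list(list(elements = "g", f = 1, weight = 1)))
  expect_equal(sat[["g"]], 1)

  expect_error(scoreNaiveBayes(list(list(elements = "g", f = 2, weight = 1))),
               "\\[0, 1\\]")
})

test_that("adding a covering neighbour strictly increases naive Bayes scores", {
  set.seed(9)
  for (rep in 1:10) {
    nb <- lapply(1:4, function(i)
      list(elements = sample(letters[1:10], 4), f = runif(1, 0.05, 0.9),
           weight = runif(1, 0.05, 0.9)))
    base <- scoreNaiveBayes(nb, elements = letters[1:10])
    extra <- list(elements = c("a", "b"), f = 0.3, weight = 0.5)
    more <- scoreNaiveBayes(c(nb, list(extra)), elements = letters[1:10])
    expect_true(all(more[c("a", "b")] > base[c("a", "b")]))
    expect_equal(more[letters[3:10]], base[letters[3:10]])
    expect_true(all(more >= 0 & more <= 1))
  }
})

test_that("prediction ranks conserve the rank sum including tie groups", {
  set.seed(77)
  for (rep in 1:20) {
    P <- sample(5:200, 1)
    scores <- sample(c(0, runif(5)), P, replace = TRUE)
    r <- rank(-scores, ties.method = "average")
    expect_equal(sum(r), P * (P + 1) / 2)
  }
  syn <- smallSynth(seed = 3)
  pl <- phenologPredict(syn$dataset, "aspA_ph001", "aspA",
                        weightingSpec(k = 5))
  p <- predictions(pl)
  expect_equal(sum(p$rank), nrow(p) * (nrow(p) + 1) / 2)
  # genes with equal score share the mean rank
  byScore <- split(p$rank, p$score)
  expect_true(all(vapply(byScore, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("phenologPredict integrates neighbours and flags known orthogroups", {
  rows <- orthoRows()
  for (i in 1:8)
    rows <- rbind(rows, orthoRows(paste0("G", i), "A", paste0("a", i),
                                  paste0("G", i), "B", paste0("b", i)))
  # a paralog a1b sits in G1 next to a1
  rows <- rbind(rows, orthoRows("G1", "A", "a1b"))
  om <- OrthologyMap(rows, "A", "B")
  assoc <- rbind(
    assocSet("A", "target", "t", c("a1", "a2", "a3")),
    assocSet("B", "nb", "n", c("b1", "b2", "b4")))
  ds <- phenologDataset(assoc, list(om), minGenes = 1L)
  pl <- phenologPredict(ds, "target", "A",
                        weightingSpec(k = 1, classifier = "additive"))
  p <- predictions(pl)
  # neighbour members map to target genes: orthogroups G1, G2, G4 -> genes
  up <- p$gene_id[p$score > 0]
  expect_setequal(up, c("a1", "a1b", "a2", "a4"))
  # known flag covers annotated genes and their orthogroup mates
  expect_true(all(p$known[p$gene_id %in% c("a1", "a1b", "a2", "a3")]))
  expect_false(any(p$known[p$gene_id %in% c("a4", "a5")]))
  # a neighbour sharing no orthogroups contributes nothing
  assoc2 <- rbind(assoc, assocSet("B", "far", "f", c("b7", "b8")))
  ds2 <- phenologDataset(assoc2, list(om), minGenes = 1L)
  pl2 <- phenologPredict(ds2, "target", "A",
                         weightingSpec(k = 10, classifier = "additive",
                                       distanceMeasure = "hypergeom"))
  co <- contributions(pl2)
  farKey <- grep("far", unique(co$neighbor), value = TRUE)
  expect_false(any(co$gene_id[co$neighbor %in% farKey] %in%
                     c("a1", "a2", "a3")))
})

test_that("gene-based and orthogroup pipelines coincide under 1:1 orthology", {
  for (seed in c(101, 202)) {
    syn <- smallSynth(seed, expansionMean = 1, retention = 1)
    for (classifier in c("additive", "naive_bayes")) {
      sg <- weightingSpec(k = 6, classifier = classifier, framework = "gene")
      so <- weightingSpec(k = 6, classifier = classifier,
                          framework = "orthogroup")
      plG <- phenologPredict(syn$dataset, "aspA_ph001", "aspA", sg)
      plO <- phenologPredict(syn$dataset, "aspA_ph001", "aspA", so)
      expect_equal(predictions(plG), predictions(plO), tolerance = 1e-12)
      expect_identical(neighbors(plG)$key, neighbors(plO)$key)
    }
  }
})

test_that("decomposeContributions is exact for the additive classifier", {
  syn <- smallSynth(seed = 5)
  pl <- phenologPredict(syn$dataset, "aspA_ph001", "aspA",
                        weightingSpec(k = 6, classifier = "additive"))
  dec <- decomposeContributions(pl, topN = 3L)
  numCols <- setdiff(names(dec), c("gene_id", "score"))
  expect_true("below_top_n" %in% names(dec))           # k > topN
  rowsums <- rowSums(dec[numCols])
  expect_equal(rowsums, dec$score, tolerance = 1e-12,
               ignore_attr = TRUE)
  # topN >= k leaves no remainder bucket
  decAll <- decomposeContributions(pl, topN = 50L)
  expect_false("below_top_n" %in% names(decAll))
  # naive Bayes decomposition is flagged
  plNb <- phenologPredict(syn$dataset, "aspA_ph001", "aspA",
                          weightingSpec(k = 6))
  expect_message(decomposeContributions(plNb), "not additive")
})
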