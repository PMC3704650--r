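test_that("readAssociations de-duplicates and validates", {
  p <- writeTsv(assocRows("m", "ph1", "x", "g1",
                          "m", "ph1", "x", "g1",
                          "m", "ph1", "x", "g2"))
  tab <- readAssociations(p)
  expect_equal(nrow(tab), 2L)

  # empty file -> empty table with the right columns
  p2 <- tempfile(); writeLines(character(), p2)
  expect_equal(nrow(readAssociations(p2)), 0L)

  # empty gene_id is a parse error
  p3 <- tempfile()
  writeLines(c("species\tphenotype_id\tphenotype_name\tgene_id",
               "m\tph1\tx\t"), p3)
  expect_error(readAssociations(p3), "parse error")

  # missing column is a parse error
  p4 <- tempfile()
  writeLines(c("species\tphenotype_id\tgene_id", "m\tph1\tg1"), p4)
  expect_error(readAssociations(p4), "missing column")

  expect_equal(unique(readAssociations(p, sourceLabel = "green-broad")$source_label),
               "green-broad")
})

test_that("filterMinGenes applies the inclusive >= minimum rule idempotently", {
  tab <- assocRows("m", "small", "x", "g1",
                   "m", "small", "x", "g2",
                   "m", "okay", "x", "g1",
                   "m", "okay", "x", "g2",
                   "m", "okay", "x", "g3")
  out <- filterMinGenes(tab, 3L)
  expect_setequal(unique(out$phenotype_id), "okay")   # 2-gene dropped
  expect_equal(nrow(out), 3L)                         # exactly 3 retained
  expect_identical(filterMinGenes(out, 3L), out)      # idempotent
  expect_identical(filterMinGenes(tab, 1L), tab)      # minimum 1 = identity
  expect_error(filterMinGenes(tab, 0L), "minimum")
})

test_that("filterEvidenceCodes keeps curated codes and drops NOT/IEA", {
  gaf <- data.frame(
    gene_id  = c("g1", "g2", "g3", "g3", "g4"),
    qualifier = c("", "", "", "", "NOT"),
    term = c("GO:1", "GO:1", "GO:2", "GO:2", "GO:3"),
    evidence = c("IEA", "IMP", "IMP", "IDA", "IMP"),
    stringsAsFactors = FALSE)
  out <- filterEvidenceCodes(gaf, species = "zebrafish")
  expect_false("g1" %in% out$gene_id)                 # IEA removed
  expect_true("g2" %in% out$gene_id)                  # IMP retained
  expect_equal(sum(out$gene_id == "g3"), 1L)          # IMP+IDA de-duplicated
  expect_false("g4" %in% out$gene_id)                 # NOT qualifier dropped
  expect_equal(unique(out$species), "zebrafish")
  expect_equal(unique(out$phenotype_id[out$gene_id == "g2"]), "GO:1")

  gaf$evidence[1] <- "XYZ"
  expect_warning(filterEvidenceCodes(gaf), "unknown evidence")
})

test_that("readGaf consumes tab-separated records and skips comments", {
  p <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "geneX", "SYM", "", "GO:0001", "ref", "IMP", "",
                     "P", sep = "\t")), p)
  g <- readGaf(p)
  expect_equal(g$gene_id, "geneX")
  expect_equal(g$evidence, "IMP")
})

test_that("profileToPhenotypes assigns top and bottom conditions", {
  mk <- function(nGenes, nCond, seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * nCond), nGenes,
                dimnames = list(paste0("g", 1:nGenes),
                                sprintf("c%03d", 1:nCond)))
    m
  }
  out <- profileToPhenotypes(mk(3, 100), species = "ecoli")
  expect_true(all(table(out$gene_id) == 80))          # 40 top + 40 bottom

  out60 <- profileToPhenotypes(mk(2, 60))
  expect_true(all(table(out60$gene_id) == 60))        # overlap covers all

  out10 <- profileToPhenotypes(mk(2, 10))
  expect_true(all(table(out10$gene_id) == 10))

  # deterministic under score ties: all-equal scores pick conditions by id
  m <- matrix(0, 1, 6, dimnames = list("g", c("b", "a", "d", "c", "f", "e")))
  tied <- profileToPhenotypes(m, topK = 2L, bottomK = 2L)
  expect_setequal(tied$phenotype_id, c("a", "b"))

  m2 <- matrix(c(1, NA), 1, 2, dimnames = list("g", c("x", "y")))
  expect_error(profileToPhenotypes(m2), "parse error")
})

test_that("profile association counts never exceed min(conditions, topK+bottomK)", {
  set.seed(3)
  for (rep in 1:5) {
    nc <- sample(5:120, 1)
    m <- matrix(sample(c(-2, 0, 1, 5), 4 * nc, replace = TRUE), 4,
                dimnames = list(paste0("g", 1:4), sprintf("c%04d", 1:nc)))
    out <- profileToPhenotypes(m, topK = 40L, bottomK = 40L)
    expect_true(all(table(out$gene_id) <= min(nc, 80)))
  }
})

test_that("expandLocationStage applies strict location and stage thresholds", {
  mkAnn <- function(nLoc, nStage, loc = "heart", stage = "10") {
    rbind(
      data.frame(gene = paste0("g", seq_len(nLoc)), location = loc,
                 stage = "", stringsAsFactors = FALSE),
      if (nStage > 0)
        data.frame(gene = paste0("g", seq_len(nStage)), location = loc,
                   stage = stage, stringsAsFactors = FALSE))
  }
  # 60-gene location with a 5-gene stage -> location + stage phenotype
  out <- expandLocationStage(mkAnn(60, 5), species = "chicken")
  expect_true("heart" %in% out$phenotype_id)
  expect_true("heart at stage 10" %in% out$phenotype_id)
  expect_equal(sum(out$phenotype_id == "heart at stage 10"), 5L)

  # 40-gene location -> no stage phenotypes even with a big stage
  out2 <- expandLocationStage(mkAnn(40, 5))
  expect_false(any(grepl("at stage", out2$phenotype_id)))

  # stage with exactly 3 genes at a big location -> strictly greater required
  out3 <- expandLocationStage(mkAnn(60, 3))
  expect_false(any(grepl("at stage", out3$phenotype_id)))

  # exactly 50 genes at a location is not "more than fifty"
  out4 <- expandLocationStage(mkAnn(50, 5))
  expect_false(any(grepl("at stage", out4$phenotype_id)))
})

test_that("buildMatrix produces the two matrix framings of the same data", {
  om <- expansionMap()
  # gene-based human rows: the mouse phenotype translates into 3 human genes
  trM <- translateGeneBased(assocRows("mouse", "phm", "p", "Am"),
                            "mouse", "human", om)
  gm <- buildMatrix(trM, "genes")
  expect_equal(unname(phenotypeInfo(gm)$cardinality), 3)

  # orthogroup rows: the same phenotype has a single entry
  prM <- projectToOrthogroups(assocRows("mouse", "phm", "p", "Am"), om)
  ogm <- buildMatrix(prM, "orthogroups", map = om)
  expect_equal(unname(phenotypeInfo(ogm)$cardinality), 1)
  expect_equal(nrow(incidence(ogm)), nOrthogroups(om))  # zero rows included

  # plain 2 genes x 1 phenotype
  m <- buildMatrix(assocRows("m", "ph", "x", "g1", "m", "ph", "x", "g2"),
                   "genes")
  expect_equal(unname(phenotypeInfo(m)$cardinality), 2)

  # total incidence equals distinct (element, phenotype) pairs
  tab <- assocRows("m", "p1", "x", "g1", "m", "p1", "x", "g2",
                   "m", "p2", "x", "g1")
  expect_equal(sum(incidence(buildMatrix(tab, "genes"))), 3)

  # genes outside a fixed universe are dropped with a message
  expect_message(
    small <- buildMatrix(tab, "genes", universe = c("g1")),
    "dropped")
  expect_equal(nrow(incidence(small)), 1L)
})
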