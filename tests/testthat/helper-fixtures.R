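# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except through the readers under test.

# write a TSV with header to a temp file, return the path
writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

orthoRows <- function(...) {
  args <- c(...)
  if (!length(args))
    return(data.frame(orthogroup_id = character(), species = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  m <- matrix(args, ncol = 3, byrow = TRUE)
  data.frame(orthogroup_id = m[, 1], species = m[, 2], gene_id = m[, 3],
             stringsAsFactors = FALSE)
}

assocRows <- function(...) {
  args <- c(...)
  stopifnot(length(args) %% 4 == 0)
  m <- matrix(args, ncol = 4, byrow = TRUE)
  data.frame(species = m[, 1], phenotype_id = m[, 2], phenotype_name = m[, 3],
             gene_id = m[, 4], stringsAsFactors = FALSE)
}

# one phenotype with a whole gene set
assocSet <- function(species, phenotype, name, genes) {
  data.frame(species = species, phenotype_id = phenotype,
             phenotype_name = name, gene_id = genes, stringsAsFactors = FALSE)
}

# the paralog-expansion example: orthogroup OA has three human paralogs and
# one mouse gene; OB is 1:1; the mouse phenotype "phm" annotates both mouse
# genes, the human phenotype "phh" annotates Ah and Bh
expansionMap <- function() {
  OrthologyMap(orthoRows(
    "OA", "human", "Ah",
    "OA", "human", "Ah2",
    "OA", "human", "Ah3",
    "OA", "mouse", "Am",
    "OB", "human", "Bh",
    "OB", "mouse", "Bm"), "human", "mouse")
}

expansionAssoc <- function() {
  assocRows(
    "mouse", "phm", "mouse phenotype", "Am",
    "mouse", "phm", "mouse phenotype", "Bm",
    "human", "phh", "human phenotype", "Ah",
    "human", "phh", "human phenotype", "Bh")
}

# small synthetic world; expansion/retention arguments control 1:1 vs paralog
# regimes
smallSynth <- function(seed, expansionMean = 1, retention = 1) {
  generateSynthData(synthConfig(
    species = c("aspA", "aspB", "aspC"),
    nOrthogroups = 60L, expansionMean = expansionMean,
    orthologRetention = retention, nModules = 2L, moduleSize = 10L,
    phenotypesPerModule = 2L, signalFraction = 0.5,
    backgroundPhenotypes = 2L, phenotypeSizeRange = c(3L, 6L), seed = seed))
}

# the planted-structure benchmark used by the heavier evaluation tests
benchSynth <- function(seed) {
  generateSynthData(synthConfig(
    nOrthogroups = 500L, nModules = 5L, moduleSize = 20L,
    phenotypesPerModule = 6L, signalFraction = 0.6,
    phenotypeSizeRange = c(5L, 15L), seed = seed))
}

# exhaustive hypergeometric tail by enumerating all n-subsets of 1..N against
# the fixed m-set 1..m
enumHyperTail <- function(v, m, n, N) {
  if (n == 0) return(as.numeric(v <= 0))
  sets <- combn(N, n)
  mean(colSums(sets <= m) >= v)
}
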