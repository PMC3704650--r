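#' Configuration for the synthetic phenolog benchmark generator
#'
#' Describes a multi-species world with planted deep homology: a set of
#' ancestral orthogroups instantiated in each species with lineage-specific
#' paralog expansions (geometric family sizes, support >= 1) and random
#' orthogroup loss; a number of conserved gene modules (disjoint blocks of
#' orthogroups); and per-species phenotypes that draw most of their genes
#' from one module (the planted phenolog structure) plus uniform background.
#'
#' @param species species names (>= 2).
#' @param nOrthogroups number of ancestral orthogroups.
#' @param expansionMean expected paralogs per orthogroup per species (>= 1);
#'   family sizes are 1 + Geometric so the mean is `expansionMean`.
#' @param orthologRetention probability an orthogroup keeps a member in a
#'   given species.
#' @param nModules number of conserved modules.
#' @param moduleSize orthogroups per module (modules are disjoint).
#' @param phenotypesPerModule module-linked phenotypes per module per species.
#' @param signalFraction fraction of a phenotype's genes drawn from its
#'   module's orthogroups (the rest are uniform background).
#' @param backgroundPhenotypes unstructured phenotypes per species.
#' @param phenotypeSizeRange inclusive (min, max) genes per phenotype;
#'   min >= 3 so every phenotype survives the minimum-gene filter.
#' @param seed RNG seed.
#' @return A validated `SynthConfig` list.
#' @export
synthConfig <- function(species = c("anolis", "bombina", "ciona", "danio"),
                        nOrthogroups = 500L,
                        expansionMean = 1.5,
                        orthologRetention = 0.9,
                        nModules = 5L,
                        moduleSize = 20L,
                        phenotypesPerModule = 6L,
                        signalFraction = 0.6,
                        backgroundPhenotypes = 10L,
                        phenotypeSizeRange = c(5L, 15L),
                        seed = 1L) {
  cfg <- list(species = as.character(species),
              nOrthogroups = as.integer(nOrthogroups),
              expansionMean = as.numeric(expansionMean),
              orthologRetention = as.numeric(orthologRetention),
              nModules = as.integer(nModules),
              moduleSize = as.integer(moduleSize),
              phenotypesPerModule = as.integer(phenotypesPerModule),
              signalFraction = as.numeric(signalFraction),
              backgroundPhenotypes = as.integer(backgroundPhenotypes),
              phenotypeSizeRange = as.integer(phenotypeSizeRange),
              seed = as.integer(seed))
  if (length(cfg$species) < 2L || anyDuplicated(cfg$species))
    stop("configuration error: need >= 2 distinct species")
  if (cfg$expansionMean < 1)
    stop("configuration error: expansionMean must be >= 1")
  if (cfg$orthologRetention < 0 || cfg$orthologRetention > 1 ||
      cfg$signalFraction < 0 || cfg$signalFraction > 1)
    stop("configuration error: probabilities must lie in [0, 1]")
  if (length(cfg$phenotypeSizeRange) != 2L ||
      cfg$phenotypeSizeRange[1] < 3L ||
      cfg$phenotypeSizeRange[1] > cfg$phenotypeSizeRange[2])
    stop("configuration error: phenotypeSizeRange must be (min >= 3, max)")
  if (cfg$nModules * cfg$moduleSize > cfg$nOrthogroups)
    stop("configuration error: modules need more orthogroups than exist")
  if (ceiling(cfg$signalFraction * cfg$phenotypeSizeRange[2]) > cfg$moduleSize)
    stop("configuration error: module smaller than the required signal draw")
  class(cfg) <- "SynthConfig"
  cfg
}

#' Generate a synthetic multi-species phenolog benchmark
#'
#' Instantiates the world described by a [synthConfig()]: every ancestral
#' orthogroup is retained in each species with probability
#' `orthologRetention` and, where retained, carries `1 + Geometric` paralogs
#' with mean `expansionMean`. Pairwise orthology between any two species is
#' derived from the shared ancestral orthogroup id, so per-pair orthogroups
#' are consistent across all pairs. Module-linked phenotypes draw
#' `ceiling(signalFraction * size)` genes from their module's orthogroups
#' (one random paralog per drawn orthogroup) and the rest uniformly;
#' background phenotypes are entirely uniform. Deterministic under the
#' config seed.
#'
#' @param config a `SynthConfig`.
#' @return list with `dataset` (a [PhenologDataset-class]), `truth` (lists:
#'   `genes` gene/orthogroup table, `modules` orthogroup-to-module table,
#'   `phenotypes` phenotype-to-module table) and `config`.
#' @export
generateSynthData <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  sp <- config$species
  og <- sprintf("OG%04d", seq_len(config$nOrthogroups))

  ## per-species instantiation: retention + paralog counts
  geneRows <- list()
  for (s in sp) {
    kept <- og[stats::runif(length(og)) < config$orthologRetention]
    nPar <- 1L + stats::rgeom(length(kept), prob = 1 / config$expansionMean)
    geneRows[[s]] <- data.frame(
      species = s,
      orthogroup_id = rep(kept, nPar),
      gene_id = paste0(s, "_", rep(kept, nPar), "_p",
                       unlist(lapply(nPar, seq_len), use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, geneRows)
  rownames(genes) <- NULL

  ## modules: disjoint blocks of orthogroups
  moduleOf <- data.frame(
    orthogroup_id = og[seq_len(config$nModules * config$moduleSize)],
    module = rep(seq_len(config$nModules), each = config$moduleSize),
    stringsAsFactors = FALSE)

  sizeRange <- config$phenotypeSizeRange
  assoc <- list()
  phenTruth <- list()
  for (s in sp) {
    gs <- geneRows[[s]]
    byOg <- split(gs$gene_id, gs$orthogroup_id)
    allGenes <- gs$gene_id
    mkPhen <- function(id, name, module) {
      size <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
      chosen <- character()
      if (!is.na(module)) {
        modOgs <- intersect(
          moduleOf$orthogroup_id[moduleOf$module == module], names(byOg))
        nSig <- min(ceiling(config$signalFraction * size), length(modOgs))
        if (nSig > 0) {
          pick <- sample(modOgs, nSig)
          chosen <- vapply(byOg[pick], function(g)
            if (length(g) == 1L) g else sample(g, 1L), character(1))
        }
      }
      rest <- setdiff(allGenes, chosen)
      need <- size - length(chosen)
      if (need > 0) chosen <- c(chosen, sample(rest, min(need, length(rest))))
      data.frame(species = s, phenotype_id = id, phenotype_name = name,
                 gene_id = unname(chosen), stringsAsFactors = FALSE)
    }
    idx <- 0L
    for (mod in seq_len(config$nModules)) {
      for (q in seq_len(config$phenotypesPerModule)) {
        idx <- idx + 1L
        id <- sprintf("%s_ph%03d", s, idx)
        assoc[[length(assoc) + 1L]] <-
          mkPhen(id, sprintf("module %d phenotype %d of %s", mod, q, s), mod)
        phenTruth[[length(phenTruth) + 1L]] <- data.frame(
          species = s, phenotype_id = id, module = mod,
          stringsAsFactors = FALSE)
      }
    }
    for (q in seq_len(config$backgroundPhenotypes)) {
      idx <- idx + 1L
      id <- sprintf("%s_ph%03d", s, idx)
      assoc[[length(assoc) + 1L]] <-
        mkPhen(id, sprintf("background phenotype %d of %s", q, s), NA)
      phenTruth[[length(phenTruth) + 1L]] <- data.frame(
        species = s, phenotype_id = id, module = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  associations <- do.call(rbind, assoc)

  ## pairwise maps from the shared ancestral ids
  maps <- list()
  cmb <- utils::combn(sp, 2)
  for (q in seq_len(ncol(cmb))) {
    a <- cmb[1, q]; b <- cmb[2, q]
    ga <- geneRows[[a]]; gb <- geneRows[[b]]
    shared <- intersect(unique(ga$orthogroup_id), unique(gb$orthogroup_id))
    rows <- rbind(ga[ga$orthogroup_id %in% shared, ],
                  gb[gb$orthogroup_id %in% shared, ])
    maps[[length(maps) + 1L]] <-
      OrthologyMap(rows[c("orthogroup_id", "species", "gene_id")], a, b)
  }

  dataset <- phenologDataset(associations, maps, minGenes = 1L)
  truth <- list(genes = genes, modules = moduleOf,
                phenotypes = do.call(rbind, phenTruth))
  list(dataset = dataset, truth = truth, config = config)
}

#' Write synthetic fixtures to disk
#'
#' Emits the exact TSV dialects the readers consume: one orthology file per
#' species pair (`orthology_<a>_<b>.tsv`), one association file per species
#' (`associations_<s>.tsv`), and the ground truth
#' (`truth_genes.tsv`, `truth_modules.tsv`, `truth_phenotypes.tsv`). Output
#' is byte-identical for a given generated object.
#'
#' @param synth result of [generateSynthData()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
writeSynthData <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files <<- c(files, path)
  }
  for (map in synth$dataset@orthology) {
    pr <- map@speciesPair
    g <- map@groups[order(map@groups$orthogroup_id, map@groups$species,
                          map@groups$gene_id), ]
    emit(g, sprintf("orthology_%s_%s.tsv", pr[1], pr[2]))
  }
  a <- synth$dataset@associations
  for (s in sort(unique(a$species))) {
    as <- a[a$species == s, c("species", "phenotype_id", "phenotype_name",
                              "gene_id")]
    as <- as[order(as$phenotype_id, as$gene_id), ]
    emit(as, sprintf("associations_%s.tsv", s))
  }
  emit(synth$truth$genes[order(synth$truth$genes$species,
                               synth$truth$genes$gene_id), ], "truth_genes.tsv")
  emit(synth$truth$modules, "truth_modules.tsv")
  emit(synth$truth$phenotypes, "truth_phenotypes.tsv")
  invisible(files)
}

#' Summary counts of a synthetic benchmark
#'
#' @param synth result of [generateSynthData()].
#' @return list with `perSpecies` (gene count, orthogroup count, mean
#'   paralogs per orthogroup) and `phenotypeSizes` (per-phenotype
#'   cardinality).
#' @export
summarizeSynthData <- function(synth) {
  g <- synth$truth$genes
  perSpecies <- do.call(rbind, lapply(split(g, g$species), function(x)
    data.frame(species = x$species[1], n_genes = nrow(x),
               n_orthogroups = length(unique(x$orthogroup_id)),
               mean_paralogs = nrow(x) / length(unique(x$orthogroup_id)),
               stringsAsFactors = FALSE)))
  rownames(perSpecies) <- NULL
  a <- synth$dataset@associations
  key <- .phenKey(a$species, a$phenotype_id)
  sizes <- tapply(a$gene_id, key, function(x) length(unique(x)))
  phenotypeSizes <- data.frame(key = names(sizes),
                               cardinality = as.integer(sizes),
                               stringsAsFactors = FALSE)
  list(perSpecies = perSpecies, phenotypeSizes = phenotypeSizes)
}
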