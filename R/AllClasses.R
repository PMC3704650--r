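#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix colSums rowSums crossprod t
#' @importFrom stats phyper median setNames rgeom runif
#' @importFrom utils head write.table packageVersion
NULL

## internal key separator for (species, gene) and (species, phenotype) pairs;
## a control character so it can never collide with identifier text
.SEP <- "\r"

.geneKey <- function(species, gene) paste(species, gene, sep = .SEP)
.phenKey <- function(species, phenotype_id) paste(species, phenotype_id, sep = .SEP)
.pairKey <- function(a, b) paste(sort(c(a, b)), collapse = .SEP)
.splitKey <- function(key) strsplit(key, .SEP, fixed = TRUE)

#' OrthologyMap: pairwise orthogroups for one species pair
#'
#' Holds the orthogroups linking two species: sets of genes descending from a
#' single gene in the species' last common ancestor, as produced by pairwise
#' orthology inference. Within one species pair each gene belongs to at most
#' one orthogroup, and every orthogroup has at least one member gene on each
#' side. The pair is stored under a canonical (lexicographic) order so that
#' all lookups are symmetric in the order the two species are given.
#'
#' @slot speciesPair character(2), the two species, lexicographically sorted.
#' @slot groups data.frame with columns `orthogroup_id`, `species`, `gene_id`
#'   (one row per member gene).
#' @slot geneIndex named character vector mapping an internal (species, gene)
#'   key to the orthogroup id.
#' @slot sideMembers list with one entry per species, each a named list from
#'   orthogroup id to the character vector of member genes on that side.
#' @exportClass OrthologyMap
setClass("OrthologyMap", slots = c(
  speciesPair = "character",
  groups      = "data.frame",
  geneIndex   = "character",
  sideMembers = "list"
))

setValidity("OrthologyMap", function(object) {
  msgs <- character()
  pr <- object@speciesPair
  if (length(pr) != 2L || anyNA(pr) || pr[1] >= pr[2])
    msgs <- c(msgs, "speciesPair must be two distinct sorted species names")
  g <- object@groups
  if (!all(c("orthogroup_id", "species", "gene_id") %in% names(g)))
    msgs <- c(msgs, "groups must have orthogroup_id, species, gene_id columns")
  else {
    if (!all(g$species %in% pr))
      msgs <- c(msgs, "groups contains species outside speciesPair")
    key <- .geneKey(g$species, g$gene_id)
    if (anyDuplicated(key))
      msgs <- c(msgs, "a gene is assigned to more than one orthogroup")
    sides <- rowsum(+(g$species == pr[1]), g$orthogroup_id)
    tot <- rowsum(rep(1L, nrow(g)), g$orthogroup_id)
    if (nrow(g) && any(sides == 0 | sides == tot))
      msgs <- c(msgs, "every orthogroup must have >=1 gene on each side")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OrthologyMap from a membership table
#'
#' @param groups data.frame with columns `orthogroup_id`, `species`,
#'   `gene_id`; duplicated rows are collapsed.
#' @param speciesA,speciesB the two species names (order irrelevant).
#' @return An [OrthologyMap-class] object.
#' @examples
#' g <- data.frame(orthogroup_id = "G1", species = c("mouse", "human"),
#'                 gene_id = c("m1", "h1"))
#' om <- OrthologyMap(g, "human", "mouse")
#' nOrthogroups(om)
#' @export
OrthologyMap <- function(groups, speciesA, speciesB) {
  stopifnot(is.data.frame(groups))
  need <- c("orthogroup_id", "species", "gene_id")
  if (!all(need %in% names(groups)))
    stop("groups must have columns orthogroup_id, species, gene_id")
  pair <- sort(c(as.character(speciesA), as.character(speciesB)))
  if (pair[1] == pair[2]) stop("speciesA and speciesB must differ")
  g <- unique(data.frame(
    orthogroup_id = as.character(groups$orthogroup_id),
    species       = as.character(groups$species),
    gene_id       = as.character(groups$gene_id),
    stringsAsFactors = FALSE))
  bad <- setdiff(unique(g$species), pair)
  if (length(bad))
    stop("configuration error: species not in the declared pair: ",
         paste(bad, collapse = ", "))
  if (nrow(g)) {
    key <- .geneKey(g$species, g$gene_id)
    dup <- unique(g$gene_id[duplicated(key) | duplicated(key, fromLast = TRUE)])
    dup <- dup[!duplicated(dup)]
    ## duplicated (species,gene) across different orthogroups
    two <- tapply(g$orthogroup_id, key, function(x) length(unique(x)) > 1L)
    if (any(two))
      stop("integrity error: gene assigned to two orthogroups in one pair: ",
           paste(head(sub(.SEP, "/", names(two)[two], fixed = TRUE), 5),
                 collapse = ", "))
    sides <- tapply(g$species, g$orthogroup_id,
                    function(s) length(unique(s)))
    if (any(sides < 2L))
      stop("integrity error: orthogroup(s) with an empty side: ",
           paste(head(names(sides)[sides < 2L], 5), collapse = ", "))
    geneIndex <- setNames(g$orthogroup_id, key)
  } else {
    geneIndex <- setNames(character(), character())
  }
  sideMembers <- lapply(pair, function(sp) {
    gi <- g[g$species == sp, , drop = FALSE]
    split(gi$gene_id, gi$orthogroup_id)
  })
  names(sideMembers) <- pair
  new("OrthologyMap", speciesPair = pair, groups = g,
      geneIndex = geneIndex, sideMembers = sideMembers)
}

#' PhenotypeMatrix: binary element-by-phenotype incidence
#'
#' A binary incidence structure whose rows ("elements") are either the genes
#' of one species or the orthogroups of a species pair, and whose columns are
#' phenotypes. Entry (i, j) is 1 when element i carries phenotype j.
#'
#' @slot incidence a [Matrix::dgCMatrix-class] of 0/1 values; rownames are
#'   element ids, colnames are internal (species, phenotype) keys.
#' @slot elementKind `"genes"` or `"orthogroups"`.
#' @slot speciesScope the species owning the elements: length 1 for genes,
#'   length 2 (sorted) for orthogroups of a pair.
#' @slot phenotypeInfo data.frame with one row per column: `key`,
#'   `phenotype_id`, `species`, `phenotype_name`, `cardinality`.
#' @exportClass PhenotypeMatrix
setClass("PhenotypeMatrix", slots = c(
  incidence     = "dgCMatrix",
  elementKind   = "character",
  speciesScope  = "character",
  phenotypeInfo = "data.frame"
))

setValidity("PhenotypeMatrix", function(object) {
  msgs <- character()
  inc <- object@incidence
  if (!all(inc@x %in% c(0, 1)))
    msgs <- c(msgs, "incidence must be binary")
  if (!object@elementKind %in% c("genes", "orthogroups"))
    msgs <- c(msgs, "elementKind must be 'genes' or 'orthogroups'")
  want <- if (identical(object@elementKind, "genes")) 1L else 2L
  if (length(object@speciesScope) != want)
    msgs <- c(msgs, "speciesScope length inconsistent with elementKind")
  info <- object@phenotypeInfo
  if (nrow(info) != ncol(inc))
    msgs <- c(msgs, "phenotypeInfo must describe every column")
  else if (ncol(inc) && !isTRUE(all.equal(unname(Matrix::colSums(inc)),
                                          as.numeric(info$cardinality))))
    msgs <- c(msgs, "phenotype cardinalities must equal column sums")
  if (anyDuplicated(rownames(inc)))
    msgs <- c(msgs, "element ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' PhenologDataset: associations plus pairwise orthology for several species
#'
#' The full input to a phenolog search: one association table pooling the
#' gene--phenotype records of all species, and one [OrthologyMap-class] per
#' species pair of interest.
#'
#' @slot associations validated association data.frame (see
#'   [readAssociations()]).
#' @slot orthology named list of [OrthologyMap-class]; names are canonical
#'   species-pair keys.
#' @slot species character vector of all species present.
#' @exportClass PhenologDataset
setClass("PhenologDataset", slots = c(
  associations = "data.frame",
  orthology    = "list",
  species      = "character"
))

setValidity("PhenologDataset", function(object) {
  msgs <- character()
  if (!all(vapply(object@orthology, is, logical(1), "OrthologyMap")))
    msgs <- c(msgs, "orthology must be a list of OrthologyMap objects")
  ok <- vapply(object@orthology, function(m)
    .pairKey(m@speciesPair[1], m@speciesPair[2]), character(1))
  if (length(ok) && !identical(unname(ok), names(object@orthology)))
    msgs <- c(msgs, "orthology list names must be canonical pair keys")
  if (length(msgs)) msgs else TRUE
})

#' Assemble a PhenologDataset
#'
#' @param associations association data.frame with columns `species`,
#'   `phenotype_id`, `phenotype_name`, `gene_id` (see [readAssociations()]).
#' @param orthology a list of [OrthologyMap-class] objects, one per species
#'   pair (at most one map per unordered pair).
#' @param minGenes minimum number of distinct genes a phenotype must have to
#'   be kept (applied with [filterMinGenes()]); use 1 to keep everything.
#' @return A [PhenologDataset-class].
#' @export
phenologDataset <- function(associations, orthology = list(), minGenes = 3L) {
  associations <- .validateAssociations(associations)
  associations <- filterMinGenes(associations, minGenes)
  if (length(orthology)) {
    keys <- vapply(orthology, function(m) {
      if (!is(m, "OrthologyMap")) stop("orthology entries must be OrthologyMap")
      .pairKey(m@speciesPair[1], m@speciesPair[2])
    }, character(1))
    if (anyDuplicated(keys)) stop("more than one OrthologyMap for a pair")
    names(orthology) <- keys
  }
  sp <- sort(unique(c(associations$species,
                      unlist(lapply(orthology, slot, "speciesPair")))))
  new("PhenologDataset", associations = associations,
      orthology = orthology, species = sp)
}

#' WeightingSpec: configuration of a phenolog search
#'
#' @slot k number of nearest neighbour phenotypes to integrate.
#' @slot distanceMeasure measure used to order candidate neighbours
#'   (`"pearson"`, `"hypergeom"`, `"cosine"`, `"tanimoto"`, `"euclidean"`,
#'   `"manhattan"`).
#' @slot weightMeasure measure converted into the weight w of each neighbour.
#' @slot classifier `"naive_bayes"` or `"additive"`.
#' @slot includeWithinSpecies whether paralogous (same-species) phenotypes may
#'   be neighbours.
#' @slot framework `"orthogroup"` (symmetric, default) or `"gene"` based
#'   translation of annotations between species.
#' @slot fDenominator denominator of the true-positive fraction f = v/n:
#'   `"target"` (cardinality of the target phenotype) or `"neighbor"`.
#' @slot speciesSubset species allowed to contribute neighbours;
#'   `character(0)` means all.
#' @exportClass WeightingSpec
setClass("WeightingSpec", slots = c(
  k                    = "integer",
  distanceMeasure      = "character",
  weightMeasure        = "character",
  classifier           = "character",
  includeWithinSpecies = "logical",
  framework            = "character",
  fDenominator         = "character",
  speciesSubset        = "character"
))

.MEASURES <- c("pearson", "cosine", "tanimoto", "euclidean", "manhattan",
               "hypergeom")

setValidity("WeightingSpec", function(object) {
  msgs <- character()
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (!object@distanceMeasure %in% .MEASURES)
    msgs <- c(msgs, "unknown distanceMeasure")
  if (!object@weightMeasure %in% .MEASURES)
    msgs <- c(msgs, "unknown weightMeasure")
  if (!object@classifier %in% c("naive_bayes", "additive"))
    msgs <- c(msgs, "classifier must be naive_bayes or additive")
  if (!object@framework %in% c("orthogroup", "gene"))
    msgs <- c(msgs, "framework must be orthogroup or gene")
  if (!object@fDenominator %in% c("target", "neighbor"))
    msgs <- c(msgs, "fDenominator must be target or neighbor")
  if (length(msgs)) msgs else TRUE
})

#' Create a WeightingSpec
#'
#' Defaults follow the best-performing configuration in cross-validation:
#' Pearson sample correlation as the distance used to find neighbours, the
#' hypergeometric tail as the weighting function, naive Bayes integration,
#' the symmetric orthogroup framework, and k = 40 neighbours.
#'
#' @param k,distanceMeasure,weightMeasure,classifier,includeWithinSpecies,framework,fDenominator,speciesSubset
#'   see [WeightingSpec-class].
#' @return A [WeightingSpec-class].
#' @examples
#' weightingSpec(k = 10, classifier = "additive")
#' @export
weightingSpec <- function(k = 40L,
                          distanceMeasure = "pearson",
                          weightMeasure = "hypergeom",
                          classifier = c("naive_bayes", "additive"),
                          includeWithinSpecies = TRUE,
                          framework = c("orthogroup", "gene"),
                          fDenominator = c("target", "neighbor"),
                          speciesSubset = character()) {
  new("WeightingSpec",
      k = as.integer(k),
      distanceMeasure = match.arg(distanceMeasure, .MEASURES),
      weightMeasure = match.arg(weightMeasure, .MEASURES),
      classifier = match.arg(classifier),
      includeWithinSpecies = isTRUE(includeWithinSpecies),
      framework = match.arg(framework),
      fDenominator = match.arg(fDenominator),
      speciesSubset = as.character(speciesSubset))
}

#' PredictionList: ranked candidate genes for one target phenotype
#'
#' @slot targetSpecies,targetPhenotype identify the phenotype predicted for.
#' @slot spec the [WeightingSpec-class] used.
#' @slot predictions data.frame with columns `gene_id`, `score`, `rank`
#'   (mean rank over tied scores), `known` (TRUE when the gene or a member of
#'   one of its orthogroups is already associated with the target).
#' @slot neighbors data.frame describing the k neighbour phenotypes used:
#'   overlap counts `v`, `m` (target cardinality in the shared space), `n`
#'   (neighbour cardinality), `N` (universe size), the distance value, and the
#'   derived `f` and `w`.
#' @slot contributions data.frame with one row per (gene, neighbour)
#'   contribution: `gene_id`, `neighbor`, `f`, `w`, `term` (w for the additive
#'   classifier, f*w for naive Bayes).
#' @exportClass PredictionList
setClass("PredictionList", slots = c(
  targetSpecies   = "character",
  targetPhenotype = "character",
  spec            = "WeightingSpec",
  predictions     = "data.frame",
  neighbors       = "data.frame",
  contributions   = "data.frame"
))

setValidity("PredictionList", function(object) {
  p <- object@predictions
  msgs <- character()
  if (nrow(p)) {
    if (is.unsorted(-p$score)) msgs <- c(msgs, "scores must be non-increasing")
    if (abs(sum(p$rank) - nrow(p) * (nrow(p) + 1) / 2) > 1e-8)
      msgs <- c(msgs, "ranks must sum to P(P+1)/2")
  }
  if (length(msgs)) msgs else TRUE
})

#' CVReport: leave-one-out cross-validation results
#'
#' @slot targetSpecies species whose phenotypes were evaluated.
#' @slot ranks data.frame with one row per (phenotype, repeat): the withheld
#'   gene, its recovered rank (mean rank over ties) and the ranking pool size.
#' @slot medians data.frame with per-phenotype median withheld rank.
#' @slot spec the [WeightingSpec-class] used.
#' @slot seed the RNG seed the run was started from.
#' @slot repeats number of repeats per phenotype.
#' @slot audit logical; TRUE when every fold passed the leakage audit
#'   (masked orthogroups contributed nothing to any neighbour overlap).
#' @exportClass CVReport
setClass("CVReport", slots = c(
  targetSpecies = "character",
  ranks         = "data.frame",
  medians       = "data.frame",
  spec          = "WeightingSpec",
  seed          = "numeric",
  repeats       = "integer",
  audit         = "logical"
))

## ---- show methods -----------------------------------------------------

setMethod("show", "OrthologyMap", function(object) {
  cat("OrthologyMap:", object@speciesPair[1], "<->", object@speciesPair[2],
      "\n  orthogroups:", length(unique(object@groups$orthogroup_id)),
      "\n  member genes:", nrow(object@groups), "\n")
})

setMethod("show", "PhenotypeMatrix", function(object) {
  cat("PhenotypeMatrix [", object@elementKind, "of",
      paste(object@speciesScope, collapse = " / "), "]\n",
      " ", nrow(object@incidence), "elements x",
      ncol(object@incidence), "phenotypes;",
      sum(object@incidence), "incidences\n")
})

setMethod("show", "PhenologDataset", function(object) {
  cat("PhenologDataset with", length(object@species), "species:",
      paste(object@species, collapse = ", "), "\n",
      " associations:", nrow(object@associations), "records,",
      length(unique(.phenKey(object@associations$species,
                             object@associations$phenotype_id))),
      "phenotypes\n",
      " orthology maps:", length(object@orthology), "\n")
})

setMethod("show", "WeightingSpec", function(object) {
  cat("WeightingSpec: k =", object@k,
      "| distance =", object@distanceMeasure,
      "| weight =", object@weightMeasure,
      "| classifier =", object@classifier,
      "| framework =", object@framework, "\n")
})

setMethod("show", "PredictionList", function(object) {
  cat("PredictionList for", object@targetPhenotype,
      "(", object@targetSpecies, ")\n",
      " ", nrow(object@predictions), "ranked genes,",
      nrow(object@neighbors), "neighbour phenotypes\n")
  print(head(object@predictions, 5))
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport:", nrow(object@medians), "phenotypes x",
      object@repeats, "repeats (seed", object@seed, ")\n",
      " median of median ranks:",
      stats::median(object@medians$median_rank), "\n")
})

## ---- accessors --------------------------------------------------------

#' Accessors for phenologr classes
#'
#' Small read-only accessors: `speciesPair` and `nOrthogroups` for
#' [OrthologyMap-class]; `incidence`, `elementKind` and `phenotypeInfo` for
#' [PhenotypeMatrix-class]; `datasetSpecies`, `associations` and
#' `orthologyMaps` for [PhenologDataset-class]; `predictions`, `neighbors`
#' and `cvRanks`/`cvMedians` for results objects.
#'
#' @param x the object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
speciesPair <- function(x) x@speciesPair

#' @rdname accessors
#' @export
nOrthogroups <- function(x) length(unique(x@groups$orthogroup_id))

#' @rdname accessors
#' @export
orthogroupIds <- function(x) sort(unique(x@groups$orthogroup_id))

#' Orthogroup of given genes
#'
#' @param x an [OrthologyMap-class].
#' @param species species the genes belong to.
#' @param genes character vector of gene ids.
#' @return Character vector of orthogroup ids (NA where the gene has none).
#' @export
groupOf <- function(x, species, genes) {
  if (!species %in% x@speciesPair)
    stop("configuration error: species '", species, "' not in this map")
  unname(x@geneIndex[.geneKey(species, genes)])
}

#' Member genes of orthogroups on one side
#'
#' @param x an [OrthologyMap-class].
#' @param species which side.
#' @param ids orthogroup ids (default: all).
#' @return Named list of character vectors of gene ids.
#' @export
membersOf <- function(x, species, ids = NULL) {
  if (!species %in% x@speciesPair)
    stop("configuration error: species '", species, "' not in this map")
  side <- x@sideMembers[[species]]
  if (is.null(ids)) side else side[as.character(ids)]
}

#' @rdname accessors
#' @export
incidence <- function(x) x@incidence

#' @rdname accessors
#' @export
elementKind <- function(x) x@elementKind

#' @rdname accessors
#' @export
phenotypeInfo <- function(x) x@phenotypeInfo

#' @rdname accessors
#' @export
datasetSpecies <- function(x) x@species

#' @rdname accessors
#' @export
associations <- function(x) x@associations

#' @rdname accessors
#' @export
orthologyMaps <- function(x) x@orthology

#' @rdname accessors
#' @export
predictions <- function(x) x@predictions

#' @rdname accessors
#' @export
neighbors <- function(x) x@neighbors

#' @rdname accessors
#' @export
contributions <- function(x) x@contributions

#' @rdname accessors
#' @export
cvRanks <- function(x) x@ranks

#' @rdname accessors
#' @export
cvMedians <- function(x) x@medians

#' Orthology map for a species pair of a dataset
#'
#' @param x a [PhenologDataset-class].
#' @param a,b the two species (order irrelevant).
#' @return The [OrthologyMap-class], or NULL when none is loaded for the pair.
#' @export
pairMap <- function(x, a, b) {
  x@orthology[[.pairKey(a, b)]]
}
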