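#' Orthogroup-aware leave-one-out cross-validation
#'
#' For every target-species phenotype with at least two associated genes, one
#' known gene is hidden at a time: the gene and every orthogroup containing
#' it are removed from the phenotype's column in all comparison spaces, the
#' neighbour search and scoring are recomputed on the masked data, and the
#' rank of the hidden gene among all target-species genes is recorded (tied
#' scores share the mean rank). The procedure is repeated `repeats` times per
#' phenotype with different random hidden genes and the per-phenotype median
#' hidden-gene rank is reported.
#'
#' @param dataset a [PhenologDataset-class].
#' @param targetSpecies species whose phenotypes are evaluated.
#' @param spec a [WeightingSpec-class].
#' @param repeats repeats per phenotype (default 3).
#' @param seed RNG seed; the run is fully deterministic given the seed.
#' @param phenotypes optional phenotype ids to restrict the evaluation to.
#' @param audit when TRUE, every fold additionally verifies that masked
#'   orthogroups contribute nothing to any neighbour overlap count (leakage
#'   guard); the result is stored in the report's `audit` slot.
#' @return A [CVReport-class].
#' @export
loocv <- function(dataset, targetSpecies, spec = weightingSpec(),
                  repeats = 3L, seed = 1L, phenotypes = NULL,
                  audit = FALSE) {
  validObject(spec)
  spaces <- .buildSpaces(dataset, targetSpecies, spec@framework)
  sets <- spaces$geneSets
  keys <- sort(names(sets)[lengths(sets) >= 2L])
  if (!is.null(phenotypes))
    keys <- intersect(keys, .phenKey(targetSpecies, phenotypes))
  skipped <- setdiff(names(sets), keys)
  if (is.null(phenotypes) && length(skipped))
    message(length(skipped),
            " phenotype(s) skipped: fewer than 2 associated genes")
  set.seed(seed)
  rows <- vector("list", length(keys))
  auditOk <- TRUE
  for (i in seq_along(keys)) {
    key <- keys[i]
    genes <- sort(sets[[key]])
    hidden <- if (length(genes) >= repeats) sample(genes, repeats)
              else sample(genes, repeats, replace = TRUE)
    rk <- numeric(repeats)
    for (r in seq_len(repeats)) {
      core <- .predictCore(spaces, key, maskGenes = hidden[r], spec = spec,
                           audit = audit)
      rk[r] <- core$ranks[[hidden[r]]]
      if (audit && !core$auditOk) auditOk <- FALSE
    }
    parts <- .splitKey(key)[[1]]
    rows[[i]] <- data.frame(
      species = parts[1], phenotype_id = parts[2],
      rep = seq_len(repeats), hidden_gene = hidden, rank = rk,
      pool_size = length(spaces$pool), stringsAsFactors = FALSE)
  }
  ranks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), phenotype_id = character(),
               rep = integer(), hidden_gene = character(), rank = numeric(),
               pool_size = integer(), stringsAsFactors = FALSE)
  med <- if (nrow(ranks))
    stats::aggregate(rank ~ phenotype_id, data = ranks, FUN = stats::median)
  else data.frame(phenotype_id = character(), rank = numeric())
  names(med)[names(med) == "rank"] <- "median_rank"
  new("CVReport", targetSpecies = targetSpecies, ranks = ranks,
      medians = med[order(med$phenotype_id), , drop = FALSE],
      spec = spec, seed = as.numeric(seed), repeats = as.integer(repeats),
      audit = auditOk)
}

#' n-fold cross-validation with ROC and precision--recall summaries
#'
#' Splits each phenotype's known genes across `folds` folds; each fold is
#' withheld (with its orthogroups) in turn and the remaining genes are used
#' for the search. Withheld genes are the positives; every other ranked gene
#' not known for the phenotype is a negative (the still-visible training
#' genes are excluded from the evaluation). Per-phenotype ROC and
#' precision--recall curves and their areas are reported. Only phenotypes
#' with at least `minPhenotypeSize` known genes are evaluated.
#'
#' @param dataset a [PhenologDataset-class].
#' @param targetSpecies species whose phenotypes are evaluated.
#' @param spec a [WeightingSpec-class].
#' @param folds number of folds (>= 2).
#' @param minPhenotypeSize smallest phenotype evaluated (default 4).
#' @param seed RNG seed for the fold assignment.
#' @param phenotypes optional phenotype ids to restrict to.
#' @return list with `perPhenotype` (data.frame: phenotype_id, auroc, aupr,
#'   n_pos, n_neg) and `curves` (per phenotype, list of `roc` and `pr`
#'   data.frames).
#' @export
nfoldCv <- function(dataset, targetSpecies, spec = weightingSpec(),
                    folds = 5L, minPhenotypeSize = 4L, seed = 1L,
                    phenotypes = NULL) {
  validObject(spec)
  if (folds < 2L) stop("folds must be >= 2")
  spaces <- .buildSpaces(dataset, targetSpecies, spec@framework)
  sets <- spaces$geneSets
  keys <- sort(names(sets)[lengths(sets) >= minPhenotypeSize])
  if (!is.null(phenotypes))
    keys <- intersect(keys, .phenKey(targetSpecies, phenotypes))
  set.seed(seed)
  per <- vector("list", length(keys))
  curves <- stats::setNames(vector("list", length(keys)), keys)
  for (i in seq_along(keys)) {
    key <- keys[i]
    genes <- sort(sets[[key]])
    assign <- sample(rep(seq_len(folds), length.out = length(genes)))
    scoresAll <- numeric()
    labelsAll <- logical()
    for (fd in unique(assign)) {
      withheld <- genes[assign == fd]
      core <- .predictCore(spaces, key, maskGenes = withheld, spec = spec)
      eval <- setdiff(names(core$scores), setdiff(genes, withheld))
      s <- core$scores[eval]
      scoresAll <- c(scoresAll, unname(s))
      labelsAll <- c(labelsAll, eval %in% withheld)
    }
    roc <- .rocCurve(scoresAll, labelsAll)
    pr <- .prCurve(scoresAll, labelsAll)
    per[[i]] <- data.frame(
      phenotype_id = .splitKey(key)[[1]][2],
      auroc = .aurocScores(scoresAll, labelsAll),
      aupr = attr(pr, "aupr"),
      n_pos = sum(labelsAll), n_neg = sum(!labelsAll),
      stringsAsFactors = FALSE)
    curves[[i]] <- list(roc = roc, pr = pr)
  }
  perPhenotype <- if (length(per)) do.call(rbind, per) else
    data.frame(phenotype_id = character(), auroc = numeric(),
               aupr = numeric(), n_pos = integer(), n_neg = integer())
  list(perPhenotype = perPhenotype, curves = curves)
}

## AUROC by the rank-sum (Mann-Whitney) identity; exact under ties with
## average ranks
.aurocScores <- function(scores, labels) {
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

## ROC curve points at tied-score group boundaries (descending thresholds)
.rocCurve <- function(scores, labels) {
  np <- sum(labels); nn <- sum(!labels)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / max(nn, 1)),
             tpr = c(0, tp[last] / max(np, 1)))
}

## precision-recall points at tied-score group boundaries; area attribute is
## the step-integrated average precision
.prCurve <- function(scores, labels) {
  np <- sum(labels)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); n <- seq_along(l)
  last <- !duplicated(grp, fromLast = TRUE)
  recall <- tp[last] / max(np, 1)
  precision <- tp[last] / n[last]
  out <- data.frame(threshold = s[last], recall = recall,
                    precision = precision)
  dr <- diff(c(0, recall))
  attr(out, "aupr") <- sum(dr * precision)
  out
}

#' Recovery curve from a cross-validation report
#'
#' For each rank threshold r = 1..maxRank, counts the phenotypes whose median
#' withheld-gene rank is at or below r. The curve is non-decreasing.
#'
#' @param report a [CVReport-class], or a data.frame with a `median_rank`
#'   column.
#' @param maxRank largest threshold (default 100).
#' @return data.frame with columns `r` and `count`.
#' @export
recoveryCurve <- function(report, maxRank = 100L) {
  med <- if (is(report, "CVReport")) report@medians$median_rank
         else report$median_rank
  r <- seq_len(maxRank)
  data.frame(r = r,
             count = vapply(r, function(x) sum(med <= x), numeric(1)))
}

#' Column-cardinality-preserving randomization of a phenotype matrix
#'
#' The randomized-matrix control: for each phenotype column of cardinality p,
#' p elements are redrawn uniformly without replacement from the element
#' universe. Cardinalities are preserved exactly; all planted structure is
#' destroyed.
#'
#' @param matrix a [PhenotypeMatrix-class].
#' @param seed RNG seed.
#' @return A [PhenotypeMatrix-class] of the same shape.
#' @export
randomizeMatrix <- function(matrix, seed = 1L) {
  stopifnot(is(matrix, "PhenotypeMatrix"))
  inc <- matrix@incidence
  set.seed(seed)
  card <- Matrix::colSums(inc)
  nr <- nrow(inc)
  i <- unlist(lapply(card, function(p) sample.int(nr, p)), use.names = FALSE)
  j <- rep(seq_along(card), card)
  out <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = dim(inc),
                              dimnames = dimnames(inc))
  new("PhenotypeMatrix", incidence = out, elementKind = matrix@elementKind,
      speciesScope = matrix@speciesScope,
      phenotypeInfo = matrix@phenotypeInfo)
}

#' Cardinality-preserving randomization of a whole dataset
#'
#' Applies the randomized-matrix control at the association level: for every
#' phenotype of every species, its gene set is replaced by an equally sized
#' uniform draw from that species' gene pool (all genes seen in its
#' associations or orthology maps). Used as the negative-control arm when
#' benchmarking against real data.
#'
#' @param dataset a [PhenologDataset-class].
#' @param seed RNG seed.
#' @return A new [PhenologDataset-class] with randomized associations and the
#'   original orthology.
#' @export
randomizeAssociations <- function(dataset, seed = 1L) {
  stopifnot(is(dataset, "PhenologDataset"))
  set.seed(seed)
  assoc <- dataset@associations
  out <- vector("list", 0L)
  for (sp in sort(unique(assoc$species))) {
    a <- assoc[assoc$species == sp, , drop = FALSE]
    pool <- unique(a$gene_id)
    for (map in dataset@orthology)
      if (sp %in% map@speciesPair)
        pool <- unique(c(pool, unlist(map@sideMembers[[sp]],
                                      use.names = FALSE)))
    pool <- sort(pool)
    sets <- split(a$gene_id, a$phenotype_id)
    nm <- a$phenotype_name[match(names(sets), a$phenotype_id)]
    for (q in seq_along(sets)) {
      g <- sample(pool, length(unique(sets[[q]])))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, phenotype_id = names(sets)[q], phenotype_name = nm[q],
        gene_id = g, stringsAsFactors = FALSE)
    }
  }
  assocR <- if (length(out)) do.call(rbind, out) else .emptyAssociations()
  phenologDataset(assocR, dataset@orthology, minGenes = 1L)
}

#' Species-subset ablation of the neighbour pool
#'
#' Reruns leave-one-out cross-validation with the neighbour search restricted
#' to each given species subset, to measure the relative contribution of each
#' species' phenotype data. All subsets are evaluated on the same phenotype
#' list, so curves are directly comparable.
#'
#' @param dataset a [PhenologDataset-class].
#' @param targetSpecies species whose phenotypes are evaluated.
#' @param spec a [WeightingSpec-class].
#' @param subsets named list of character vectors of species.
#' @param repeats,seed,maxRank passed through to [loocv()] /
#'   [recoveryCurve()].
#' @return list with `reports` (one [CVReport-class] per subset) and
#'   `curves` (one recovery-curve data.frame per subset).
#' @export
speciesAblation <- function(dataset, targetSpecies, spec = weightingSpec(),
                            subsets, repeats = 3L, seed = 1L,
                            maxRank = 100L) {
  stopifnot(is.list(subsets), length(subsets) >= 1L)
  if (is.null(names(subsets)))
    names(subsets) <- vapply(subsets, paste, character(1), collapse = "+")
  reports <- curves <- stats::setNames(vector("list", length(subsets)),
                                       names(subsets))
  for (nm in names(subsets)) {
    sub <- as.character(subsets[[nm]])
    if (!length(sub)) stop("configuration error: empty species subset")
    bad <- setdiff(sub, dataset@species)
    if (length(bad))
      stop("configuration error: unknown species: ",
           paste(bad, collapse = ", "))
    sp <- spec
    sp@speciesSubset <- sub
    reports[[nm]] <- loocv(dataset, targetSpecies, sp, repeats = repeats,
                           seed = seed)
    curves[[nm]] <- recoveryCurve(reports[[nm]], maxRank)
  }
  list(reports = reports, curves = curves)
}
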