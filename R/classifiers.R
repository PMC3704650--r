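#' True-positive fraction f of a single phenolog
#'
#' The fraction of elements common to the target and neighbour phenotypes
#' over the number of elements known for the target phenotype, f = v/n.
#' Empirically this approximates the probability that a candidate suggested
#' by a single phenolog is a true positive.
#'
#' @param v overlap count.
#' @param nTarget target phenotype cardinality (>= 1).
#' @return v / nTarget.
#' @export
fractionF <- function(v, nTarget) {
  if (any(nTarget == 0)) stop("domain error: nTarget must be >= 1")
  if (any(v < 0 | v > nTarget)) stop("domain error: require 0 <= v <= nTarget")
  v / nTarget
}

#' Map a similarity/distance value to a weight in \[0, 1\]
#'
#' The integration schemes treat the neighbour weight w as a probability, but
#' the raw measures live on different scales; this maps each onto \[0, 1\]:
#' hypergeometric p becomes 1 - p, Pearson r is clamped at zero, cosine and
#' Tanimoto pass through unchanged, and distances d map to 1/(1 + d).
#'
#' @param value measure value(s).
#' @param measure measure name.
#' @return Weight(s) in \[0, 1\].
#' @export
weightFromMeasure <- function(value, measure) {
  if (!measure %in% .MEASURES)
    stop("configuration error: unknown measure '", measure, "'")
  out <- switch(measure,
    hypergeom = 1 - value,
    pearson = pmax(value, 0),
    cosine = value,
    tanimoto = value,
    euclidean = 1 / (1 + value),
    manhattan = 1 / (1 + value))
  pmin(pmax(out, 0), 1)
}

#' Additive integration of neighbour phenotypes
#'
#' The additive score of element i is the weighted sum over neighbours
#' containing it: X_i = sum_k w_k * Phi_ik, i.e. the product of the incidence
#' matrix with the weight vector.
#'
#' @param neighbors list of neighbours, each a list with `elements`
#'   (character vector) and `weight` (non-negative scalar).
#' @param elements optional full element universe for the returned vector;
#'   defaults to the union of neighbour members.
#' @return Named numeric vector of scores (0 for elements in no neighbour).
#' @examples
#' scoreAdditive(list(list(elements = c("g1", "g2"), weight = 0.5),
#'                    list(elements = c("g2", "g3"), weight = 0.25)))
#' @export
scoreAdditive <- function(neighbors, elements = NULL) {
  memb <- lapply(neighbors, function(nb) unique(as.character(nb$elements)))
  w <- vapply(neighbors, function(nb) as.numeric(nb$weight), numeric(1))
  if (any(w < 0)) stop("weights must be >= 0")
  if (is.null(elements))
    elements <- sort(unique(unlist(memb, use.names = FALSE)))
  scores <- stats::setNames(numeric(length(elements)), elements)
  if (length(memb)) {
    g <- unlist(memb, use.names = FALSE)
    ww <- rep(w, lengths(memb))
    keep <- g %in% elements
    if (any(keep)) {
      s <- rowsum(ww[keep], g[keep])
      scores[rownames(s)] <- s[, 1]
    }
  }
  scores
}

#' Naive Bayes integration of neighbour phenotypes
#'
#' The naive Bayes score of element i is
#' X_i = 1 - prod_l (1 - f_l * w_l) over the neighbours containing i, where
#' f_l is the per-phenolog true-positive fraction and w_l the neighbour
#' weight, both treated as probabilities. Elements in no neighbour score 0.
#'
#' @param neighbors list of neighbours, each a list with `elements`, `f` and
#'   `weight`, all with f, w in \[0, 1\].
#' @param elements optional full element universe.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
scoreNaiveBayes <- function(neighbors, elements = NULL) {
  memb <- lapply(neighbors, function(nb) unique(as.character(nb$elements)))
  f <- vapply(neighbors, function(nb) as.numeric(nb$f), numeric(1))
  w <- vapply(neighbors, function(nb) as.numeric(nb$weight), numeric(1))
  if (any(f < 0 | f > 1 | w < 0 | w > 1))
    stop("f and w must lie in [0, 1]")
  if (is.null(elements))
    elements <- sort(unique(unlist(memb, use.names = FALSE)))
  logq <- stats::setNames(numeric(length(elements)), elements)
  if (length(memb)) {
    g <- unlist(memb, use.names = FALSE)
    term <- rep(log1p(-f * w), lengths(memb))   # log(1 - f w), -Inf at fw = 1
    keep <- g %in% elements
    if (any(keep)) {
      s <- rowsum(term[keep], g[keep])
      logq[rownames(s)] <- s[, 1]
    }
  }
  1 - exp(logq)
}

#' Rank candidate genes for a target phenotype
#'
#' Runs the full phenolog pipeline for one phenotype: finds the k nearest
#' neighbour phenotypes across all species (in the element space each
#' comparison shares), derives each neighbour's weight w and true-positive
#' fraction f from its overlap statistics, maps orthogroup-level
#' contributions down to target-species genes (every target-side member of a
#' contributing orthogroup inherits the contribution, once per source
#' species), and integrates contributions with the chosen classifier. All
#' target-species genes in the dataset are ranked; genes already associated
#' with the target (or sharing an orthogroup with one that is) are flagged
#' `known` but retained.
#'
#' @param dataset a [PhenologDataset-class].
#' @param phenotype target phenotype id.
#' @param species species of the target phenotype.
#' @param spec a [WeightingSpec-class].
#' @param maskGenes optional target-species genes to hide from the target
#'   column (together with their orthogroups) before the search -- the
#'   masking used by cross-validation.
#' @return A [PredictionList-class].
#' @export
phenologPredict <- function(dataset, phenotype, species,
                            spec = weightingSpec(), maskGenes = NULL) {
  validObject(spec)
  spaces <- .buildSpaces(dataset, species, spec@framework)
  key <- .phenKey(species, phenotype)
  if (!key %in% spaces$targetPhenotypes)
    stop("lookup error: unknown phenotype '", phenotype, "' for species '",
         species, "'")
  core <- .predictCore(spaces, key, maskGenes = maskGenes, spec = spec,
                       wantContrib = TRUE)
  knownGenes <- spaces$geneSets[[key]]
  for (map in dataset@orthology) {
    if (!species %in% map@speciesPair) next
    ogs <- unique(groupOf(map, species, knownGenes))
    ogs <- ogs[!is.na(ogs)]
    if (length(ogs))
      knownGenes <- unique(c(knownGenes,
                             unlist(membersOf(map, species, ogs),
                                    use.names = FALSE)))
  }
  pred <- data.frame(gene_id = names(core$scores),
                     score = unname(core$scores),
                     rank = unname(core$ranks),
                     known = names(core$scores) %in% knownGenes,
                     stringsAsFactors = FALSE)
  pred <- pred[order(-pred$score, pred$gene_id), , drop = FALSE]
  rownames(pred) <- NULL
  new("PredictionList", targetSpecies = species, targetPhenotype = phenotype,
      spec = spec, predictions = pred, neighbors = core$neighbors,
      contributions = core$contributions)
}

#' Per-neighbour contribution decomposition of a prediction
#'
#' Breaks each gene's score into the contribution of each of the `topN`
#' nearest neighbour phenotypes plus one aggregated "below top-n" remainder
#' bucket -- the table behind waterfall-style prediction charts. For the
#' additive classifier the decomposition is exact: each row sums to the
#' gene's score. For naive Bayes scores the terms reported are the f*w
#' factors, which do not sum to the score (flagged with a message).
#'
#' @param predictionList a [PredictionList-class].
#' @param topN number of neighbours broken out individually (default 20).
#' @return data.frame: `gene_id`, `score`, one column per top neighbour key,
#'   and a `below_top_n` remainder column (absent when topN >= k).
#' @export
decomposeContributions <- function(predictionList, topN = 20L) {
  stopifnot(is(predictionList, "PredictionList"))
  if (predictionList@spec@classifier != "additive")
    message("naive Bayes scores are not additive; reporting f*w factors")
  co <- predictionList@contributions
  nb <- predictionList@neighbors
  topKeys <- head(nb$key, topN)
  restKeys <- setdiff(nb$key, topKeys)
  genes <- unique(co$gene_id)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$score <- predictionList@predictions$score[
    match(genes, predictionList@predictions$gene_id)]
  for (kk in topKeys) {
    x <- co[co$neighbor == kk, , drop = FALSE]
    out[[kk]] <- 0
    out[[kk]][match(x$gene_id, genes)] <- x$term
  }
  if (length(restKeys)) {
    x <- co[co$neighbor %in% restKeys, , drop = FALSE]
    s <- rowsum(x$term, x$gene_id)
    out$below_top_n <- 0
    out$below_top_n[match(rownames(s), genes)] <- s[, 1]
  }
  out[order(-out$score, out$gene_id), , drop = FALSE]
}
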