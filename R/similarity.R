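#' Upper tail of the hypergeometric distribution
#'
#' The phenolog significance measure: the probability of seeing an
#' intersection of `v` or greater between a phenotype with `m` associated
#' elements and one with `n`, out of `N` total elements shared by the
#' species pair. Computed through the survival form of [stats::phyper] for
#' numerical stability. All arguments are vectorised.
#'
#' @param v observed overlap (0 <= v <= min(m, n)).
#' @param m,n the two set cardinalities (<= N).
#' @param N universe size.
#' @return P(X >= v), in \[0, 1\].
#' @examples
#' hypergeomTail(3, 3, 3, 10)  # 1/120
#' @export
hypergeomTail <- function(v, m, n, N) {
  ok <- v >= 0 & v <= pmin(m, n) & m <= N & n <= N & m >= 0 & n >= 0 & N >= 0
  if (anyNA(ok) || any(!ok))
    stop("domain error: require 0 <= v <= min(m, n) <= N")
  ## evaluate with the smaller set as the "white balls" so that the result is
  ## bitwise identical under exchange of m and n
  lo <- pmin(m, n)
  hi <- pmax(m, n)
  stats::phyper(v - 1, lo, N - lo, hi, lower.tail = FALSE)
}

## vectorised measure from overlap counts; returns NA where the measure is
## undefined (constant indicator vector under pearson, two empty sets under
## tanimoto/cosine)
.measureFromCounts <- function(v, m, n, N, measure) {
  switch(measure,
    hypergeom = hypergeomTail(v, m, n, N),
    pearson = {
      den <- sqrt(m * (N - m)) * sqrt(n * (N - n))
      out <- (N * v - m * n) / den
      out[den == 0] <- NA_real_
      out
    },
    cosine = {
      den <- sqrt(m * n)
      out <- v / den
      out[den == 0] <- NA_real_
      out
    },
    tanimoto = {
      den <- m + n - v
      out <- v / den
      out[den == 0] <- NA_real_
      out
    },
    euclidean = sqrt(m + n - 2 * v),
    manhattan = m + n - 2 * v,
    stop("configuration error: unknown measure '", measure, "'")
  )
}

## convert a measure value into a "larger is nearer" key
.nearnessKey <- function(value, measure) {
  switch(measure,
    hypergeom = -value,
    euclidean = -value,
    manhattan = -value,
    value)
}

#' Similarity / distance between two binary annotation sets
#'
#' Computes one of the six supported measures from two element sets over a
#' common universe: Pearson sample correlation of the 0/1 indicator vectors
#' (equal to the phi coefficient of the 2x2 contingency table), cosine
#' similarity v/sqrt(mn), Tanimoto coefficient v/(m+n-v), Euclidean distance
#' sqrt(m+n-2v), Manhattan distance m+n-2v, or the hypergeometric tail
#' probability of the overlap.
#'
#' @param x,y character vectors (element sets); duplicates ignored.
#' @param universe universe size N (>= 1), or a character vector whose length
#'   is used. `x` and `y` must lie inside the universe.
#' @param measure one of `"pearson"`, `"cosine"`, `"tanimoto"`,
#'   `"euclidean"`, `"manhattan"`, `"hypergeom"`.
#' @return The measure value. Pearson on a constant indicator vector (an
#'   empty or universe-sized set) is undefined and raises an error.
#' @examples
#' binarySimilarity(c("a", "b"), c("b", "c"), 10, "tanimoto")  # 1/3
#' @export
binarySimilarity <- function(x, y, universe,
                             measure = c("pearson", "cosine", "tanimoto",
                                         "euclidean", "manhattan",
                                         "hypergeom")) {
  measure <- match.arg(measure)
  x <- unique(as.character(x))
  y <- unique(as.character(y))
  if (is.character(universe)) {
    if (!all(c(x, y) %in% universe))
      stop("domain error: x and y must be subsets of the universe")
    N <- length(unique(universe))
  } else {
    N <- as.numeric(universe)
  }
  if (N < 1) stop("domain error: universe must have >= 1 element")
  m <- length(x); n <- length(y)
  if (m > N || n > N)
    stop("domain error: set larger than the universe")
  v <- length(intersect(x, y))
  out <- .measureFromCounts(v, m, n, N, measure)
  if (is.na(out) && measure == "pearson")
    stop("undefined value: Pearson correlation of a constant indicator vector")
  if (is.na(out)) 0 else out
}

#' Find the k nearest neighbour phenotypes of a target phenotype
#'
#' Searches every candidate phenotype across all species of the dataset for
#' the ones whose associated gene sets most resemble the target's. Each
#' comparison is performed in the element space the two phenotypes share:
#' orthogroups of the species pair for cross-species candidates (or, under
#' the gene framework, target-species genes with orthologs in the pair), and
#' the target species' annotated genes for within-species (paralogous)
#' candidates. The target's own column is never a candidate. Ordering is by
#' nearness under `distanceMeasure`, ties broken by phenotype key.
#'
#' @param dataset a [PhenologDataset-class].
#' @param phenotype target phenotype id.
#' @param species species the target phenotype belongs to.
#' @param k how many neighbours to return.
#' @param spec optional [WeightingSpec-class]; `k` and `distanceMeasure`
#'   arguments override its fields when given.
#' @param distanceMeasure measure used for the search.
#' @return data.frame with one row per neighbour: `key`, `species`,
#'   `phenotype_id`, `space` (comparison space id), overlap counts `v`, `m`
#'   (target cardinality in that space), `n` (neighbour cardinality), `N`
#'   (universe size), `distance` (raw measure value) and all six measure
#'   values as extra columns.
#' @export
nearestNeighbors <- function(dataset, phenotype, species, k = 10L,
                             spec = NULL, distanceMeasure = "pearson") {
  if (is.null(spec)) {
    spec <- weightingSpec(k = k, distanceMeasure = distanceMeasure)
  } else {
    if (!missing(k)) spec@k <- as.integer(k)
    if (!missing(distanceMeasure)) spec@distanceMeasure <- distanceMeasure
  }
  spaces <- .buildSpaces(dataset, species, spec@framework)
  key <- .phenKey(species, phenotype)
  if (!key %in% spaces$targetPhenotypes)
    stop("lookup error: unknown phenotype '", phenotype, "' for species '",
         species, "'")
  cand <- .scoreCandidates(spaces, key, maskGenes = NULL, spec = spec)
  if (!nrow(cand)) return(cand)
  for (msr in .MEASURES)
    cand[[msr]] <- .measureFromCounts(cand$v, cand$m, cand$n, cand$N, msr)
  head(cand, spec@k)
}
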