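## Internal comparison-space machinery.
##
## A phenolog search compares the target phenotype against candidates in the
## element space the two phenotypes share:
##   * within-species candidates: the target species' annotated genes;
##   * cross-species candidates, orthogroup framework: the orthogroups of the
##     species pair (symmetric in direction);
##   * cross-species candidates, gene framework: the target-species genes
##     having an ortholog in the pair (asymmetric under paralog expansions).
## .buildSpaces() precomputes, for one target species, the incidence of all
## target and candidate phenotype columns in every space, plus the maps
## between space elements and target-species genes needed for contribution
## mapping and for orthogroup-aware masking during cross-validation.

.buildSpaces <- function(dataset, targetSpecies, framework = "orthogroup") {
  if (!targetSpecies %in% dataset@species)
    stop("configuration error: unknown species '", targetSpecies, "'")
  assoc <- dataset@associations
  at <- assoc[assoc$species == targetSpecies, , drop = FALSE]
  targetKeys <- sort(unique(.phenKey(at$species, at$phenotype_id)))

  ## (species, phen) -> gene sets of the target species
  geneSets <- split(at$gene_id, .phenKey(at$species, at$phenotype_id))
  geneSets <- lapply(geneSets, unique)

  spaces <- list()

  ## ---- within-species gene space -------------------------------------
  geneUniverse <- sort(unique(at$gene_id))
  if (length(geneUniverse)) {
    gmat <- .incidenceFrom(at$gene_id, .phenKey(at$species, at$phenotype_id),
                           geneUniverse, targetKeys)
    spaces[["within"]] <- list(
      id = "within", within = TRUE, candSpecies = targetSpecies,
      N = length(geneUniverse),
      targMat = gmat, candMat = gmat,
      candCard = unname(Matrix::colSums(gmat)),
      elementGenes = as.list(geneUniverse),
      geneElements = as.list(stats::setNames(seq_along(geneUniverse),
                                             geneUniverse)))
  }

  ## ---- cross-species spaces ------------------------------------------
  pool <- unique(at$gene_id)
  for (S in setdiff(dataset@species, targetSpecies)) {
    map <- pairMap(dataset, targetSpecies, S)
    if (is.null(map)) next
    aS <- assoc[assoc$species == S, , drop = FALSE]
    candKeys <- sort(unique(.phenKey(aS$species, aS$phenotype_id)))
    tSide <- map@sideMembers[[targetSpecies]]
    pool <- unique(c(pool, unlist(tSide, use.names = FALSE)))
    if (framework == "orthogroup") {
      universe <- orthogroupIds(map)
      pT <- projectToOrthogroups(at, map)
      pS <- projectToOrthogroups(aS, map)
      targMat <- .incidenceFrom(pT$orthogroup_id,
                                .phenKey(pT$species, pT$phenotype_id),
                                universe, targetKeys)
      candMat <- .incidenceFrom(pS$orthogroup_id,
                                .phenKey(pS$species, pS$phenotype_id),
                                universe, candKeys)
      members <- tSide[universe]                # t-side genes per orthogroup
      geneEl <- .invertMembers(members)
      spaces[[paste0("pair:", S)]] <- list(
        id = paste0("pair:", S), within = FALSE, candSpecies = S,
        N = length(universe), targMat = targMat, candMat = candMat,
        candCard = unname(Matrix::colSums(candMat)),
        elementGenes = unname(members), geneElements = geneEl)
    } else {
      universe <- sort(unique(unlist(tSide, use.names = FALSE)))
      trS <- translateGeneBased(aS, S, targetSpecies, map)
      atIn <- at[at$gene_id %in% universe, , drop = FALSE]
      targMat <- .incidenceFrom(atIn$gene_id,
                                .phenKey(atIn$species, atIn$phenotype_id),
                                universe, targetKeys)
      candMat <- .incidenceFrom(trS$gene_id,
                                .phenKey(trS$species, trS$phenotype_id),
                                universe, candKeys)
      ## a hidden gene must also hide its in-orthogroup paralogs' translated
      ## image, so masking maps a gene to itself only (its own row)
      geneEl <- as.list(stats::setNames(seq_along(universe), universe))
      spaces[[paste0("pair:", S)]] <- list(
        id = paste0("pair:", S), within = FALSE, candSpecies = S,
        N = length(universe), targMat = targMat, candMat = candMat,
        candCard = unname(Matrix::colSums(candMat)),
        elementGenes = as.list(universe), geneElements = geneEl)
    }
  }

  list(targetSpecies = targetSpecies, framework = framework,
       targetPhenotypes = targetKeys, geneSets = geneSets,
       pool = sort(pool), spaces = spaces)
}

.incidenceFrom <- function(elements, phenKeys, universe, columns) {
  keep <- elements %in% universe & phenKeys %in% columns
  i <- match(elements[keep], universe)
  j <- match(phenKeys[keep], columns)
  ij <- !duplicated(paste(i, j))
  Matrix::sparseMatrix(i = i[ij], j = j[ij], x = 1,
                       dims = c(length(universe), length(columns)),
                       dimnames = list(universe, columns))
}

## orthogroup-members list -> gene -> element indices
.invertMembers <- function(members) {
  n <- lengths(members)
  g <- unlist(members, use.names = FALSE)
  split(rep(seq_along(members), n), g)
}

## Rank all candidate phenotype columns by nearness to the target column.
## maskGenes: target-species genes hidden from the target column, together
## with the orthogroups containing them (orthogroup-aware masking).
.scoreCandidates <- function(spaces, targetKey, maskGenes = NULL, spec) {
  res <- list()
  subset <- spec@speciesSubset
  for (sp in spaces$spaces) {
    if (sp$within && !spec@includeWithinSpecies) next
    if (length(subset) && !sp$candSpecies %in% subset) next
    j <- match(targetKey, colnames(sp$targMat))
    if (is.na(j)) next
    tcol <- sp$targMat[, j]
    if (!is.null(maskGenes)) {
      idx <- unique(unlist(sp$geneElements[
        intersect(maskGenes, names(sp$geneElements))], use.names = FALSE))
      if (length(idx)) tcol[idx] <- 0
    }
    mT <- sum(tcol)
    if (mT == 0) next
    v <- as.vector(Matrix::crossprod(sp$candMat, tcol))
    n <- sp$candCard
    d <- .measureFromCounts(v, mT, n, sp$N, spec@distanceMeasure)
    keys <- colnames(sp$candMat)
    keep <- !is.na(d) & n > 0
    if (sp$within) keep <- keep & keys != targetKey
    if (!any(keep)) next
    res[[sp$id]] <- data.frame(
      key = keys[keep], space = sp$id, v = v[keep], m = mT, n = n[keep],
      N = sp$N, distance = d[keep],
      nearness = .nearnessKey(d[keep], spec@distanceMeasure),
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(key = character(), species = character(),
                      phenotype_id = character(), space = character(),
                      v = numeric(), m = numeric(), n = numeric(),
                      N = numeric(), distance = numeric(),
                      nearness = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  parts <- do.call(rbind, .splitKey(out$key))
  out$species <- parts[, 1]
  out$phenotype_id <- parts[, 2]
  out <- out[order(-out$nearness, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out[c("key", "species", "phenotype_id", "space", "v", "m", "n", "N",
        "distance", "nearness")]
}

## Core prediction for one (possibly masked) target column: k-neighbour
## search, weight/f computation, contribution mapping to target genes, and
## classifier integration. Returns scores over the full gene pool.
.predictCore <- function(spaces, targetKey, maskGenes = NULL, spec,
                         wantContrib = FALSE, audit = FALSE) {
  cand <- .scoreCandidates(spaces, targetKey, maskGenes, spec)
  sel <- head(cand, spec@k)
  pool <- spaces$pool
  auditOk <- TRUE
  neighborsArg <- vector("list", nrow(sel))
  if (nrow(sel)) {
    wVal <- .measureFromCounts(sel$v, sel$m, sel$n, sel$N, spec@weightMeasure)
    wVal[is.na(wVal)] <- 0
    sel$w <- weightFromMeasure(wVal, spec@weightMeasure)
    den <- if (spec@fDenominator == "target") sel$m else sel$n
    sel$f <- ifelse(den > 0, sel$v / den, 0)
    for (i in seq_len(nrow(sel))) {
      sp <- spaces$spaces[[sel$space[i]]]
      jc <- match(sel$key[i], colnames(sp$candMat))
      memb <- which(sp$candMat[, jc] != 0)
      genes <- unlist(sp$elementGenes[memb], use.names = FALSE)
      neighborsArg[[i]] <- list(key = sel$key[i], elements = genes,
                                f = sel$f[i], weight = sel$w[i])
      if (audit) {
        jt <- match(targetKey, colnames(sp$targMat))
        tcol <- sp$targMat[, jt]
        maskedIdx <- unique(unlist(sp$geneElements[
          intersect(maskGenes, names(sp$geneElements))], use.names = FALSE))
        if (length(maskedIdx)) tcol[maskedIdx] <- 0
        tset <- which(tcol != 0)
        if (length(intersect(tset, maskedIdx)) ||
            length(intersect(memb, tset)) != sel$v[i])
          auditOk <- FALSE
      }
    }
  } else {
    sel$w <- numeric(0)
    sel$f <- numeric(0)
  }
  scores <- if (spec@classifier == "additive")
    scoreAdditive(neighborsArg, elements = pool)
  else
    scoreNaiveBayes(neighborsArg, elements = pool)
  ranks <- rank(-scores, ties.method = "average")
  out <- list(scores = scores, ranks = ranks, neighbors = sel,
              auditOk = auditOk)
  if (wantContrib) {
    cl <- lapply(neighborsArg, function(nb) {
      if (!length(nb$elements)) return(NULL)
      term <- if (spec@classifier == "additive") nb$weight else nb$f * nb$weight
      data.frame(gene_id = unique(nb$elements), neighbor = nb$key,
                 f = nb$f, w = nb$weight, term = term,
                 stringsAsFactors = FALSE)
    })
    cl <- cl[!vapply(cl, is.null, logical(1))]
    out$contributions <- if (length(cl)) do.call(rbind, cl) else
      data.frame(gene_id = character(), neighbor = character(), f = numeric(),
                 w = numeric(), term = numeric(), stringsAsFactors = FALSE)
  }
  out
}
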