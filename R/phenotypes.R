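## Association tables are plain data.frames with columns
## species, phenotype_id, phenotype_name, gene_id (+ optional gene_species,
## source_label). .validateAssociations() normalises and de-duplicates.

.emptyAssociations <- function(geneSpecies = FALSE) {
  out <- data.frame(species = character(), phenotype_id = character(),
                    phenotype_name = character(), gene_id = character(),
                    stringsAsFactors = FALSE)
  if (geneSpecies) out$gene_species <- character()
  out
}

.validateAssociations <- function(x) {
  if (!is.data.frame(x)) stop("associations must be a data.frame")
  need <- c("species", "phenotype_id", "phenotype_name", "gene_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parse error: association table missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in need) x[[col]] <- as.character(x[[col]])
  bad <- !nzchar(x$species) | !nzchar(x$phenotype_id) | !nzchar(x$gene_id)
  if (any(bad))
    stop("parse error: empty species/phenotype_id/gene_id in association row ",
         which(bad)[1])
  x <- x[!duplicated(x[c("species", "phenotype_id", "gene_id")]), ,
         drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a gene--phenotype association table
#'
#' Expects a 4-column TSV with header `species`, `phenotype_id`,
#' `phenotype_name`, `gene_id` (UTF-8, `#` comment lines skipped). Duplicate
#' (species, phenotype, gene) triples are collapsed.
#'
#' @param path path to the TSV file.
#' @param sourceLabel optional dataset tag (e.g. `"green-broad"` vs
#'   `"green-specific"`), stored in a `source_label` column.
#' @return Association data.frame.
#' @export
readAssociations <- function(path, sourceLabel = NULL) {
  tab <- .readTsv(path, c("species", "phenotype_id", "phenotype_name",
                          "gene_id"),
                  allowExtra = TRUE, optional = "phenotype_name")
  tab <- .validateAssociations(tab)
  if (!is.null(sourceLabel)) tab$source_label <- as.character(sourceLabel)
  tab
}

#' Drop phenotypes with too few associated genes
#'
#' Phenotypes associated with fewer than `minimum` distinct genes carry too
#' little signal for overlap statistics and are removed entirely (the default
#' of 3 is the dataset-construction rule used throughout).
#'
#' @param table association data.frame.
#' @param minimum minimum number of distinct genes (inclusive); must be >= 1.
#' @return Filtered association data.frame. Idempotent.
#' @export
filterMinGenes <- function(table, minimum = 3L) {
  table <- .validateAssociations2(table)
  if (minimum < 1L) stop("minimum must be >= 1")
  if (!nrow(table) || minimum == 1L) return(table)
  key <- .phenKey(table$species, table$phenotype_id)
  sizes <- tapply(table$gene_id, key, function(g) length(unique(g)))
  keep <- key %in% names(sizes)[sizes >= minimum]
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## validate but preserve extra columns such as source_label / gene_species
.validateAssociations2 <- function(x) {
  core <- .validateAssociations(x[intersect(
    names(x), c("species", "phenotype_id", "phenotype_name", "gene_id"))])
  extra <- setdiff(names(x), names(core))
  if (length(extra)) {
    ## re-attach extras aligned with the de-duplicated rows
    key0 <- paste(x$species, x$phenotype_id, x$gene_id, sep = .SEP)
    keyc <- paste(core$species, core$phenotype_id, core$gene_id, sep = .SEP)
    idx <- match(keyc, key0)
    for (col in extra) core[[col]] <- x[[col]][idx]
  }
  core
}

#' Read a GAF 2.x annotation file
#'
#' Minimal reader for the tab-delimited Gene Ontology Annotation File format:
#' keeps the DB object id (column 2), qualifier (4), GO id (5), evidence code
#' (7) and aspect (9). `!`-prefixed lines are skipped.
#'
#' @param path path to the GAF file (uncompressed).
#' @return data.frame with columns `gene_id`, `qualifier`, `term`,
#'   `evidence`, `aspect`.
#' @export
readGaf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("parse error: GAF row with fewer than 9 columns at record ",
         which(nf < 9L)[1])
  grab <- function(j) vapply(fields, `[[`, character(1), j)
  data.frame(gene_id = grab(2), qualifier = grab(4), term = grab(5),
             evidence = grab(7), aspect = grab(9), stringsAsFactors = FALSE)
}

## evidence codes defined by the GO consortium (used to distinguish a merely
## disallowed code from a malformed one)
.GO_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "HTP", "HDA",
                  "HMP", "HGI", "HEP", "IBA", "IBD", "IKR", "IRD", "ISS",
                  "ISO", "ISA", "ISM", "IGC", "RCA", "TAS", "NAS", "IC",
                  "ND", "IEA")

#' Filter GO annotations by evidence code
#'
#' Keeps only annotations whose evidence code is experimental or
#' curator-asserted (default IMP, IDA, IPI, IGI, TAS, NAS, IC, IEP), so that
#' no annotation inferred from another model organism leaks into the
#' phenotype data. `NOT`-qualified rows are dropped; (gene, term) pairs are
#' de-duplicated, and the GO term becomes the phenotype id.
#'
#' @param gaf data.frame as returned by [readGaf()], or a path to a GAF file.
#' @param allowed character vector of evidence codes to keep.
#' @param species species label for the resulting associations.
#' @return Association data.frame (phenotype_name = GO term id).
#' @export
filterEvidenceCodes <- function(gaf,
                                allowed = c("IMP", "IDA", "IPI", "IGI",
                                            "TAS", "NAS", "IC", "IEP"),
                                species = "unknown") {
  if (is.character(gaf) && length(gaf) == 1L) gaf <- readGaf(gaf)
  stopifnot(is.data.frame(gaf),
            all(c("gene_id", "term", "evidence") %in% names(gaf)))
  unknown <- setdiff(unique(gaf$evidence), .GO_EVIDENCE)
  if (length(unknown))
    warning("unknown evidence code(s) excluded: ",
            paste(unknown, collapse = ", "))
  keep <- gaf$evidence %in% allowed
  if ("qualifier" %in% names(gaf))
    keep <- keep & !grepl("(^|\\|)NOT($|\\|)", gaf$qualifier)
  g <- gaf[keep, , drop = FALSE]
  out <- data.frame(species = species, phenotype_id = g$term,
                    phenotype_name = g$term, gene_id = g$gene_id,
                    stringsAsFactors = FALSE)
  .validateAssociations(if (nrow(out)) out else .emptyAssociations())
}

#' Convert quantitative phenomic profiles to phenotype associations
#'
#' Each condition of a gene-by-condition score matrix becomes a phenotype;
#' a gene is associated with the conditions in which its growth was most
#' affected, positively or negatively: its `topK` highest-scoring and
#' `bottomK` lowest-scoring conditions. Ties in score are broken by condition
#' id (lexicographic) so the assignment is deterministic.
#'
#' @param profiles numeric matrix (genes in rows, named conditions in
#'   columns), or a data.frame whose first column is the gene id, or a path
#'   to a TSV laid out that way.
#' @param topK,bottomK how many conditions to take from each end of a gene's
#'   sorted profile (default 40 and 40).
#' @param species species label for the resulting associations.
#' @return Association data.frame (condition id as phenotype id and name).
#' @export
profileToPhenotypes <- function(profiles, topK = 40L, bottomK = 40L,
                                species = "unknown") {
  if (is.character(profiles) && length(profiles) == 1L) {
    raw <- utils::read.delim(profiles, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    profiles <- raw
  }
  if (is.data.frame(profiles)) {
    genes <- as.character(profiles[[1]])
    m <- as.matrix(profiles[-1])
    rownames(m) <- genes
    profiles <- m
  }
  storage.mode(profiles) <- "numeric"
  if (anyNA(profiles))
    stop("parse error: non-numeric or missing score in profile matrix")
  conds <- colnames(profiles)
  if (is.null(conds) || anyDuplicated(conds))
    stop("profile conditions must be uniquely named")
  ord <- order(conds)           # lexicographic tie-break baseline
  profiles <- profiles[, ord, drop = FALSE]
  conds <- conds[ord]
  res <- lapply(rownames(profiles), function(g) {
    s <- profiles[g, ]
    ## order is stable, so prior sort by condition id breaks score ties
    top <- conds[order(-s)][seq_len(min(topK, length(s)))]
    bot <- conds[order(s)][seq_len(min(bottomK, length(s)))]
    union(top, bot)
  })
  n <- lengths(res)
  out <- data.frame(species = species,
                    phenotype_id = unlist(res, use.names = FALSE),
                    phenotype_name = unlist(res, use.names = FALSE),
                    gene_id = rep(rownames(profiles), n),
                    stringsAsFactors = FALSE)
  .validateAssociations(if (nrow(out)) out else .emptyAssociations())
}

#' Expand expression location/stage annotations into phenotypes
#'
#' Turns in-situ expression annotations (gene, anatomical location,
#' developmental stage) into phenotypes: every location becomes a phenotype;
#' additionally, for locations with more than `locationGeneThreshold` distinct
#' genes, every stage there with more than `stageMinGenes` distinct genes
#' becomes a phenotype named `"<location> at stage <x>"`. Both thresholds are
#' strict inequalities.
#'
#' @param annotations data.frame with columns `gene`, `location`, `stage`
#'   (stage may be NA/empty).
#' @param locationGeneThreshold locations must exceed this many distinct
#'   genes before stage phenotypes are created (default 50).
#' @param stageMinGenes stages must exceed this many distinct genes
#'   (default 3).
#' @param species species label for the resulting associations.
#' @return Association data.frame.
#' @export
expandLocationStage <- function(annotations, locationGeneThreshold = 50L,
                                stageMinGenes = 3L, species = "unknown") {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "location", "stage") %in% names(annotations)))
  a <- data.frame(gene = as.character(annotations$gene),
                  location = as.character(annotations$location),
                  stage = as.character(annotations$stage),
                  stringsAsFactors = FALSE)
  a <- a[nzchar(a$gene) & nzchar(a$location), , drop = FALSE]
  loc <- unique(a[c("gene", "location")])
  out <- data.frame(species = species, phenotype_id = loc$location,
                    phenotype_name = loc$location, gene_id = loc$gene,
                    stringsAsFactors = FALSE)
  nloc <- tapply(loc$gene, loc$location, length)
  bigLocs <- names(nloc)[nloc > locationGeneThreshold]
  st <- a[a$location %in% bigLocs & !is.na(a$stage) & nzchar(a$stage), ,
          drop = FALSE]
  if (nrow(st)) {
    st <- unique(st)
    stKey <- paste(st$location, "at stage", st$stage)
    nst <- tapply(st$gene, stKey, length)
    keep <- stKey %in% names(nst)[nst > stageMinGenes]
    if (any(keep)) {
      out <- rbind(out, data.frame(
        species = species, phenotype_id = stKey[keep],
        phenotype_name = stKey[keep], gene_id = st$gene[keep],
        stringsAsFactors = FALSE))
    }
  }
  .validateAssociations(if (nrow(out)) out else .emptyAssociations())
}

#' Build a binary phenotype incidence matrix
#'
#' Constructs the element-by-phenotype 0/1 matrix for one species (elements =
#' genes) or one species pair (elements = orthogroups; the table must first
#' be projected with [projectToOrthogroups()] and the same map supplied so
#' the row universe covers all orthogroups of the pair, including
#' unannotated ones). Element and phenotype orderings are lexicographic.
#'
#' @param table association data.frame; for `elementKind = "orthogroups"` it
#'   must carry an `orthogroup_id` column.
#' @param elementKind `"genes"` or `"orthogroups"`.
#' @param map [OrthologyMap-class]; required for orthogroup matrices.
#' @param universe optional character vector fixing the element universe
#'   (rows); elements in the table but outside the universe are dropped with
#'   a message. Defaults to the elements present in the table (genes) or all
#'   orthogroups of `map`.
#' @return A [PhenotypeMatrix-class].
#' @export
buildMatrix <- function(table, elementKind = c("genes", "orthogroups"),
                        map = NULL, universe = NULL) {
  elementKind <- match.arg(elementKind)
  if (elementKind == "orthogroups") {
    if (is.null(map))
      stop("an OrthologyMap is required for orthogroup matrices")
    if (!"orthogroup_id" %in% names(table))
      stop("table must be projected to orthogroups first ",
           "(missing orthogroup_id column)")
    elemCol <- "orthogroup_id"
    if (is.null(universe)) universe <- orthogroupIds(map)
    scope <- map@speciesPair
  } else {
    table <- .validateAssociations2(table)
    elemCol <- "gene_id"
    if (is.null(universe)) universe <- unique(table$gene_id)
    scope <- if (nrow(table)) sort(unique(table$species)) else "none"
    if (length(scope) > 1L)
      stop("a gene matrix must cover a single species; found: ",
           paste(scope, collapse = ", "))
  }
  universe <- sort(unique(as.character(universe)))
  elems <- as.character(table[[elemCol]])
  inUniverse <- elems %in% universe
  if (any(!inUniverse)) {
    message(sum(!inUniverse), " association(s) dropped: element absent ",
            "from the element universe")
    table <- table[inUniverse, , drop = FALSE]
    elems <- elems[inUniverse]
  }
  key <- .phenKey(table$species, table$phenotype_id)
  pkeys <- sort(unique(key))
  inc <- Matrix::sparseMatrix(
    i = match(elems, universe), j = match(key, pkeys), x = 1,
    dims = c(length(universe), length(pkeys)),
    dimnames = list(universe, pkeys), use.last.ij = TRUE)
  inc <- methods::as(methods::as(inc, "CsparseMatrix"), "generalMatrix")
  inc@x[] <- 1                               # collapse duplicates to binary
  info <- data.frame(key = pkeys, stringsAsFactors = FALSE)
  parts <- do.call(rbind, .splitKey(pkeys))
  if (length(pkeys)) {
    info$species <- parts[, 1]
    info$phenotype_id <- parts[, 2]
    nm <- table$phenotype_name[match(pkeys, key)]
    info$phenotype_name <- nm
  } else {
    info$species <- character()
    info$phenotype_id <- character()
    info$phenotype_name <- character()
  }
  info$cardinality <- unname(Matrix::colSums(inc))
  new("PhenotypeMatrix", incidence = inc, elementKind = elementKind,
      speciesScope = scope, phenotypeInfo = info)
}
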