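#' Load a pairwise orthology table
#'
#' Reads a normalized orthology TSV (columns `orthogroup_id`, `species`,
#' `gene_id`; an optional 4th confidence column is ignored) describing the
#' orthogroups shared by two species. Lines starting with `#` are skipped; a
#' header row naming the three columns is required.
#'
#' @param path path to the TSV file.
#' @param speciesA,speciesB the two species the file covers; any other
#'   species value in the file is an error.
#' @return An [OrthologyMap-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("orthogroup_id\tspecies\tgene_id",
#'              "G1\thuman\th1", "G1\tmouse\tm1"), tf)
#' loadOrthology(tf, "human", "mouse")
#' @export
loadOrthology <- function(path, speciesA, speciesB) {
  tab <- .readTsv(path, c("orthogroup_id", "species", "gene_id"),
                  allowExtra = TRUE)
  OrthologyMap(tab, speciesA, speciesB)
}

## shared strict TSV reader: header required, '#' comments skipped, empty
## required fields rejected with the offending line number
.readTsv <- function(path, columns, allowExtra = FALSE,
                     optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(stats::setNames(
      as.data.frame(replicate(length(columns), character(), simplify = FALSE),
                    stringsAsFactors = FALSE), columns))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(columns, header)
  if (length(missing))
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "),
         " in header of ", path)
  body <- lines[-1]
  lineno <- lineno[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- length(header)
  short <- nf < length(columns) | (!allowExtra & nf > want)
  if (any(short))
    stop("parse error: malformed row at line ", lineno[which(short)[1]],
         " of ", path)
  out <- lapply(seq_along(header), function(j)
    vapply(fields, function(f) if (length(f) >= j) f[j] else "", character(1)))
  names(out) <- header
  out <- as.data.frame(out[intersect(header, c(columns, optional))],
                       stringsAsFactors = FALSE)
  required <- setdiff(columns, optional)
  for (col in required) {
    bad <- !nzchar(trimws(out[[col]]))
    if (any(bad))
      stop("parse error: empty '", col, "' at line ", lineno[which(bad)[1]],
           " of ", path)
  }
  out
}

#' Translate gene--phenotype associations into another species (gene-based)
#'
#' Implements the gene-based matrix framework: every (source gene, phenotype)
#' record becomes one record per gene of the target species that shares an
#' orthogroup with the source gene. Source genes with no orthogroup in the
#' pair contribute nothing; duplicates are collapsed. Note that a single
#' source association can fan out into several target-species associations
#' when the gene family has expanded in the target lineage, which is what
#' makes gene-based similarity asymmetric between search directions.
#'
#' @param assoc association data.frame (see [readAssociations()]); only the
#'   records of `source` are translated.
#' @param source,target species names; must be the pair covered by `map`.
#' @param map an [OrthologyMap-class] for the pair.
#' @return Association data.frame whose `gene_id` column holds target-species
#'   genes and whose `gene_species` column is `target`; `species` still names
#'   the species the phenotype belongs to.
#' @export
translateGeneBased <- function(assoc, source, target, map) {
  assoc <- .validateAssociations(assoc)
  if (source == target) stop("configuration error: source == target")
  if (!all(c(source, target) %in% map@speciesPair))
    stop("configuration error: (", source, ", ", target,
         ") is not the pair of the supplied OrthologyMap")
  a <- assoc[assoc$species == source, , drop = FALSE]
  if (!nrow(a)) return(.emptyAssociations(geneSpecies = TRUE))
  og <- groupOf(map, source, a$gene_id)
  keep <- !is.na(og)
  a <- a[keep, , drop = FALSE]
  og <- og[keep]
  if (!nrow(a)) return(.emptyAssociations(geneSpecies = TRUE))
  members <- membersOf(map, target)[og]
  n <- lengths(members)
  out <- data.frame(
    species        = rep(a$species, n),
    phenotype_id   = rep(a$phenotype_id, n),
    phenotype_name = rep(a$phenotype_name, n),
    gene_id        = unlist(members, use.names = FALSE),
    gene_species   = target,
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("species", "phenotype_id", "gene_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project gene--phenotype associations onto orthogroups of a species pair
#'
#' Implements the orthogroup-based matrix framework: a record (orthogroup,
#' phenotype) is present iff at least one member gene of the orthogroup (on
#' the phenotype's own species side) carries the phenotype. Genes without an
#' orthogroup in the pair are dropped: the element universe is restricted to
#' elements shared by the two species. The result is independent of which
#' species of the pair is treated as the prediction target.
#'
#' @param assoc association data.frame; all its species must belong to the
#'   pair of `map`.
#' @param map an [OrthologyMap-class].
#' @return data.frame with columns `species`, `phenotype_id`,
#'   `phenotype_name`, `orthogroup_id` (one row per orthogroup-level
#'   association).
#' @export
projectToOrthogroups <- function(assoc, map) {
  assoc <- .validateAssociations(assoc)
  bad <- setdiff(unique(assoc$species), map@speciesPair)
  if (length(bad))
    stop("configuration error: species outside the pair: ",
         paste(bad, collapse = ", "))
  if (!nrow(assoc))
    return(data.frame(species = character(), phenotype_id = character(),
                      phenotype_name = character(),
                      orthogroup_id = character(), stringsAsFactors = FALSE))
  og <- unname(map@geneIndex[.geneKey(assoc$species, assoc$gene_id)])
  keep <- !is.na(og)
  out <- data.frame(
    species        = assoc$species[keep],
    phenotype_id   = assoc$phenotype_id[keep],
    phenotype_name = assoc$phenotype_name[keep],
    orthogroup_id  = og[keep],
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("species", "phenotype_id", "orthogroup_id")]), ,
             drop = FALSE]
  ## deterministic ordering
  out <- out[order(out$species, out$phenotype_id, out$orthogroup_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
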