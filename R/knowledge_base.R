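#' Load the lipopeptide knowledge base
#'
#' Reads the packaged (or a user-supplied) family table into an
#' [LpKnowledgeBase]. The packaged table encodes the 13 lipopeptide
#' families with their `[l:m]` signatures, module-configuration templates,
#' peptide variants and flanking-gene templates, plus the predicted LPs
#' that match no family template.
#'
#' @param path JSON family table; default: the packaged table.
#' @param predictedPath JSON predicted-LP table; default: packaged.
#' @return an [LpKnowledgeBase].
#' @export
loadKnowledgeBase <- function(path = NULL, predictedPath = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lp_families.json", package = "lipomine")
  if (is.null(predictedPath))
    predictedPath <- system.file("extdata", "lp_predicted.json", package = "lipomine")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  fams <- lapply(raw$families, function(f) {
    v <- f$variants
    variants <- data.frame(
      name = vapply(v, `[[`, character(1), "name"),
      leu5Stereo = vapply(v, function(x)
        if (is.null(x$leu5_stereo)) NA_character_ else x$leu5_stereo, character(1)),
      source = vapply(v, `[[`, character(1), "source"),
      provenance = vapply(v, `[[`, character(1), "provenance"),
      stringsAsFactors = FALSE
    )
    variants$sequence <- lapply(v, `[[`, "sequence")
    fam <- tryCatch(new("LpFamily",
        name = f$name,
        peptideLength = as.integer(f$peptide_length),
        macrocycleSize = as.integer(f$macrocycle_size),
        moduleConfigs = if (is.matrix(f$module_configs)) {
          lapply(seq_len(nrow(f$module_configs)), function(r)
            as.integer(f$module_configs[r, ]))
        } else lapply(f$module_configs, as.integer),
        organizations = as.character(f$organizations),
        variants = variants,
        taxonGroups = as.character(f$taxon_groups),
        accessoryGenes = f$accessory_genes,
        superfamily = if (is.null(f$superfamily)) NA_integer_
                      else as.integer(f$superfamily)),
      error = function(e)
        stop(sprintf("knowledge base row '%s' is corrupt: %s", f$name,
                     conditionMessage(e)), call. = FALSE))
    fam
  })
  praw <- jsonlite::fromJSON(predictedPath, simplifyDataFrame = FALSE,
                             simplifyVector = TRUE)
  predicted <- data.frame(
    name = vapply(praw$predicted, `[[`, character(1), "name"),
    derivedFrom = vapply(praw$predicted, `[[`, character(1), "derived_from"),
    mechanism = vapply(praw$predicted, `[[`, character(1), "mechanism"),
    stringsAsFactors = FALSE
  )
  predicted$sequence <- lapply(praw$predicted, `[[`, "sequence")
  kb <- new("LpKnowledgeBase", families = fams,
            alphabet = as.character(raw$alphabet),
            predicted = predicted, version = raw$schema_version)
  ok <- validObject(kb, test = TRUE)
  if (!isTRUE(ok)) stop("corrupt knowledge base: ", ok, call. = FALSE)
  kb
}

.kbCache <- new.env(parent = emptyenv())

#' Default knowledge base (cached)
#' @return the packaged [LpKnowledgeBase].
#' @export
defaultKnowledgeBase <- function() {
  if (is.null(.kbCache$kb)) .kbCache$kb <- loadKnowledgeBase()
  .kbCache$kb
}

#' List all lipopeptide families
#'
#' @param kb an [LpKnowledgeBase]; default: packaged.
#' @return list of [LpFamily], each family exactly once, stable order.
#' @export
lpFamilies <- function(kb = defaultKnowledgeBase()) kb@families

#' Look up one family by name (case-insensitive)
#'
#' @inheritParams lpFamilies
#' @param name family identifier.
#' @return the matching [LpFamily].
#' @export
lpFamily <- function(name, kb = defaultKnowledgeBase()) {
  nm <- vapply(kb@families, function(f) f@name, character(1))
  i <- match(tolower(name), tolower(nm))
  if (is.na(i)) {
    stop(sprintf("unknown family '%s'; valid names: %s",
                 name, paste(nm, collapse = ", ")), call. = FALSE)
  }
  kb@families[[i]]
}

#' Families with a given peptide length
#'
#' Length alone is not unique: Orfamide and Poaeamide share the 10:8
#' signature, so downstream assignment must disambiguate.
#'
#' @inheritParams lpFamilies
#' @param peptideLength residue count (>= 1).
#' @return list of matching [LpFamily] (possibly empty).
#' @export
familiesByLength <- function(peptideLength, kb = defaultKnowledgeBase()) {
  stopifnot(peptideLength >= 1)
  Filter(function(f) f@peptideLength == peptideLength, kb@families)
}

#' Peptide variants of a family
#'
#' @inheritParams lpFamily
#' @return the family's variant data.frame, in packaged order.
#' @export
familyVariants <- function(name, kb = defaultKnowledgeBase()) {
  lpFamily(name, kb)@variants
}

#' Predicted lipopeptides outside the family templates
#' @inheritParams lpFamilies
#' @return data.frame of predicted LPs.
#' @export
predictedLps <- function(kb = defaultKnowledgeBase()) kb@predicted

# accessors used throughout the package --------------------------------------

#' @describeIn lpFamily family name accessor
#' @param family an [LpFamily].
#' @export
familyName <- function(family) family@name

#' @describeIn lpFamily peptide length accessor
#' @export
peptideLength <- function(family) family@peptideLength

#' @describeIn lpFamily macrocycle size accessor
#' @export
macrocycleSize <- function(family) family@macrocycleSize

#' @describeIn lpFamily module configuration templates
#' @export
moduleConfigs <- function(family) family@moduleConfigs

#' @describeIn lpFamily allowed genomic organizations
#' @export
organizations <- function(family) family@organizations

#' @describeIn lpFamily superfamily number (NA when unassigned)
#' @export
superfamily <- function(family) family@superfamily
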