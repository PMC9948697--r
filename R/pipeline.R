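#' lipomine: mining and classification of Pseudomonas lipopeptide NRPS systems
#'
#' See the package vignette for the model, the diagnostic rules and the
#' synthetic-data design.
#'
#' @keywords internal
#' @aliases lipomine-package
"_PACKAGE"

#' Mine, predict and classify lipopeptide BGCs in one pass
#'
#' Runs the full pipeline on an annotated genome: candidate NRPS
#' detection, diagnostic exclusions, organization resolution and synteny,
#' peptide prediction under collinearity, and family/variant assignment.
#' The full lineage reference database (including Thanafactin) is used for
#' specificity calls, since family assignment for thanafactin producers is
#' in the pipeline's scope.
#'
#' @param genome an [LpGenome].
#' @param kb knowledge base.
#' @param refs A-domain reference database; default: packaged lineages,
#'   Thanafactin included.
#' @param domainRefs domain reference library for the caller.
#' @param threshold domain score threshold.
#' @return list with one entry per retained BGC: `bgc` ([BgcRecord]),
#'   `prediction` (`PeptidePrediction`), `assignment`
#'   (`FamilyAssignment`); plus `excludedGenes` and `partial`.
#' @export
mineLipopeptides <- function(genome, kb = defaultKnowledgeBase(),
                             refs = lpReferenceDomains(kb,
                               includeThanafactin = TRUE),
                             domainRefs = domainReferenceLibrary(),
                             threshold = 0.5) {
  mined <- mineGenome(genome, domainRefs, threshold, kb)
  hits <- lapply(mined$bgcs, function(b) {
    pred <- predictPeptide(b@system, refs)
    list(bgc = b, prediction = pred,
         assignment = assignFamily(pred, b, refs, kb))
  })
  list(hits = hits, partial = mined$partial,
       excludedGenes = mined$excludedGenes)
}

#' Tabulate pipeline hits for TSV/JSON export
#'
#' @param hits the `hits` element returned by [mineLipopeptides()].
#' @return data.frame, one row per BGC: organization, predicted peptide,
#'   ambiguity count, family call and evidence.
#' @export
predictionTable <- function(hits) {
  do.call(rbind, lapply(hits, function(h) {
    data.frame(
      systemId = h$bgc@system@id,
      genomeId = h$bgc@genomeId,
      organization = h$bgc@organization,
      nModules = nrow(h$bgc@system@modules),
      peptide = paste(h$prediction$sequencePrimary, collapse = "-"),
      nAmbiguous = h$prediction$nAmbiguous,
      family = h$assignment$family,
      status = h$assignment$status,
      matchedVariant = h$assignment$matchedVariant,
      impliedMacrocycle = h$assignment$impliedMacrocycle,
      homologyScore = h$assignment$evidence$homologyScore,
      stringsAsFactors = FALSE)
  }))
}
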