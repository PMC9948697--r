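# A-domain substrate specificity by nearest-reference identity, mirroring
# the clade behaviour of the curated database: homogeneous Leu/Val/Ser
# clades, a promiscuous Ile clade (can recruit Val/Leu), and an
# intertwined Glu/Gln/Asp clade reported as ambiguous at low confidence.

.ACIDIC <- c("Glu", "Gln", "Asp")

#' Classify the substrate specificity of an A domain
#'
#' Nearest-neighbour call over pairwise identity to the reference set.
#' The ambiguity set is expanded to every specificity whose best reference
#' lies within `delta` of the nearest hit; Glu/Gln/Asp mutually inflate
#' each other's ambiguity whenever confidence falls below the acidic-clade
#' threshold; an Ile call below the promiscuity threshold carries the
#' `{Val, Leu}` alternates; calls below the confidence floor are labelled
#' `unknown`.
#'
#' @param aSequence query A-domain sequence.
#' @param refs reference data.frame (`id`, `sequence`, `specificity`, ...).
#' @param delta ambiguity half-width on identity (default 0.05).
#' @param acidicThreshold confidence below which Glu/Gln/Asp calls inflate
#'   each other (default 0.75).
#' @param promiscuityThreshold Ile confidence below which Val/Leu
#'   alternates are reported (default 0.9).
#' @param floor confidence below which the call is `unknown` (default 0.4).
#' @return one-row data.frame: `primary`, `confidence`, `ambiguitySet`
#'   (comma-joined), `promiscuity` (comma-joined or `""`), `neighborId`.
#' @export
classifySpecificity <- function(aSequence, refs, delta = 0.05,
                                acidicThreshold = 0.75,
                                promiscuityThreshold = 0.9, floor = 0.4) {
  if (is.null(refs) || !nrow(refs))
    stop("configuration error: empty reference set", call. = FALSE)
  ident <- identityToRefs(aSequence, refs$sequence)
  best <- max(ident)
  # deterministic tie-break: lexicographically smallest reference id wins
  top <- which(ident == best)
  top <- top[order(refs$id[top])][1]
  primary <- refs$specificity[top]
  amb <- unique(refs$specificity[ident >= best - delta])
  tiedSpecs <- unique(refs$specificity[ident == best])
  amb <- unique(c(primary, amb, tiedSpecs))
  if (primary %in% .ACIDIC && best < acidicThreshold) {
    amb <- unique(c(amb, .ACIDIC))
  }
  promiscuity <- if (primary == "Ile" && best < promiscuityThreshold) {
    c("Val", "Leu")
  } else character()
  if (best < floor) primary <- "unknown"
  data.frame(primary = primary, confidence = best,
             ambiguitySet = paste(sort(unique(amb)), collapse = ","),
             promiscuity = paste(promiscuity, collapse = ","),
             neighborId = refs$id[top], stringsAsFactors = FALSE)
}

#' Neighbor-joining clade tree of A domains with specificity colouring
#'
#' Builds an identity-distance NJ tree over references plus optional
#' queries and reports, per specificity, whether its leaves form a
#' monophyletic group (an unrooted split separating exactly those leaves).
#'
#' @param refs reference data.frame; optionally rbind queries with their
#'   own `specificity` labels.
#' @return list with `tree` (ape `phylo`, tip labels = ids), `leafSpec`
#'   (named specificity per leaf) and `monophyly` (named logical).
#' @export
cladeTree <- function(refs) {
  if (nrow(refs) < 4L) stop("need >= 4 sequences for a clade tree",
                            call. = FALSE)
  dm <- distanceMatrix(stats::setNames(refs$sequence, refs$id))
  tree <- njTree(dm)
  spec <- stats::setNames(refs$specificity, refs$id)
  mono <- vapply(unique(spec), function(s) {
    tipsIn <- names(spec)[spec == s]
    if (length(tipsIn) <= 1L || length(tipsIn) == length(spec)) return(TRUE)
    .hasSplit(tree, tipsIn)
  }, logical(1))
  list(tree = tree, leafSpec = spec, monophyly = mono)
}

# does the unrooted tree contain a split separating exactly `tips`?
.hasSplit <- function(tree, tips) {
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  want <- sort(match(tips, labs))
  all <- seq_along(labs)
  for (p in bp) {
    if (identical(sort(p), want) || identical(sort(setdiff(all, p)), want))
      return(TRUE)
  }
  # prop.part on unrooted trees enumerates clades of an arbitrary rooting;
  # also accept the complement splits induced by internal edges
  FALSE
}
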