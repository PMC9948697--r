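# Peptide prediction under the collinearity rule, family/variant
# assignment, variant position comparison (Q-S switches) and superfamily
# grouping by A-domain homology profiles.

#' Predict the peptide encoded by an NRPS system
#'
#' One specificity call per module, in module order (bifurcate initiator
#' first): the collinearity rule maps module order to residue order.
#'
#' @param system a validated [NrpsSystem] (`teTandem` must be `TRUE`).
#' @param refs A-domain reference data.frame.
#' @param ... passed to [classifySpecificity()].
#' @return list of class `PeptidePrediction`: `systemId`, `calls`
#'   (data.frame, one row per module), `sequencePrimary` (residue vector),
#'   `nAmbiguous`.
#' @export
predictPeptide <- function(system, refs, ...) {
  if (!system@teTandem)
    stop("system failed LP validation (no TE tandem); refusing prediction",
         call. = FALSE)
  mods <- system@modules
  if (any(is.na(mods$aSequence)) || !nrow(mods))
    stop("prediction error: module without an A domain", call. = FALSE)
  calls <- do.call(rbind, lapply(seq_len(nrow(mods)), function(i)
    classifySpecificity(mods$aSequence[i], refs, ...)))
  calls$index <- mods$index
  ambiguous <- vapply(strsplit(calls$ambiguitySet, ","), length,
                      integer(1)) > 1L
  structure(list(systemId = system@id, calls = calls,
                 sequencePrimary = calls$primary,
                 nAmbiguous = sum(ambiguous)),
            class = "PeptidePrediction")
}

#' @export
print.PeptidePrediction <- function(x, ...) {
  cat(sprintf("PeptidePrediction %s: %s (%d ambiguous)\n", x$systemId,
              paste(x$sequencePrimary, collapse = "-"), x$nAmbiguous))
  invisible(x)
}

# does predicted sequence match a variant, treating ambiguous positions as
# matching any member of their ambiguity set
.ambiguityMatch <- function(prediction, variantSeq) {
  if (length(prediction$sequencePrimary) != length(variantSeq)) return(FALSE)
  ambSets <- strsplit(prediction$calls$ambiguitySet, ",")
  all(vapply(seq_along(variantSeq), function(i) {
    variantSeq[i] == prediction$sequencePrimary[i] ||
      variantSeq[i] %in% ambSets[[i]] ||
      (nzchar(prediction$calls$promiscuity[i]) &&
         variantSeq[i] %in% strsplit(prediction$calls$promiscuity[i], ",")[[1]])
  }, logical(1)))
}

#' Assign a predicted peptide to a lipopeptide family
#'
#' Candidate families are those with the predicted length; disambiguation
#' uses (i) module distribution against the family templates, (ii) genomic
#' organization and (iii) mean A-domain identity to each family's
#' reference lineages (this resolves Orfamide vs Poaeamide, which share
#' the 10:8 signature but differ in organization and NRPS similarity).
#' The implied macrocycle is copied from the family definition, never
#' derived from the sequence (TE phylogeny has poor discriminatory value
#' for the cyclization pattern).
#'
#' @param prediction a `PeptidePrediction`.
#' @param bgc the source [BgcRecord] (organization + module distribution
#'   evidence); may be `NULL`.
#' @param refs reference data.frame with `system` = family for the
#'   homology profile score (the packaged lineage database).
#' @param kb knowledge base.
#' @param homologyThreshold minimal family homology score for a
#'   `new_variant` call (default 0.7).
#' @return list of class `FamilyAssignment`: `family`, `status`
#'   (`known_member`, `new_variant`, `candidate_new_family`, `unassigned`),
#'   `matchedVariant`, `impliedMacrocycle`, `evidence`.
#' @export
assignFamily <- function(prediction, bgc = NULL, refs,
                         kb = defaultKnowledgeBase(),
                         homologyThreshold = 0.7) {
  n <- length(prediction$sequencePrimary)
  candidates <- familiesByLength(n, kb)
  aSeqs <- if (!is.null(bgc)) bgc@system@modules$aSequence else NULL
  famScore <- function(fam) {
    sub <- refs[refs$system == fam@name, , drop = FALSE]
    if (!nrow(sub) || is.null(aSeqs)) return(NA_real_)
    mean(vapply(aSeqs, function(q) max(identityToRefs(q, sub$sequence)),
                numeric(1)))
  }
  if (!length(candidates)) {
    return(structure(list(family = NA_character_,
                          status = "candidate_new_family",
                          matchedVariant = NA_character_,
                          impliedMacrocycle = NA_integer_,
                          evidence = list(organizationMatch = NA,
                                          homologyScore = NA_real_)),
                     class = "FamilyAssignment"))
  }
  moduleDist <- if (!is.null(bgc) && nrow(bgc@system@modules)) {
    as.integer(table(factor(bgc@system@modules$gene,
                            levels = unique(bgc@system@modules$gene))))
  } else NULL
  score <- vapply(candidates, function(fam) {
    s <- 0
    if (!is.null(moduleDist) &&
        any(vapply(fam@moduleConfigs, function(cfg)
          identical(as.integer(cfg), moduleDist), logical(1)))) s <- s + 1
    if (!is.null(bgc) && bgc@organization %in% fam@organizations) s <- s + 1
    s
  }, numeric(1))
  hom <- vapply(candidates, famScore, numeric(1))
  rank <- order(-score, -ifelse(is.na(hom), -Inf, hom))
  fam <- candidates[[rank[1]]]
  homScore <- hom[rank[1]]
  orgMatch <- if (!is.null(bgc)) bgc@organization %in% fam@organizations else NA
  v <- fam@variants
  matched <- NA_character_
  for (i in seq_len(nrow(v))) {
    if (.ambiguityMatch(prediction, v$sequence[[i]])) {
      matched <- v$name[i]
      break
    }
  }
  status <- if (!is.na(matched)) "known_member"
            else if (!is.na(homScore) && homScore >= homologyThreshold)
              "new_variant"
            else if (is.na(homScore)) "new_variant"  # no homology evidence
            else "candidate_new_family"
  structure(list(family = if (status %in% c("known_member", "new_variant"))
                   fam@name else NA_character_,
                 status = status,
                 matchedVariant = matched,
                 impliedMacrocycle = if (status %in%
                     c("known_member", "new_variant")) fam@macrocycleSize
                   else NA_integer_,
                 evidence = list(organizationMatch = orgMatch,
                                 homologyScore = homScore)),
            class = "FamilyAssignment")
}

#' @export
print.FamilyAssignment <- function(x, ...) {
  cat(sprintf("FamilyAssignment: %s (%s%s)\n",
              ifelse(is.na(x$family), "unassigned", x$family), x$status,
              ifelse(is.na(x$matchedVariant), "",
                     paste0(", variant ", x$matchedVariant))))
  invisible(x)
}

#' Variable positions among aligned peptide variants
#'
#' @param sequences list (or matrix rows) of equal-length residue vectors.
#' @return list: `positions` (1-based positions where >= 2 residues
#'   occur), `pairwiseDifferences` (data.frame `i`, `j`, `n`), `qsSwitches`
#'   (positions among `positions` where the variation is exactly a
#'   Gln <-> Ser substitution).
#' @export
compareVariants <- function(sequences) {
  lens <- vapply(sequences, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("input error: sequences have unequal lengths", call. = FALSE)
  m <- do.call(rbind, sequences)
  positions <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  qs <- positions[vapply(positions, function(p)
    setequal(unique(m[, p]), c("Gln", "Ser")), logical(1))]
  pairs <- utils::combn(length(sequences), 2)
  pd <- data.frame(i = pairs[1, ], j = pairs[2, ],
                   n = apply(pairs, 2, function(ij)
                     sum(m[ij[1], ] != m[ij[2], ])))
  list(positions = positions, pairwiseDifferences = pd, qsSwitches = qs)
}

#' A-domain homology profiles and superfamily grouping
#'
#' All A domains across the given systems are clustered by average-linkage
#' at an identity cutoff; each system's profile is its ordered vector of
#' cluster ids. Systems whose profiles overlap (shared cluster ids over
#' the shorter profile length) at or above the threshold are grouped, and
#' the partition is read off the connected components of the resulting
#' graph.
#'
#' @param systems named list of A-domain sequence vectors (one entry per
#'   system, ordered by module).
#' @param identityCutoff average-linkage merge cutoff on identity
#'   (default 0.6, i.e. distance 0.4).
#' @param overlapThreshold profile overlap needed to join a superfamily
#'   (default 0.5).
#' @return list: `profiles` (named list of cluster-id vectors), `groups`
#'   (named integer membership vector), `overlap` (pairwise overlap
#'   matrix).
#' @export
superfamilyGroup <- function(systems, identityCutoff = 0.6,
                             overlapThreshold = 0.5) {
  if (!length(systems)) {
    return(list(profiles = list(), groups = integer(), overlap = NULL))
  }
  allSeqs <- unlist(systems, use.names = FALSE)
  sysOf <- rep(names(systems), vapply(systems, length, integer(1)))
  n <- length(allSeqs)
  cl <- if (n == 1L) 1L else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      ident <- identityToRefs(allSeqs[i], allSeqs[(i + 1):n])
      d[i, (i + 1):n] <- 1 - ident
      d[(i + 1):n, i] <- 1 - ident
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    stats::cutree(hc, h = 1 - identityCutoff)
  }
  profiles <- split(cl, sysOf)[names(systems)]
  names(profiles) <- names(systems)
  k <- length(systems)
  ov <- matrix(1, k, k, dimnames = list(names(systems), names(systems)))
  overlapOf <- function(a, b) {
    shared <- sum(pmin(table(factor(a, levels = unique(c(a, b)))),
                       table(factor(b, levels = unique(c(a, b))))))
    shared / min(length(a), length(b))
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) ov[i, j] <- ov[j, i] <- overlapOf(profiles[[i]], profiles[[j]])
  }
  g <- igraph::graph_from_adjacency_matrix(ov >= overlapThreshold,
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  list(profiles = profiles, groups = stats::setNames(as.integer(comp),
                                                     names(systems)),
       overlap = ov)
}

#' Profile matrix export (systems x module positions)
#'
#' @param result output of [superfamilyGroup()].
#' @param residues optional named list of residue vectors matching the
#'   systems, appended as `clusterId:residue` cells.
#' @return character matrix, rows = systems, columns = module positions.
#' @export
profileMatrix <- function(result, residues = NULL) {
  k <- length(result$profiles)
  width <- max(vapply(result$profiles, length, integer(1)))
  m <- matrix("", k, width,
              dimnames = list(names(result$profiles), seq_len(width)))
  for (i in seq_len(k)) {
    p <- result$profiles[[i]]
    cells <- as.character(p)
    if (!is.null(residues)) {
      cells <- paste(cells, residues[[names(result$profiles)[i]]], sep = ":")
    }
    m[i, seq_along(p)] <- cells
  }
  m
}
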