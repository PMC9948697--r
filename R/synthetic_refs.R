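# Synthetic reference universe: per-kind domain anchors, per-specificity
# A-domain anchors, and per-(family, position, residue) A-domain lineages.
# All derive from a fixed internal library seed so that genomes generated
# under any user seed remain classifiable against one packaged universe;
# SimConfig seeds drive only divergence, layout and jitter.

#' Construct a synthetic-data configuration
#'
#' @param seed master seed (integer).
#' @param nRefsPerSpecificity diverged copies per substrate in
#'   [makeReferenceSet()].
#' @param domainLength named lengths for A, C, T, TE and E domains (aa).
#' @param mutationRate per-site substitution probability.
#' @param spacerRange intergenic spacer bounds (bp) inside contiguous operons.
#' @param decoyGeneCount decoy genes per synthetic genome.
#' @param peakJitter HSQC jitter SDs `(1H ppm, 13C ppm)`.
#' @return a [SimConfig].
#' @export
simConfig <- function(seed = 1L,
                      nRefsPerSpecificity = 3L,
                      domainLength = c(A = 450L, C = 440L, T = 80L,
                                       TE = 230L, E = 300L),
                      mutationRate = 0.05,
                      spacerRange = c(150L, 300L),
                      decoyGeneCount = 3L,
                      peakJitter = c(0.01, 0.1)) {
  new("SimConfig",
      seed = as.integer(seed),
      nRefsPerSpecificity = as.integer(nRefsPerSpecificity),
      domainLength = vapply(domainLength, as.integer, integer(1)),
      mutationRate = as.numeric(mutationRate),
      spacerRange = as.integer(spacerRange),
      decoyGeneCount = as.integer(decoyGeneCount),
      peakJitter = as.numeric(peakJitter))
}

.refCache <- new.env(parent = emptyenv())

# per-specificity A-domain anchors; rejection sampling keeps every anchor
# pair below 40% mutual identity (random 450-mers sit near 6%, so this is a
# guard, not a search)
specificityAnchors <- function(domainLength = 450L, maxTries = 50L) {
  key <- paste0("anchors_", domainLength)
  if (!is.null(.refCache[[key]])) return(.refCache[[key]])
  kb <- defaultKnowledgeBase()
  anchors <- withTagSeed(.LIBRARY_SEED, "specificity-anchors", {
    out <- list()
    for (res in kb@alphabet) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        cand <- randomProtein(domainLength)
        if (all(vapply(out, function(a) hammingIdentity(a, cand) < 0.4,
                       logical(1)))) {
          out[[res]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not satisfy anchor divergence constraints",
                    call. = FALSE)
    }
    out
  })
  .refCache[[key]] <- anchors
  anchors
}

# non-A domain anchors, one per structural kind
domainKindAnchors <- function(config = simConfig()) {
  dl <- config@domainLength
  key <- paste0("kinds_", paste(dl, collapse = "_"))
  if (!is.null(.refCache[[key]])) return(.refCache[[key]])
  kinds <- withTagSeed(.LIBRARY_SEED, "domain-kind-anchors", {
    list(Cs = randomProtein(dl[["C"]]),
         LCL = randomProtein(dl[["C"]]),
         CE = randomProtein(dl[["C"]]),
         T = randomProtein(dl[["T"]]),
         TE = randomProtein(dl[["TE"]]),
         E = randomProtein(dl[["E"]]))
  })
  .refCache[[key]] <- kinds
  kinds
}

# A-domain lineage for one (family, position, residue): the specificity
# anchor diverged at a fixed per-lineage rate, emulating how real A domains
# of one substrate differ between systems yet stay within their clade
.LINEAGE_DIVERGENCE <- 0.25

lineageSequence <- function(family, position, residue, domainLength = 450L) {
  key <- sprintf("lin_%s_%02d_%s_%d", family, position, residue, domainLength)
  if (!is.null(.refCache[[key]])) return(.refCache[[key]])
  anchor <- specificityAnchors(domainLength)[[residue]]
  if (is.null(anchor)) stop("unknown residue: ", residue, call. = FALSE)
  seqv <- withTagSeed(.LIBRARY_SEED, key,
                      mutateProtein(anchor, .LINEAGE_DIVERGENCE))
  .refCache[[key]] <- seqv
  seqv
}

#' Synthetic A-domain reference set over the LP residue alphabet
#'
#' For each residue of the alphabet, takes its specificity anchor (fixed,
#' packaged) and emits `nRefsPerSpecificity` copies diverged at the
#' configured mutation rate. Anchors for different specificities are
#' mutually < 40% identical by construction.
#'
#' @param config a [SimConfig]; `seed` drives the divergence draws.
#' @return data.frame with columns `id`, `sequence`, `specificity`,
#'   `system`, `position`.
#' @export
makeReferenceSet <- function(config = simConfig()) {
  stopifnot(config@nRefsPerSpecificity >= 1L)
  anchors <- specificityAnchors(config@domainLength[["A"]])
  withTagSeed(config@seed, "make-reference-set", {
    rows <- list()
    for (res in names(anchors)) {
      for (k in seq_len(config@nRefsPerSpecificity)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_ref%02d", res, k),
          sequence = mutateProtein(anchors[[res]], config@mutationRate),
          specificity = res,
          system = "synthetic",
          position = k,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Curated-style A-domain reference database from the knowledge base
#'
#' One reference per (family, module position, residue) across the
#' characterized peptide variants: the packaged lineage sequences that the
#' BGC generator also descends from, i.e. the synthetic stand-in for a
#' database of A domains with experimentally determined specificity.
#' Thanafactin behaves as a homogeneous outgroup and is excluded by
#' default, mirroring its separate treatment in clade analyses.
#'
#' @param kb an [LpKnowledgeBase].
#' @param domainLength A-domain length (aa).
#' @param includeThanafactin include the Thanafactin lineages (the
#'   end-to-end miner sets this to `TRUE`).
#' @param includePredicted include references from predicted-only variants.
#' @return data.frame with columns `id`, `sequence`, `specificity`,
#'   `system`, `position`.
#' @export
lpReferenceDomains <- function(kb = defaultKnowledgeBase(),
                               domainLength = 450L,
                               includeThanafactin = FALSE,
                               includePredicted = FALSE) {
  rows <- list()
  for (f in kb@families) {
    if (!includeThanafactin && f@name == "Thanafactin") next
    v <- f@variants
    if (!includePredicted) v <- v[v$source == "characterized", , drop = FALSE]
    seen <- character()
    for (i in seq_len(nrow(v))) {
      sq <- v$sequence[[i]]
      for (p in seq_along(sq)) {
        key <- paste(f@name, p, sq[p], sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_m%02d_%s", f@name, p, sq[p]),
          sequence = lineageSequence(f@name, p, sq[p], domainLength),
          specificity = sq[p],
          system = f@name,
          position = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write/read labelled A-domain reference FASTA
#'
#' Header dialect: `id|specificity|system|position`.
#' @param refs reference data.frame as from [makeReferenceSet()].
#' @param path FASTA file path.
#' @export
writeReferenceFasta <- function(refs, path) {
  seqs <- Biostrings::AAStringSet(refs$sequence)
  names(seqs) <- sprintf("%s|%s|%s|%s", refs$id, refs$specificity,
                         refs$system, refs$position)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
readReferenceFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, character(1), 1),
    sequence = as.character(seqs),
    specificity = vapply(parts, `[`, character(1), 2),
    system = vapply(parts, `[`, character(1), 3),
    position = as.integer(vapply(parts, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
}
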