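# Module-level diversification: sliding-window identity profiles over
# aligned NRPS concatenates, module alignment between systems, and
# duplication / deletion / exchange event calls.

#' Sliding-window identity profile of two protein sequences
#'
#' Sequences are globally aligned (BLOSUM62); percent identity is then
#' computed in windows of `window` alignment columns sliding by one, with
#' gap columns counting as mismatches. Values are binned
#' full (100) / mid (30-99) / low (< 30), the three-colour scheme used for
#' NRPS backbone comparisons.
#'
#' @param a,b protein sequences.
#' @param window window width in alignment columns (default 50).
#' @return data.frame: `position` (window center, 1-based alignment
#'   column), `identity` (percent), `bin`.
#' @export
windowedIdentity <- function(a, b, window = 50L) {
  aln <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = .blosum62(),
                           gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT,
                           type = "global")
  pa <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  windowedIdentityFromAlignment(pa, ps, window)
}

#' @rdname windowedIdentity
#' @param pa,ps aligned sequences as character vectors (gaps as `"-"`).
#' @export
windowedIdentityFromAlignment <- function(pa, ps, window = 50L) {
  L <- length(pa)
  if (window > L) stop("input error: window exceeds alignment length",
                       call. = FALSE)
  match <- as.numeric(pa == ps & pa != "-")
  cums <- c(0, cumsum(match))
  starts <- seq_len(L - window + 1L)
  ident <- (cums[starts + window] - cums[starts]) / window * 100
  bin <- ifelse(ident >= 100, "full", ifelse(ident >= 30, "mid", "low"))
  data.frame(position = starts + (window - 1L) / 2, identity = ident,
             bin = bin, stringsAsFactors = FALSE)
}

# global module-level NW alignment maximising summed A-domain identity with
# a linear gap penalty; deterministic traceback preference:
# diagonal > up (gap in B) > left (gap in A)
.moduleAlign <- function(identMat, gapPenalty = 0.4) {
  nA <- nrow(identMat)
  nB <- ncol(identMat)
  S <- matrix(0, nA + 1L, nB + 1L)
  S[, 1] <- -gapPenalty * (0:nA)
  S[1, ] <- -gapPenalty * (0:nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    S[i + 1, j + 1] <- max(S[i, j] + identMat[i, j],
                           S[i, j + 1] - gapPenalty,
                           S[i + 1, j] - gapPenalty)
  }
  i <- nA; j <- nB
  path <- list()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(S[i + 1, j + 1], S[i, j] + identMat[i, j]))) {
      path[[length(path) + 1L]] <- c(i, j)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 &&
               isTRUE(all.equal(S[i + 1, j + 1], S[i, j + 1] - gapPenalty))) {
      path[[length(path) + 1L]] <- c(i, NA)
      i <- i - 1L
    } else {
      path[[length(path) + 1L]] <- c(NA, j)
      j <- j - 1L
    }
  }
  do.call(rbind, rev(path))
}

#' Align two NRPS systems at module level and call diversification events
#'
#' Modules are aligned globally with match score = pairwise A-domain
#' identity and a linear gap penalty. Unaligned runs in the shorter system
#' are reported as deletions (with flanking-module homology evidence);
#' aligned module pairs whose specificities differ while both flanking
#' pairs match are reported as exchanges (terminal modules are reported as
#' substitutions instead); adjacent near-identical modules within either
#' system are reported as duplications.
#'
#' @param sysA,sysB [NrpsSystem] objects (A must be the longer or equal
#'   system for deletion reporting; the function orients internally).
#' @param specA,specB optional per-module specificity labels (truth or
#'   classifier output) used for exchange calls.
#' @param gapPenalty module gap penalty (default 0.4).
#' @param duplicationThreshold adjacent-module identity for duplication
#'   calls (default 0.9).
#' @param matchThreshold aligned-pair identity regarded as homologous
#'   flank support (default 0.7).
#' @return list: `alignment` (data.frame `a`, `b`, `identity`), `events`
#'   (data.frame `kind`, `system`, `modules`, `evidence`).
#' @export
alignModules <- function(sysA, sysB, specA = NULL, specB = NULL,
                         gapPenalty = 0.4, duplicationThreshold = 0.9,
                         matchThreshold = 0.7) {
  modA <- sysA@modules$aSequence
  modB <- sysB@modules$aSequence
  if (!length(modA) || !length(modB))
    stop("input error: empty module list", call. = FALSE)
  swapped <- length(modB) > length(modA)
  if (swapped) {
    tmp <- list(sysA, specA)
    sysA <- sysB; specA <- specB
    sysB <- tmp[[1]]; specB <- tmp[[2]]
    modA <- sysA@modules$aSequence
    modB <- sysB@modules$aSequence
  }
  identMat <- matrix(0, length(modA), length(modB))
  for (i in seq_along(modA)) {
    identMat[i, ] <- identityToRefs(modA[i], modB)
  }
  path <- .moduleAlign(identMat, gapPenalty)
  alignment <- data.frame(
    a = path[, 1], b = path[, 2],
    identity = ifelse(is.na(path[, 1]) | is.na(path[, 2]), NA_real_,
                      identMat[cbind(path[, 1], path[, 2])]))
  events <- list()
  addEvent <- function(kind, system, modules, evidence) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, system = system,
      modules = paste(modules, collapse = ","),
      evidence = evidence, stringsAsFactors = FALSE)
  }
  # deletions: runs of modules in the longer system A with no partner in B
  gapRows <- which(is.na(alignment$b))
  if (length(gapRows)) {
    runs <- split(gapRows, cumsum(c(TRUE, diff(gapRows) > 1)))
    for (run in runs) {
      mods <- alignment$a[run]
      before <- alignment[seq_len(min(run) - 1L), , drop = FALSE]
      after <- alignment[-seq_len(max(run)), , drop = FALSE]
      flankIdent <- c(utils::tail(stats::na.omit(before$identity), 1),
                      utils::head(stats::na.omit(after$identity), 1))
      addEvent("deletion", sysB@id, mods,
               sprintf("span=%d; flanking identities %s", length(mods),
                       paste(round(flankIdent, 3), collapse = "/")))
    }
  }
  # exchanges: aligned pairs with differing specificity, matched flanks
  if (!is.null(specA) && !is.null(specB)) {
    aligned <- which(!is.na(alignment$a) & !is.na(alignment$b))
    for (r in aligned) {
      i <- alignment$a[r]; j <- alignment$b[r]
      if (specA[i] == specB[j]) next
      prev <- alignment[alignment$a %in% (i - 1L) & alignment$b %in% (j - 1L), ]
      nxt <- alignment[alignment$a %in% (i + 1L) & alignment$b %in% (j + 1L), ]
      flankOk <- nrow(prev) == 1L && nrow(nxt) == 1L &&
        !is.na(prev$identity) && prev$identity >= matchThreshold &&
        !is.na(nxt$identity) && nxt$identity >= matchThreshold
      terminal <- i == 1L || i == length(modA) || j == 1L || j == length(modB)
      if (flankOk && !terminal) {
        addEvent("exchange", paste(sysA@id, sysB@id, sep = "|"),
                 c(i, j), sprintf("%s->%s", specA[i], specB[j]))
      } else if (terminal && specA[i] != specB[j]) {
        addEvent("substitution", paste(sysA@id, sysB@id, sep = "|"),
                 c(i, j), sprintf("terminal %s->%s", specA[i], specB[j]))
      }
    }
  }
  for (d in list(list(sysA, "A"), list(sysB, "B"))) {
    dup <- detectDuplications(d[[1]], threshold = duplicationThreshold)
    if (nrow(dup)) {
      for (r in seq_len(nrow(dup))) {
        addEvent("duplication", d[[1]]@id, dup$modules[r], dup$evidence[r])
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), system = character(), modules = character(),
               evidence = character(), stringsAsFactors = FALSE)
  list(alignment = alignment, events = ev, swapped = swapped)
}

#' Detect adjacent-module duplications within one system
#'
#' Adjacent near-identical A domains within a gene hint at module
#' duplication; all adjacent pairs at or above the identity threshold are
#' reported.
#'
#' @param sys an [NrpsSystem] (>= 2 modules).
#' @param threshold A-domain identity threshold (default 0.9).
#' @return data.frame: `kind`, `modules` (`"i,i+1"`), `evidence`
#'   (identity).
#' @export
detectDuplications <- function(sys, threshold = 0.9) {
  mods <- sys@modules$aSequence
  out <- list()
  if (length(mods) >= 2L) {
    for (i in seq_len(length(mods) - 1L)) {
      ident <- adomainIdentity(mods[i], mods[i + 1L])
      if (ident >= threshold) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "duplication", modules = paste(i, i + 1L, sep = ","),
          evidence = sprintf("identity=%.3f", ident),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), modules = character(),
               evidence = character(), stringsAsFactors = FALSE)
}
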