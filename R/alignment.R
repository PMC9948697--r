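#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject AAString
NULL

.alnCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.alnCache$b62)) {
    data("BLOSUM62", package = "Biostrings", envir = .alnCache)
    .alnCache$b62 <- .alnCache$BLOSUM62
  }
  .alnCache$b62
}

# gap parameters used for all protein alignments in the package
.GAP_OPEN <- 10
.GAP_EXT <- 0.5

#' Fractional identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with affine gaps
#' (open 10, extend 0.5); identity is matches over alignment columns after
#' discarding terminal-gap columns, so length overhangs are not penalised.
#' Symmetric in its arguments.
#'
#' @param a,b protein sequences (plain strings).
#' @return identity in `[0, 1]`.
#' @export
adomainIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  assertAminoAcid(c(a, b))
  # canonical argument order makes the value exactly symmetric even when
  # co-optimal alignments differ between orientations
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = .blosum62(),
                           gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT,
                           type = "global")
  pa <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  alignedIdentity(pa, ps)
}

# identity over columns of an alignment given as two character vectors,
# excluding terminal-gap columns; internal gap columns count as mismatches
alignedIdentity <- function(pa, ps) {
  n <- length(pa)
  nonA <- which(pa != "-")
  nonB <- which(ps != "-")
  lo <- max(min(nonA), min(nonB))
  hi <- min(max(nonA), max(nonB))
  if (lo > hi) return(0)
  keep <- lo:hi
  mean(pa[keep] == ps[keep] & pa[keep] != "-")
}

# identity of one query against many references. Equal-length pairs use the
# exact positional (Hamming) identity: extracted domains and their
# references share the reference window length, where the ungapped diagonal
# is the relevant global alignment. Unequal-length pairs fall back to full
# alignment identity.
identityToRefs <- function(query, refSeqs) {
  qi <- utf8ToInt(query)
  vapply(refSeqs, function(r) {
    ri <- utf8ToInt(r)
    if (length(ri) == length(qi)) mean(ri == qi)
    else adomainIdentity(query, r)
  }, numeric(1))
}
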