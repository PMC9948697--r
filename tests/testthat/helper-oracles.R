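# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Gotoh affine-gap global alignment score (gap of length L costs
# open + ext * L), plain-R dynamic programme
gotohScore <- function(a, b, submat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive optimal peak assignment: minimises the count of unmatched
# peaks (cost 1 each) plus the summed normalised distance of accepted
# pairs (d <= 1); for n <= 8 reference peaks
exhaustiveAssignment <- function(query, ref, tolH, tolC) {
  nq <- nrow(query); nr <- nrow(ref)
  d <- outer(seq_len(nq), seq_len(nr), function(i, j)
    sqrt(((query$h_ppm[i] - ref$h_ppm[j]) / tolH)^2 +
           ((query$c_ppm[i] - ref$c_ppm[j]) / tolC)^2))
  best <- list(cost = Inf, pairs = NULL)
  # enumerate injective partial assignments query -> ref via permutations
  # of ref slots padded with "unmatched" slots
  slots <- c(seq_len(nr), rep(0L, nq))
  perms <- function(v, k) {
    if (k == 0) return(list(integer()))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i], k - 1)
      for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
    }
    out
  }
  seen <- new.env()
  for (p in perms(slots, nq)) {
    key <- paste(p, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    used <- p[p > 0]
    if (anyDuplicated(used)) next
    cost <- 0
    pairs <- 0L
    ok <- TRUE
    for (i in seq_len(nq)) {
      if (p[i] == 0L) cost <- cost + 1
      else if (d[i, p[i]] > 1) { ok <- FALSE; break }
      else { cost <- cost + d[i, p[i]]; pairs <- pairs + 1L }
    }
    if (!ok) next
    cost <- cost + (nr - pairs)  # unmatched reference peaks
    if (cost < best$cost) best <- list(cost = cost, nMatched = pairs)
  }
  best
}

# helpers to fabricate NrpsSystem objects from residue vectors using the
# packaged lineage sequences (zero extra divergence)
syntheticSystem <- function(residues, family = "Xantholysin", id = "sys") {
  seqs <- vapply(seq_along(residues), function(i)
    lipomine:::lineageSequence(family, i, residues[i]), character(1))
  systemFromAseqs(seqs, id)
}

systemFromAseqs <- function(aSeqs, id = "sys") {
  n <- length(aSeqs)
  mods <- data.frame(index = seq_len(n), gene = rep("g1", n),
                     cKind = if (n) c("Cs", rep("CE", n - 1L)) else character(),
                     aStart = rep(NA_integer_, n), aEnd = rep(NA_integer_, n),
                     aSequence = aSeqs, hasT = rep(TRUE, n),
                     stringsAsFactors = FALSE)
  new("NrpsSystem", id = id, genes = "g1", modules = mods, teTandem = TRUE,
      concatenate = paste(aSeqs, collapse = ""))
}

# drop modules (1-based indices) from a system, renumbering
dropModules <- function(sys, drop) {
  mods <- sys@modules[-drop, , drop = FALSE]
  mods$index <- seq_len(nrow(mods))
  rownames(mods) <- NULL
  new("NrpsSystem", id = paste0(sys@id, "_del"), genes = sys@genes,
      modules = mods, teTandem = TRUE,
      concatenate = paste(mods$aSequence, collapse = ""))
}
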