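# HSQC CH-alpha fingerprint matching and dereplication. Peak lists are
# data.frames (peak_id, h_ppm, c_ppm); matching solves an optimal
# one-to-one assignment under tolerance-normalised distances.

# Jonker-Volgenant shortest augmenting path solver for the square linear
# assignment problem (no LSAP solver among the installed packages);
# O(n^3), deterministic. Returns column assigned to each row.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

.BIGCOST <- 1e6

#' Match two HSQC CH-alpha peak lists
#'
#' Peaks are paired by an optimal one-to-one assignment minimising the
#' summed tolerance-normalised distance
#' `d = sqrt((dH/tolH)^2 + (dC/tolC)^2)`; candidate pairs with `d > 1` are
#' rejected (handled by augmenting the cost matrix with dummy nodes at
#' cost 1 per unmatched peak). Coverage is matched peaks over the larger
#' list size; `shiftRmsd` is the RMS of the normalised distances over
#' accepted pairs (dimensionless; 0 = perfect overlay, 1 = at tolerance).
#'
#' @param query,ref peak lists (`peak_id`, `h_ppm`, `c_ppm`).
#' @param tolH,tolC matching tolerances in ppm (defaults 0.03 / 0.4,
#'   typical HSQC reproducibility under identical acquisition conditions).
#' @param coverageThreshold verdict threshold on coverage (default 0.9).
#' @param rmsdCap verdict cap on `shiftRmsd` (default 1, i.e. within
#'   tolerance on average).
#' @return list of class `MatchResult`: `reference`, `nMatched`,
#'   `coverage`, `shiftRmsd`, `verdict`, `pairs` (data.frame `query`,
#'   `ref`, `d`).
#' @export
matchPeaks <- function(query, ref, tolH = 0.03, tolC = 0.4,
                       coverageThreshold = 0.9, rmsdCap = 1) {
  stopifnot(tolH > 0, tolC > 0)
  if (!nrow(query) || !nrow(ref))
    stop("input error: empty peak list", call. = FALSE)
  nq <- nrow(query)
  nr <- nrow(ref)
  d <- outer(seq_len(nq), seq_len(nr), function(i, j) {
    sqrt(((query$h_ppm[i] - ref$h_ppm[j]) / tolH)^2 +
           ((query$c_ppm[i] - ref$c_ppm[j]) / tolC)^2)
  })
  n <- nq + nr
  cost <- matrix(0, n, n)
  cost[seq_len(nq), seq_len(nr)] <- ifelse(d > 1, .BIGCOST, d)
  cost[seq_len(nq), nr + seq_len(nq)] <- .BIGCOST
  cost[cbind(seq_len(nq), nr + seq_len(nq))] <- 1
  cost[nq + seq_len(nr), seq_len(nr)] <- .BIGCOST
  cost[cbind(nq + seq_len(nr), seq_len(nr))] <- 1
  assign <- solveAssignment(cost)
  qi <- seq_len(nq)
  matchedCols <- assign[qi]
  keep <- matchedCols <= nr & d[cbind(qi, pmin(matchedCols, nr))] <= 1
  pairs <- data.frame(query = query$peak_id[qi[keep]],
                      ref = ref$peak_id[matchedCols[keep]],
                      d = d[cbind(qi[keep], matchedCols[keep])],
                      stringsAsFactors = FALSE)
  nMatched <- nrow(pairs)
  coverage <- nMatched / max(nq, nr)
  shiftRmsd <- if (nMatched) sqrt(mean(pairs$d^2)) else NA_real_
  verdict <- if (nMatched && coverage >= coverageThreshold &&
                 shiftRmsd <= rmsdCap) "match" else "no_match"
  structure(list(reference = attr(ref, "compound") %||% "reference",
                 nMatched = nMatched, coverage = coverage,
                 shiftRmsd = shiftRmsd, verdict = verdict, pairs = pairs),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult vs %s: %s (coverage %.2f, RMSD %.3f, n=%d)\n",
              x$reference, x$verdict, x$coverage,
              ifelse(is.na(x$shiftRmsd), NaN, x$shiftRmsd), x$nMatched))
  invisible(x)
}

#' Dereplicate a query fingerprint against a reference library
#'
#' @param query peak list.
#' @param library named list of reference peak lists.
#' @param tolH,tolC tolerances in ppm.
#' @param ... passed to [matchPeaks()].
#' @return list of `MatchResult`, sorted by verdict (matches first), then
#'   coverage (desc), then RMSD (asc).
#' @export
dereplicate <- function(query, library, tolH = 0.03, tolC = 0.4, ...) {
  if (!length(library))
    stop("configuration error: empty reference library", call. = FALSE)
  results <- lapply(names(library), function(nm) {
    ref <- library[[nm]]
    attr(ref, "compound") <- nm
    matchPeaks(query, ref, tolH, tolC, ...)
  })
  ord <- order(vapply(results, function(r) r$verdict != "match", logical(1)),
               -vapply(results, `[[`, numeric(1), "coverage"),
               vapply(results, function(r)
                 ifelse(is.na(r$shiftRmsd), Inf, r$shiftRmsd), numeric(1)))
  results[ord]
}

#' Synthetic CH-alpha reference fingerprint of a peptide variant
#'
#' One CH-alpha cross-peak per residue, with seeded positions inside the
#' CH-alpha region (1H 3.5-5.5 ppm, 13C 48-65 ppm); positions are fixed
#' per variant by the packaged library seed.
#'
#' @param variantName variant (compound) name from the knowledge base.
#' @param kb knowledge base.
#' @return peak list data.frame.
#' @export
referenceFingerprint <- function(variantName, kb = defaultKnowledgeBase()) {
  hit <- NULL
  for (f in kb@families) {
    i <- match(tolower(variantName), tolower(f@variants$name))
    if (!is.na(i)) { hit <- f@variants$sequence[[i]]; break }
  }
  if (is.null(hit)) stop("unknown variant: ", variantName, call. = FALSE)
  n <- length(hit)
  withTagSeed(.LIBRARY_SEED, paste("hsqc-ref", tolower(variantName)), {
    data.frame(peak_id = sprintf("%s_CHa%d", gsub("\\s+", "_", variantName),
                                 seq_len(n)),
               h_ppm = stats::runif(n, 3.5, 5.5),
               c_ppm = stats::runif(n, 48, 65),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a measured HSQC peak list for a variant
#'
#' Reference fingerprint perturbed by Gaussian jitter with the configured
#' standard deviations; one peak per residue.
#'
#' @param variantName variant (compound) name.
#' @param config a [SimConfig] (`peakJitter`, `seed`).
#' @param kb knowledge base.
#' @return peak list data.frame.
#' @export
makeHsqc <- function(variantName, config = simConfig(),
                     kb = defaultKnowledgeBase()) {
  ref <- referenceFingerprint(variantName, kb)
  withTagSeed(config@seed, paste("make-hsqc", tolower(variantName)), {
    ref$h_ppm <- ref$h_ppm + stats::rnorm(nrow(ref), 0, config@peakJitter[1])
    ref$c_ppm <- ref$c_ppm + stats::rnorm(nrow(ref), 0, config@peakJitter[2])
    ref
  })
}

#' Read/write peak-list CSV (`peak_id`, `h_ppm`, `c_ppm`)
#' @param peaks peak list data.frame.
#' @param path CSV path.
#' @export
writePeakList <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePeakList
#' @export
readPeakList <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peak_id", "h_ppm", "c_ppm") %in% names(p)))
  if (any(!is.finite(p$h_ppm)) || any(!is.finite(p$c_ppm)))
    stop("input error: non-finite chemical shifts", call. = FALSE)
  p
}

#' Build the packaged synthetic spectral library
#'
#' @param variantNames compound names (default: all characterized variants).
#' @param kb knowledge base.
#' @return named list of reference peak lists.
#' @export
spectralLibrary <- function(variantNames = NULL, kb = defaultKnowledgeBase()) {
  if (is.null(variantNames)) {
    variantNames <- unlist(lapply(kb@families, function(f)
      f@variants$name[f@variants$source == "characterized"]))
  }
  stats::setNames(lapply(variantNames, referenceFingerprint, kb = kb),
                  variantNames)
}
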