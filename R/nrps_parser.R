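# Domain calling on candidate NRPS proteins, module segmentation and
# multi-gene system assembly in biosynthetic order.

#' Domain reference library for the caller
#'
#' Exemplar sequences per structural kind (Cs, LCL, CE, T, TE, E) plus one
#' A-domain exemplar per substrate specificity. The caller slides each
#' exemplar along the protein and reports windows above the per-kind score
#' threshold.
#'
#' @param config a [SimConfig] (domain lengths).
#' @return data.frame with columns `kind`, `reference`, `sequence`.
#' @export
domainReferenceLibrary <- function(config = simConfig()) {
  kinds <- domainKindAnchors(config)
  anchors <- specificityAnchors(config@domainLength[["A"]])
  rbind(
    data.frame(kind = c("Cs", "LCL", "CE", "T", "TE", "E"),
               reference = c("Cs", "LCL", "CE", "T", "TE", "E"),
               sequence = unlist(kinds[c("Cs", "LCL", "CE", "T", "TE", "E")]),
               stringsAsFactors = FALSE),
    data.frame(kind = "A", reference = names(anchors),
               sequence = unlist(anchors), stringsAsFactors = FALSE))
}

# coarse windowed identity of `refChars` at every offset of `protChars`
# (stride `by`), fully vectorised
.windowScan <- function(protInt, refInt, by = 10L) {
  W <- length(refInt)
  L <- length(protInt)
  if (L < W) return(data.frame(offset = integer(), identity = numeric()))
  offsets <- seq.int(1L, L - W + 1L, by = by)
  idx <- outer(offsets - 1L, seq_len(W), `+`)
  m <- matrix(protInt[idx], nrow = length(offsets))
  ident <- rowMeans(m == matrix(refInt, nrow = length(offsets), ncol = W,
                                byrow = TRUE))
  data.frame(offset = offsets, identity = ident)
}

# refine a coarse hit to the stride-1 local identity maximum
.refineHit <- function(protInt, refInt, offset, halo = 12L) {
  W <- length(refInt)
  lo <- max(1L, offset - halo)
  hi <- min(length(protInt) - W + 1L, offset + halo)
  cand <- lo:hi
  ident <- vapply(cand, function(o)
    mean(protInt[o:(o + W - 1L)] == refInt), numeric(1))
  best <- cand[which.max(ident)]
  list(offset = best, identity = max(ident))
}

#' Call NRPS domains on a protein
#'
#' Windowed nearest-reference scan: each reference exemplar slides along
#' the protein (stride 10, then stride-1 local refinement); windows are
#' scored by global-alignment identity against the exemplar, and hits with
#' score >= the per-kind threshold are selected greedily best-score-first
#' with overlap suppression (ties: higher score, then longer hit, then
#' smaller start).
#'
#' @param protein protein sequence (string; may contain `*` for internal
#'   stops, which are reported via the `hasStop` attribute).
#' @param refs domain reference library, see [domainReferenceLibrary()].
#' @param threshold per-kind minimum score (single value applied to all
#'   kinds).
#' @param capture coarse-scan identity needed before a window is refined.
#' @return data.frame of non-overlapping annotations ordered by `start`
#'   (0-based half-open): `kind`, `start`, `end`, `score`, `reference`.
#' @export
callDomains <- function(protein, refs = domainReferenceLibrary(),
                        threshold = 0.5, capture = 0.35) {
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  protChars <- strsplit(protein, "")[[1]]
  protInt <- utf8ToInt(protein)
  hits <- list()
  for (r in seq_len(nrow(refs))) {
    refInt <- utf8ToInt(refs$sequence[r])
    coarse <- .windowScan(protInt, refInt, by = 10L)
    coarse <- coarse[coarse$identity >= capture, , drop = FALSE]
    if (!nrow(coarse)) next
    # collapse runs of adjacent qualifying offsets into one candidate each
    grp <- cumsum(c(TRUE, diff(coarse$offset) > length(refInt) / 2))
    for (g in unique(grp)) {
      sub <- coarse[grp == g, , drop = FALSE]
      seedOff <- sub$offset[which.max(sub$identity)]
      ref <- .refineHit(protInt, refInt, seedOff)
      winSeq <- substr(protein, ref$offset, ref$offset + length(refInt) - 1L)
      score <- if (grepl("\\*", winSeq)) ref$identity
               else adomainIdentity(winSeq, refs$sequence[r])
      if (score >= threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          kind = refs$kind[r], start = ref$offset - 1L,
          end = ref$offset - 1L + length(refInt), score = score,
          reference = refs$reference[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(kind = character(), start = integer(), end = integer(),
                      score = numeric(), reference = character(),
                      stringsAsFactors = FALSE)
  } else {
    h <- do.call(rbind, hits)
    h <- h[order(-h$score, -(h$end - h$start), h$start), , drop = FALSE]
    taken <- rep(FALSE, nchar(protein))
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      span <- (h$start[i] + 1L):h$end[i]
      if (!any(taken[span])) {
        keep[i] <- TRUE
        taken[span] <- TRUE
      }
    }
    out <- h[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "hasStop") <- grepl("\\*", protein)
  out
}

#' Read/write domain tables (adapter for external annotations)
#'
#' TSV dialect: `protein_id`, `kind`, `start`, `end` (0-based half-open),
#' optional `score`, `reference`.
#'
#' @param domains data.frame with a `proteinId` column plus the annotation
#'   columns.
#' @param path TSV path.
#' @export
writeDomainTable <- function(domains, path) {
  utils::write.table(domains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDomainTable
#' @export
readDomainTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Segment called domains into modules
#'
#' Modules are delimited at each condensation-type domain (Cs, LCL, CE);
#' trailing TE domains attach to the final module. Structured warnings are
#' raised for an A domain without a following T, or a C-type domain without
#' a following A.
#'
#' @param domains annotation data.frame from [callDomains()] (ordered,
#'   non-overlapping).
#' @param protein optional protein sequence used to extract A-domain
#'   sequences into the module table.
#' @return data.frame of modules: `index`, `cKind`, `aStart`, `aEnd`,
#'   `aSequence`, `hasT`; attribute `teTandem` flags terminal TE-TE;
#'   attribute `teCount` gives the trailing TE count; attribute `hasE`
#'   flags standalone epimerization domains.
#' @export
segmentModules <- function(domains, protein = NULL) {
  if (!sum(domains$kind == "A")) stop("parse error: zero A domains", call. = FALSE)
  ckinds <- c("Cs", "LCL", "CE")
  n <- nrow(domains)
  modules <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) modules[[length(modules) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_len(n)) {
    k <- domains$kind[i]
    if (k %in% ckinds) {
      if (!is.null(cur) && is.na(cur$aStart))
        warning("module with C domain but no A domain", call. = FALSE)
      flush()
      cur <- list(cKind = k, aStart = NA_integer_, aEnd = NA_integer_,
                  hasT = FALSE)
    } else if (k == "A") {
      if (is.null(cur)) {
        warning("module without C domain", call. = FALSE)
        cur <- list(cKind = "none", aStart = NA_integer_, aEnd = NA_integer_,
                    hasT = FALSE)
      } else if (!is.na(cur$aStart)) {
        # second A in a row opens a new (C-less) module
        warning("module without C domain", call. = FALSE)
        flush()
        cur <- list(cKind = "none", aStart = NA_integer_, aEnd = NA_integer_,
                    hasT = FALSE)
      }
      cur$aStart <- domains$start[i]
      cur$aEnd <- domains$end[i]
    } else if (k == "T") {
      if (!is.null(cur)) {
        if (is.na(cur$aStart)) warning("T domain without preceding A domain",
                                       call. = FALSE)
        cur$hasT <- TRUE
        flush()
      }
    }
  }
  if (!is.null(cur)) {
    if (!is.na(cur$aStart)) warning("module without T domain", call. = FALSE)
    flush()
  }
  out <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(index = i, cKind = m$cKind, aStart = m$aStart, aEnd = m$aEnd,
               hasT = m$hasT, stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$aStart), , drop = FALSE]
  out$index <- seq_len(nrow(out))
  out$aSequence <- if (!is.null(protein)) {
    substr(rep(protein, nrow(out)), out$aStart + 1L, out$aEnd)
  } else NA_character_
  # trailing TE domains after the last module
  lastNonTe <- max(which(domains$kind != "TE"), 0L)
  teCount <- sum(domains$kind == "TE" & seq_len(n) > lastNonTe)
  attr(out, "teCount") <- teCount
  attr(out, "teTandem") <- teCount >= 2L
  attr(out, "hasE") <- any(domains$kind == "E")
  rownames(out) <- NULL
  out
}

#' Assemble a multi-gene NRPS system in biosynthetic order
#'
#' Orders parsed genes so the gene starting with a Cs domain comes first
#' and the gene ending in the TE-TE tandem last; middle genes keep genomic
#' order. Module indices are renumbered 1..n across genes.
#'
#' @param genes list of parsed genes, each a list with `id`, `protein`,
#'   `domains` (from [callDomains()]) and optionally precomputed
#'   `modules`.
#' @param id system identifier.
#' @param orderHint `"operon_order"` (middle genes keep the supplied,
#'   i.e. genomic, order) or `"initiator_first"`; the initiator gene is
#'   promoted to the front in either mode, so the modes differ only in how
#'   the supplied order is interpreted for middle genes.
#' @return an [NrpsSystem]; `teTandem` is `FALSE` (validation failure, the
#'   system is excluded from the LP set) when the tandem is missing.
#' @export
assembleSystem <- function(genes, id = "system",
                           orderHint = c("operon_order", "initiator_first")) {
  orderHint <- match.arg(orderHint)
  parsed <- lapply(genes, function(g) {
    mods <- if (!is.null(g$modules)) g$modules
            else segmentModules(g$domains, g$protein)
    list(id = g$id, protein = g$protein, modules = mods,
         startsCs = nrow(mods) > 0 && mods$cKind[1] == "Cs",
         teTandem = isTRUE(attr(mods, "teTandem")))
  })
  csIdx <- which(vapply(parsed, `[[`, logical(1), "startsCs"))
  if (length(csIdx) != 1L) {
    stop(sprintf(
      "assembly error: expected exactly one Cs-initiated gene, found %d (%s)",
      length(csIdx),
      paste(vapply(parsed[csIdx], `[[`, character(1), "id"), collapse = ", ")),
      call. = FALSE)
  }
  teIdx <- which(vapply(parsed, `[[`, logical(1), "teTandem"))
  ord <- c(csIdx, setdiff(seq_along(parsed), unique(c(csIdx, teIdx))),
           setdiff(teIdx, csIdx))
  parsed <- parsed[ord]
  modules <- do.call(rbind, lapply(parsed, function(p) {
    m <- p$modules
    m$gene <- p$id
    m
  }))
  modules$index <- seq_len(nrow(modules))
  rownames(modules) <- NULL
  new("NrpsSystem", id = id,
      genes = vapply(parsed, `[[`, character(1), "id"),
      modules = modules[, c("index", "gene", "cKind", "aStart", "aEnd",
                            "aSequence", "hasT")],
      teTandem = parsed[[length(parsed)]]$teTandem,
      concatenate = paste(vapply(parsed, `[[`, character(1), "protein"),
                          collapse = ""))
}
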