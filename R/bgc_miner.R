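# Genome-level mining: candidate detection, diagnostic exclusions, flanking
# synteny, contiguous/bifurcate resolution.

# role keywords used to label flanking genes from their annotations when no
# explicit role tag is present (real-data route)
.roleKeywords <- c(
  luxR = "LuxR",
  pleA = "periplasmic adaptor",
  pleB = "(PleB|MacB|ATP-dependent transporter)",
  pleC = "outer membrane",
  syrD = "SyrD",
  dab = "aminotransferase",
  mfs = "major facilitator")

.featureRole <- function(feature) {
  if (nzchar(feature$role) && feature$role != "decoy" && feature$role != "nrps")
    return(feature$role)
  if (feature$role %in% c("decoy", "nrps")) return(feature$role)
  for (r in names(.roleKeywords)) {
    if (grepl(.roleKeywords[[r]], feature$product, ignore.case = (r != "luxR")))
      return(r)
  }
  ""
}

#' Find candidate NRPS genes in an annotated genome
#'
#' Calls domains on every protein and keeps genes with at least one A
#' domain and one condensation-type domain.
#'
#' @param genome an [LpGenome] (from [makeGenome()], [readGenbank()] or
#'   [readGff3Genome()]).
#' @param refs domain reference library.
#' @param threshold per-kind domain score threshold.
#' @return list of candidate genes: `record`, `id`, `start`, `end`,
#'   `strand`, `protein`, `domains`, `hasStop`.
#' @export
findCandidates <- function(genome, refs = domainReferenceLibrary(),
                           threshold = 0.5) {
  out <- list()
  for (rec in genome@records) {
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      if (!nzchar(f$translation[i])) {
        stop(sprintf("I/O error: record %s feature %s lacks a translation",
                     rec$id, f$locusTag[i]), call. = FALSE)
      }
      dom <- callDomains(f$translation[i], refs, threshold = threshold)
      if (sum(dom$kind == "A") >= 1L &&
          sum(dom$kind %in% c("Cs", "LCL", "CE")) >= 1L) {
        out[[length(out) + 1L]] <- list(
          record = rec$id, id = f$locusTag[i], start = f$start[i],
          end = f$end[i], strand = f$strand[i],
          protein = f$translation[i], domains = dom,
          hasStop = isTRUE(attr(dom, "hasStop")))
      }
    }
  }
  out
}

#' Apply the diagnostic lipopeptide exclusion rules
#'
#' Removes candidates carrying standalone epimerization (E) domains (a
#' pyoverdine/siderophore hallmark), genes that terminate in a single TE
#' domain (siderophore/Mycin-type), and fragmented genes with internal
#' stops. Each removal carries a named flag.
#'
#' @param candidates list from [findCandidates()].
#' @return list with `retained` (candidates, with per-gene module tables
#'   attached) and `excluded` (candidates with `flags`).
#' @export
applyExclusions <- function(candidates) {
  retained <- list()
  excluded <- list()
  for (cand in candidates) {
    flags <- character()
    if (any(cand$domains$kind == "E")) flags <- c(flags, "standalone_E")
    if (cand$hasStop) flags <- c(flags, "fragment")
    kinds <- cand$domains$kind
    lastNonTe <- max(which(kinds != "TE"), 0L)
    teCount <- sum(kinds == "TE" & seq_along(kinds) > lastNonTe)
    # terminating gene with exactly one TE: siderophore-type, not LP
    if (teCount == 1L) flags <- c(flags, "single_TE")
    if (length(flags)) {
      cand$flags <- flags
      excluded[[length(excluded) + 1L]] <- cand
    } else {
      retained[[length(retained) + 1L]] <- cand
    }
  }
  list(retained = retained, excluded = excluded)
}

#' Scan flanking genes for the conserved lipopeptide synteny
#'
#' Role-labelled neighbour scan within a configurable window on each side
#' of the cluster: upstream LuxR-family regulator (strand-aware), PleC,
#' downstream PleAB, optional second regulator, and accessory genes
#' (SyrD + Dab aminotransferase for Tolaasin-type, MFS for
#' thanafactin-type clusters).
#'
#' @param clusterGenes candidate-gene list for one cluster (same record).
#' @param genome the [LpGenome].
#' @param windowGenes neighbour genes scanned on each side.
#' @param windowBp maximal distance (bp) from the cluster edge.
#' @return synteny report list: `upstreamRegulator`, `pleC`, `pleAB`,
#'   `secondRegulator`, `accessory`.
#' @export
checkSynteny <- function(clusterGenes, genome, windowGenes = 5L,
                         windowBp = 10000L) {
  recId <- clusterGenes[[1]]$record
  rec <- genome@records[[which(vapply(genome@records, `[[`, character(1),
                                      "id") == recId)]]
  f <- rec$features
  lo <- min(vapply(clusterGenes, `[[`, numeric(1), "start"))
  hi <- max(vapply(clusterGenes, `[[`, numeric(1), "end"))
  inCluster <- f$locusTag %in% vapply(clusterGenes, `[[`, character(1), "id")
  upIdx <- which(!inCluster & f$end <= lo & f$end >= lo - windowBp)
  upIdx <- utils::tail(upIdx[order(f$end[upIdx])], windowGenes)
  downIdx <- which(!inCluster & f$start >= hi & f$start <= hi + windowBp)
  downIdx <- utils::head(downIdx[order(f$start[downIdx])], windowGenes)
  roleAt <- function(i) .featureRole(as.list(f[i, , drop = FALSE]))
  upRoles <- vapply(upIdx, roleAt, character(1))
  downRoles <- vapply(downIdx, roleAt, character(1))
  upReg <- "absent"
  luxUp <- upIdx[upRoles == "luxR"]
  if (length(luxUp)) {
    upReg <- if (any(f$strand[luxUp] == "-")) "present_antisense"
             else "present_sense"
  }
  allRoles <- c(upRoles, downRoles)
  accessory <- if (all(c("syrD", "dab") %in% allRoles)) "syrD_dab"
               else if ("mfs" %in% allRoles) "mfs" else "none"
  list(upstreamRegulator = upReg,
       pleC = "pleC" %in% allRoles,
       pleAB = all(c("pleA", "pleB") %in% downRoles),
       secondRegulator = "luxR" %in% downRoles,
       accessory = accessory)
}

# group retained candidates on one record into proximity clusters
.proximityClusters <- function(cands, maxGap = 20000L) {
  if (!length(cands)) return(list())
  ord <- order(vapply(cands, `[[`, numeric(1), "start"))
  cands <- cands[ord]
  groups <- list()
  cur <- list(cands[[1]])
  for (i in seq_along(cands)[-1]) {
    prevEnd <- cur[[length(cur)]]$end
    if (cands[[i]]$start - prevEnd <= maxGap) {
      cur[[length(cur) + 1L]] <- cands[[i]]
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- list(cands[[i]])
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

.clusterModuleCount <- function(genes) {
  sum(vapply(genes, function(g) sum(g$domains$kind == "A"), integer(1)))
}

.clusterStartsCs <- function(genes) {
  first <- genes[[which.min(vapply(genes, `[[`, numeric(1), "start"))]]
  nrow(first$domains) > 0 && first$domains$kind[1] == "Cs"
}

.clusterEndsTeTandem <- function(genes) {
  last <- genes[[which.max(vapply(genes, `[[`, numeric(1), "end"))]]
  kinds <- last$domains$kind
  n <- length(kinds)
  n >= 2 && all(kinds[c(n - 1L, n)] == "TE")
}

#' Resolve contiguous vs bifurcate organization into BGC records
#'
#' Groups retained candidate genes into proximity clusters, assembles
#' complete (Cs ... TE-TE) clusters directly, and pairs each orphan
#' initiator cluster with the operon whose module count best completes a
#' known family total (`|family_total - (initiator + operon)|` minimised
#' over the knowledge base, ties broken by A-domain homology between the
#' initiator and the operon's reference family lineages). Unpaired partial
#' systems are flagged incomplete.
#'
#' @param candidates retained candidate list (see [applyExclusions()]).
#' @param genome the [LpGenome].
#' @param kb knowledge base (family totals for pairing).
#' @param refs reference A domains used for the homology tie-break
#'   (defaults to the packaged lineage database).
#' @return list of [BgcRecord]; incomplete partial systems carry an
#'   `incomplete` exclusion flag and an empty module table is avoided by
#'   keeping their genes in the record.
#' @export
resolveOrganization <- function(candidates, genome,
                                kb = defaultKnowledgeBase(),
                                refs = NULL) {
  byRecord <- split(candidates,
                    vapply(candidates, `[[`, character(1), "record"))
  clusters <- list()
  for (recCands in byRecord) {
    for (grp in .proximityClusters(recCands)) {
      clusters[[length(clusters) + 1L]] <- grp
    }
  }
  complete <- list()
  initiators <- list()
  operons <- list()
  for (grp in clusters) {
    startsCs <- .clusterStartsCs(grp)
    endsTe <- .clusterEndsTeTandem(grp)
    if (startsCs && endsTe) complete[[length(complete) + 1L]] <- grp
    else if (startsCs) initiators[[length(initiators) + 1L]] <- grp
    else if (endsTe) operons[[length(operons) + 1L]] <- grp
    else initiators[[length(initiators) + 1L]] <- grp  # partial, unpaired later
  }
  if (length(initiators) > 1L && length(operons) > 1L) {
    scores <- expand.grid(i = seq_along(initiators), o = seq_along(operons))
    scores$score <- mapply(function(i, o)
      .pairingScore(initiators[[i]], operons[[o]], kb), scores$i, scores$o)
    stop(paste0("ambiguous initiator/operon pairing; candidate pairings ",
                "(initiator, operon, score): ",
                paste(sprintf("(%d,%d,%d)", scores$i, scores$o, scores$score),
                      collapse = " ")), call. = FALSE)
  }
  records <- list()
  mkRecord <- function(genes, organization, interDist = NA_real_,
                       flags = character()) {
    genes <- genes[order(vapply(genes, `[[`, character(1), "record"),
                         vapply(genes, `[[`, numeric(1), "start"))]
    parsed <- lapply(genes, function(g)
      list(id = g$id, protein = g$protein, domains = g$domains))
    system <- tryCatch(
      assembleSystem(parsed, id = paste(vapply(genes, `[[`, character(1),
                                               "id")[1], "system", sep = "_")),
      error = function(e) NULL)
    if (is.null(system)) {
      flags <- c(flags, "incomplete")
      system <- new("NrpsSystem", id = "incomplete",
                    genes = vapply(genes, `[[`, character(1), "id"),
                    modules = data.frame(), teTandem = FALSE, concatenate = "")
    } else if (!system@teTandem) {
      flags <- c(flags, "missing_TE_tandem")
    }
    spacers <- numeric()
    if (organization == "contiguous" && length(genes) > 1L) {
      ord <- order(vapply(genes, `[[`, numeric(1), "start"))
      st <- vapply(genes, `[[`, numeric(1), "start")[ord]
      en <- vapply(genes, `[[`, numeric(1), "end")[ord]
      spacers <- st[-1] - en[-length(en)]
    }
    # bifurcate clusters carry flank evidence on both records; scan each
    # record's gene group and merge the reports
    recIds <- unique(vapply(genes, `[[`, character(1), "record"))
    reports <- lapply(recIds, function(rid)
      checkSynteny(genes[vapply(genes, `[[`, character(1), "record") == rid],
                   genome))
    synteny <- Reduce(function(a, b) list(
      upstreamRegulator = if (a$upstreamRegulator != "absent")
        a$upstreamRegulator else b$upstreamRegulator,
      pleC = a$pleC || b$pleC,
      pleAB = a$pleAB || b$pleAB,
      secondRegulator = a$secondRegulator || b$secondRegulator,
      accessory = if (a$accessory != "none") a$accessory else b$accessory),
      reports)
    new("BgcRecord", genomeId = genome@id, system = system,
        organization = organization, interClusterDistance = interDist,
        spacers = spacers, synteny = synteny, exclusionFlags = flags)
  }
  for (grp in complete) {
    records[[length(records) + 1L]] <- mkRecord(grp, "contiguous")
  }
  usedOperons <- logical(length(operons))
  for (ini in initiators) {
    if (!.clusterStartsCs(ini)) {
      records[[length(records) + 1L]] <- mkRecord(ini, "contiguous",
                                                  flags = "incomplete")
      next
    }
    if (!length(operons) || all(usedOperons)) {
      records[[length(records) + 1L]] <- mkRecord(ini, "bifurcate",
                                                  flags = "incomplete")
      next
    }
    open <- which(!usedOperons)
    sc <- vapply(open, function(o) .pairingScore(ini, operons[[o]], kb),
                 numeric(1))
    tied <- open[sc == min(sc)]
    best <- if (length(tied) > 1L) {
      # tie-break by A-domain homology between initiator and operon
      hom <- vapply(tied, function(o)
        .clusterHomology(ini, operons[[o]]), numeric(1))
      tied[which.max(hom)]
    } else tied[1]
    usedOperons[best] <- TRUE
    pair <- c(ini, operons[[best]])
    sameRecord <- length(unique(vapply(pair, `[[`, character(1), "record"))) == 1L
    interDist <- if (sameRecord) {
      iniHi <- max(vapply(ini, `[[`, numeric(1), "end"))
      opLo <- min(vapply(operons[[best]], `[[`, numeric(1), "start"))
      abs(opLo - iniHi)
    } else NA_real_
    records[[length(records) + 1L]] <- mkRecord(pair, "bifurcate", interDist)
  }
  for (o in which(!usedOperons)) {
    records[[length(records) + 1L]] <- mkRecord(operons[[o]], "contiguous",
                                                flags = "incomplete")
  }
  records
}

# |family_total - (initiator + operon modules)| minimised over families
.pairingScore <- function(ini, operon, kb) {
  total <- .clusterModuleCount(ini) + .clusterModuleCount(operon)
  min(vapply(kb@families, function(f) abs(f@peptideLength - total), numeric(1)))
}

# mean best identity between the A domains of two clusters (homology proxy
# for synteny-based pairing of split systems)
.clusterAseqs <- function(genes) {
  unlist(lapply(genes, function(g) {
    a <- g$domains[g$domains$kind == "A", , drop = FALSE]
    substring(g$protein, a$start + 1L, a$end)
  }))
}

.clusterHomology <- function(ini, operon) {
  qi <- .clusterAseqs(ini)
  qo <- .clusterAseqs(operon)
  if (!length(qi) || !length(qo)) return(0)
  mean(vapply(qi, function(q) max(identityToRefs(q, qo)), numeric(1)))
}

#' Mine a genome end-to-end
#'
#' Candidate detection, exclusion rules, organization resolution and
#' synteny in one call.
#'
#' @inheritParams findCandidates
#' @param kb knowledge base.
#' @return list with `bgcs` (list of retained [BgcRecord]), `excludedGenes`
#'   (candidates removed by exclusion rules, with flags).
#' @export
mineGenome <- function(genome, refs = domainReferenceLibrary(),
                       threshold = 0.5, kb = defaultKnowledgeBase()) {
  cand <- findCandidates(genome, refs, threshold)
  filt <- applyExclusions(cand)
  bgcs <- if (length(filt$retained))
    resolveOrganization(filt$retained, genome, kb) else list()
  keep <- vapply(bgcs, function(b)
    !length(b@exclusionFlags), logical(1))
  list(bgcs = bgcs[keep], partial = bgcs[!keep], excludedGenes = filt$excluded)
}

#' Export BGC records as a report table
#'
#' @param bgcs list of [BgcRecord].
#' @return data.frame, one row per record (documented columns including
#'   organization, inter-cluster distance and exclusion flags).
#' @export
bgcReportTable <- function(bgcs) {
  do.call(rbind, lapply(bgcs, function(b) {
    data.frame(
      genomeId = b@genomeId,
      systemId = b@system@id,
      nGenes = length(b@system@genes),
      nModules = nrow(b@system@modules),
      teTandem = b@system@teTandem,
      organization = b@organization,
      interClusterDistance = b@interClusterDistance,
      upstreamRegulator = b@synteny$upstreamRegulator,
      pleC = b@synteny$pleC,
      pleAB = b@synteny$pleAB,
      secondRegulator = b@synteny$secondRegulator,
      accessory = b@synteny$accessory,
      exclusionFlags = paste(b@exclusionFlags, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}
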