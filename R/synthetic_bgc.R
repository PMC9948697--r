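# Family-templated synthetic BGC and genome generators.

#' Synthetic BGC
#'
#' Seeded instantiation of one family template: NRPS genes carrying
#' concatenated synthetic domains, the planted truth (module architecture
#' and per-module specificity), flanking-gene roles and, for contiguous
#' operons, the sampled intergenic spacers.
#'
#' @slot family family name.
#' @slot organization `"contiguous"` or `"bifurcate"`.
#' @slot variant planted peptide variant name.
#' @slot genes list of gene entries (`name`, `protein`, `domains`
#'   data.frame, `moduleIndices`).
#' @slot spacers intergenic spacers (bp) between consecutive NRPS genes of
#'   a contiguous operon; empty for bifurcate.
#' @slot truth list: `modules` data.frame (`index`, `gene`, `cKind`,
#'   `specificity`), `flanks` character vector of planted flanking roles.
#' @export
setClass("SyntheticBgc",
  representation(family = "character", organization = "character",
                 variant = "character", genes = "list", spacers = "integer",
                 truth = "list"))

setMethod("show", "SyntheticBgc", function(object) {
  cat(sprintf("SyntheticBgc %s (%s, variant %s): genes [%s]\n",
              object@family, object@organization, object@variant,
              paste(vapply(object@genes, function(g)
                length(g$moduleIndices), integer(1)), collapse = "-")))
})

# C-domain kind for extension module i (module 1 is always Cs); most
# extension condensations are dual C/E, with a regular LCL interspersed
.extensionCKind <- function(i) if (i %% 4L == 0L) "LCL" else "CE"

# build one NRPS gene protein by concatenating synthetic domains; returns
# protein plus a 0-based half-open domain table
.buildNrpsGene <- function(moduleIdx, residues, isTerminal, config) {
  kinds <- domainKindAnchors(config)
  parts <- character()
  dom <- list()
  pos <- 0L
  addDomain <- function(kind, seqv, refId) {
    parts[[length(parts) + 1L]] <<- seqv
    dom[[length(dom) + 1L]] <<- data.frame(
      kind = kind, start = pos, end = pos + nchar(seqv),
      reference = refId, stringsAsFactors = FALSE)
    pos <<- pos + nchar(seqv)
  }
  mu <- config@mutationRate
  for (j in seq_along(moduleIdx)) {
    i <- moduleIdx[j]
    ck <- if (i == 1L) "Cs" else .extensionCKind(i)
    addDomain(ck, mutateProtein(kinds[[ck]], mu), ck)
    lin <- lineageSequence(attr(moduleIdx, "family"), i, residues[j],
                           config@domainLength[["A"]])
    addDomain("A", mutateProtein(lin, mu), residues[j])
    addDomain("T", mutateProtein(kinds$T, mu), "T")
  }
  if (isTerminal) {
    addDomain("TE", mutateProtein(kinds$TE, mu), "TE")
    addDomain("TE", mutateProtein(kinds$TE, mu), "TE")
  }
  list(protein = paste0(parts, collapse = ""), domains = do.call(rbind, dom))
}

#' Generate a synthetic BGC from a family template
#'
#' Genes carry concatenated synthetic domains in biosynthetic order
#' `Cs-A-T | (C-A-T)* | ...-TE-TE` following the family's module
#' configuration; a packaged peptide variant fixes the per-module A-domain
#' lineages. Intergenic spacers of contiguous operons are drawn uniformly
#' from the configured range.
#'
#' @param family family name (knowledge-base lookup, case-insensitive).
#' @param organization `"contiguous"` or `"bifurcate"`; must be allowed for
#'   the family.
#' @param config a [SimConfig].
#' @param variant variant name; default: first characterized variant.
#' @param configIndex which module configuration template to instantiate.
#' @param kb knowledge base.
#' @return a [SyntheticBgc].
#' @export
makeBgc <- function(family, organization = NULL, config = simConfig(),
                    variant = NULL, configIndex = 1L,
                    kb = defaultKnowledgeBase()) {
  fam <- lpFamily(family, kb)
  if (is.null(organization)) organization <- fam@organizations[1]
  if (!organization %in% fam@organizations) {
    stop(sprintf("organization '%s' not allowed for family %s (allowed: %s)",
                 organization, fam@name,
                 paste(fam@organizations, collapse = ", ")), call. = FALSE)
  }
  v <- fam@variants
  if (is.null(variant)) {
    i <- which(v$source == "characterized")[1]
  } else {
    i <- match(tolower(variant), tolower(v$name))
    if (is.na(i)) stop("unknown variant: ", variant, call. = FALSE)
  }
  residues <- v$sequence[[i]]
  cfg <- fam@moduleConfigs[[configIndex]]
  bounds <- c(0L, cumsum(cfg))
  withTagSeed(config@seed, paste("make-bgc", fam@name, organization, i,
                                 configIndex), {
    genes <- list()
    truthModules <- list()
    for (g in seq_along(cfg)) {
      idx <- (bounds[g] + 1L):bounds[g + 1L]
      attr(idx, "family") <- fam@name
      built <- .buildNrpsGene(idx, residues[idx],
                              isTerminal = (g == length(cfg)), config)
      gname <- sprintf("%s_nrps%d", tolower(fam@name), g)
      genes[[g]] <- list(name = gname, protein = built$protein,
                         domains = built$domains, moduleIndices = as.integer(idx))
      truthModules[[g]] <- data.frame(
        index = as.integer(idx), gene = gname,
        cKind = ifelse(idx == 1L, "Cs",
                       vapply(idx, .extensionCKind, character(1))),
        specificity = residues[idx], stringsAsFactors = FALSE)
    }
    spacers <- if (organization == "contiguous" && length(cfg) > 1L) {
      as.integer(sample(seq(config@spacerRange[1], config@spacerRange[2]),
                        length(cfg) - 1L, replace = TRUE))
    } else integer()
    flanks <- switch(fam@accessoryGenes,
      none = c("luxR", "pleC", "pleA", "pleB", "luxR2"),
      syrD_dab = c("luxR", "pleC", "syrD", "pleA", "pleB", "dab", "luxR2"),
      mfs = "mfs")
    new("SyntheticBgc", family = fam@name, organization = organization,
        variant = v$name[i], genes = genes, spacers = spacers,
        truth = list(modules = do.call(rbind, truthModules), flanks = flanks))
  })
}

#' Synthetic annotated genome
#'
#' @slot id genome identifier.
#' @slot records list of contig records (`id`, `length`, `features`
#'   data.frame with 0-based half-open `start`/`end`).
#' @slot truth machine-readable sidecar: planted clusters with genes,
#'   module specificities, flank roles, organization; planted decoys.
#' @export
setClass("LpGenome",
  representation(id = "character", records = "list", truth = "list"))

setMethod("show", "LpGenome", function(object) {
  cat(sprintf("LpGenome %s: %d record(s), %d planted cluster(s), %d decoy(s)\n",
              object@id, length(object@records),
              length(object@truth$clusters), length(object@truth$decoys)))
})

.flankProducts <- c(
  luxR = "LuxR-family transcriptional regulator",
  luxR2 = "LuxR-family transcriptional regulator",
  pleA = "PleA periplasmic adaptor protein",
  pleB = "PleB ATP-dependent transporter",
  pleC = "PleC outer membrane protein",
  syrD = "SyrD-like ABC transporter",
  dab = "2,4-diaminobutyrate aminotransferase",
  mfs = "major facilitator superfamily transporter")

# one decoy gene; kinds exercise the miner's exclusion rules
.buildDecoy <- function(kind, config, tagIdx) {
  kinds <- domainKindAnchors(config)
  anchors <- specificityAnchors(config@domainLength[["A"]])
  mu <- max(config@mutationRate, 0.2)
  a1 <- mutateProtein(anchors[[(tagIdx %% length(anchors)) + 1L]], mu)
  a2 <- mutateProtein(anchors[[((tagIdx + 3L) %% length(anchors)) + 1L]], mu)
  protein <- switch(kind,
    single_te = paste0(mutateProtein(kinds$Cs, mu), a1,
                       mutateProtein(kinds$T, mu),
                       mutateProtein(kinds$CE, mu), a2,
                       mutateProtein(kinds$T, mu),
                       mutateProtein(kinds$TE, mu)),
    standalone_e = paste0(mutateProtein(kinds$Cs, mu), a1,
                          mutateProtein(kinds$T, mu),
                          mutateProtein(kinds$E, mu),
                          mutateProtein(kinds$CE, mu), a2,
                          mutateProtein(kinds$T, mu),
                          mutateProtein(kinds$TE, mu),
                          mutateProtein(kinds$TE, mu)),
    fragment = paste0(mutateProtein(kinds$Cs, mu), a1,
                      mutateProtein(kinds$T, mu), "*",
                      mutateProtein(kinds$CE, mu), a2,
                      mutateProtein(kinds$T, mu),
                      mutateProtein(kinds$TE, mu),
                      mutateProtein(kinds$TE, mu)),
    plain = randomProtein(sample(300:600, 1L)))
  list(kind = kind, protein = protein)
}

# append one CDS feature row; start0 is 0-based, gene length from protein
.featureRow <- function(locusTag, start0, protein, strand, role, product) {
  data.frame(locusTag = locusTag, type = "CDS", start = start0,
             end = start0 + nchar(protein) * 3L + 3L, strand = strand,
             role = role, product = product, translation = protein,
             stringsAsFactors = FALSE)
}

#' Generate an annotated synthetic genome
#'
#' Plants the requested BGCs with their flanking synteny (upstream
#' antisense LuxR regulator and PleC, downstream PleAB and a second
#' regulator; SyrD/Dab for Tolaasin; a lone MFS gene for Thanafactin) plus
#' decoy genes, on one main record; bifurcate clusters put the initiator
#' gene (with its upstream flank) on a separate record.
#'
#' @param bgcSpecs list of `list(family=, organization=, variant=,
#'   configIndex=)` entries (`family` alone suffices).
#' @param config a [SimConfig].
#' @param genomeId identifier used in record names and file output.
#' @param decoyKinds decoy repertoire cycled over `decoyGeneCount`
#'   (subset of `"single_te"`, `"standalone_e"`, `"fragment"`, `"plain"`).
#' @param kb knowledge base.
#' @return an [LpGenome] with a machine-readable `truth` sidecar.
#' @export
makeGenome <- function(bgcSpecs, config = simConfig(), genomeId = "synthetic1",
                       decoyKinds = c("single_te", "standalone_e", "plain"),
                       kb = defaultKnowledgeBase()) {
  bgcs <- lapply(bgcSpecs, function(s) {
    makeBgc(s$family, s$organization, config,
            variant = s$variant,
            configIndex = if (is.null(s$configIndex)) 1L else s$configIndex,
            kb = kb)
  })
  withTagSeed(config@seed, paste("make-genome", genomeId), {
    mainFeatures <- list()
    records <- list()
    truthClusters <- list()
    truthDecoys <- list()
    cursor <- 1000L
    emit <- function(row) {
      mainFeatures[[length(mainFeatures) + 1L]] <<- row
      cursor <<- row$end + 0L
    }
    gap <- function(lo, hi) cursor <<- cursor + sample(lo:hi, 1L)
    flankGene <- function(role, tag, strand = "+") {
      prot <- randomProtein(250L)
      .featureRow(tag, cursor, prot, strand, sub("2$", "", role),
                  .flankProducts[[role]])
    }
    for (b in seq_along(bgcs)) {
      bgc <- bgcs[[b]]
      pfx <- sprintf("%s_b%d", genomeId, b)
      geneTags <- character(length(bgc@genes))
      upstreamRoles <- intersect(c("luxR", "pleC", "syrD"), bgc@truth$flanks)
      downstreamRoles <- intersect(c("pleA", "pleB", "dab", "luxR2", "mfs"),
                                   bgc@truth$flanks)
      placeUpstream <- function() {
        for (r in upstreamRoles) {
          emit(flankGene(r, sprintf("%s_%s", pfx, r),
                         strand = if (r == "luxR") "-" else "+"))
          gap(100L, 400L)
        }
      }
      placeOperon <- function(geneIdx, spacers) {
        for (k in seq_along(geneIdx)) {
          g <- bgc@genes[[geneIdx[k]]]
          tag <- sprintf("%s_%s", pfx, g$name)
          geneTags[geneIdx[k]] <<- tag
          emit(.featureRow(tag, cursor, g$protein, "+", "nrps",
                           sprintf("%s-family NRPS", bgc@family)))
          if (k < length(geneIdx)) cursor <<- cursor + spacers[k]
        }
      }
      placeDownstream <- function() {
        gap(100L, 400L)
        for (r in downstreamRoles) {
          emit(flankGene(r, sprintf("%s_%s", pfx, r)))
          gap(100L, 400L)
        }
      }
      if (bgc@organization == "contiguous") {
        placeUpstream()
        placeOperon(seq_along(bgc@genes), bgc@spacers)
        placeDownstream()
      } else {
        # operon (genes 2..n) on the main record with its downstream flank
        operonSpacers <- as.integer(sample(
          seq(config@spacerRange[1], config@spacerRange[2]),
          max(length(bgc@genes) - 2L, 0L), replace = TRUE))
        placeOperon(seq_along(bgc@genes)[-1L], operonSpacers)
        placeDownstream()
        # initiator + upstream flank on a separate record
        ctgFeatures <- list()
        ctgCursor <- 500L
        for (r in upstreamRoles) {
          prot <- randomProtein(250L)
          row <- .featureRow(sprintf("%s_%s", pfx, r), ctgCursor, prot,
                             if (r == "luxR") "-" else "+",
                             sub("2$", "", r), .flankProducts[[r]])
          ctgFeatures[[length(ctgFeatures) + 1L]] <- row
          ctgCursor <- row$end + sample(100:400, 1L)
        }
        g <- bgc@genes[[1L]]
        tag <- sprintf("%s_%s", pfx, g$name)
        geneTags[1L] <- tag
        row <- .featureRow(tag, ctgCursor, g$protein, "+", "nrps",
                           sprintf("%s-family NRPS initiator", bgc@family))
        ctgFeatures[[length(ctgFeatures) + 1L]] <- row
        records[[length(records) + 1L]] <- list(
          id = sprintf("%s_ctg%d", genomeId, length(records) + 2L),
          length = row$end + 500L,
          features = do.call(rbind, ctgFeatures))
      }
      gap(2000L, 5000L)
      truthClusters[[b]] <- list(
        family = bgc@family, organization = bgc@organization,
        variant = bgc@variant, genes = geneTags,
        spacers = bgc@spacers,
        modules = data.frame(bgc@truth$modules,
                             locusTag = geneTags[match(bgc@truth$modules$gene,
                               vapply(bgc@genes, `[[`, character(1), "name"))],
                             stringsAsFactors = FALSE),
        flanks = bgc@truth$flanks)
    }
    for (d in seq_len(config@decoyGeneCount)) {
      kind <- decoyKinds[((d - 1L) %% length(decoyKinds)) + 1L]
      dec <- .buildDecoy(kind, config, d)
      tag <- sprintf("%s_decoy%d", genomeId, d)
      emit(.featureRow(tag, cursor, dec$protein, "+", "decoy",
                       "hypothetical protein"))
      gap(500L, 2000L)
      truthDecoys[[d]] <- list(locusTag = tag, kind = kind)
    }
    main <- list(id = paste0(genomeId, "_ctg1"), length = cursor + 500L,
                 features = if (length(mainFeatures))
                   do.call(rbind, mainFeatures)
                 else .emptyFeatures())
    records <- c(list(main), records)
    for (rec in records) {
      f <- rec$features
      if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
        stop("layout error: overlapping planted features on ", rec$id,
             call. = FALSE)
    }
    new("LpGenome", id = genomeId, records = records,
        truth = list(clusters = truthClusters, decoys = truthDecoys))
  })
}

.emptyFeatures <- function() {
  data.frame(locusTag = character(), type = character(), start = integer(),
             end = integer(), strand = character(), role = character(),
             product = character(), translation = character(),
             stringsAsFactors = FALSE)
}
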