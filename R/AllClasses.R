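#' @import methods
NULL

#' Lipopeptide family definition
#'
#' One chemical lipopeptide (LP) family: its `[l:m]` signature (peptide
#' length `l` and macrocycle size `m`, with `m = 0` for the linear
#' families), the per-gene module-count templates of its NRPS systems, the
#' genomic organizations it occurs in, its peptide variants and accessory
#' flanking-gene template.
#'
#' @slot name family identifier (capitalised, e.g. `"Viscosin"`).
#' @slot peptideLength residue count `l`.
#' @slot macrocycleSize residue count `m` of the lactone ring; 0 for linear.
#' @slot moduleConfigs list of integer vectors, one per known per-gene
#'   module distribution (each sums to `peptideLength`).
#' @slot organizations subset of `"contiguous"`, `"bifurcate"`.
#' @slot variants data.frame of peptide variants: `name`, `sequence`
#'   (list column of residue vectors), `leu5Stereo`, `source`, `provenance`.
#' @slot taxonGroups producer (sub)group labels.
#' @slot accessoryGenes synteny template: `"none"`, `"syrD_dab"` or `"mfs"`.
#' @slot superfamily superfamily number (1-4) or `NA`.
#' @export
setClass("LpFamily",
  representation(
    name = "character",
    peptideLength = "integer",
    macrocycleSize = "integer",
    moduleConfigs = "list",
    organizations = "character",
    variants = "data.frame",
    taxonGroups = "character",
    accessoryGenes = "character",
    superfamily = "integer"
  )
)

setValidity("LpFamily", function(object) {
  msg <- character()
  for (cfg in object@moduleConfigs) {
    if (sum(cfg) != object@peptideLength) {
      msg <- c(msg, sprintf("module config [%s] does not sum to peptide length %d",
                            paste(cfg, collapse = ","), object@peptideLength))
    }
  }
  if (object@macrocycleSize > object@peptideLength) {
    msg <- c(msg, "macrocycle size exceeds peptide length")
  }
  if (!all(object@organizations %in% c("contiguous", "bifurcate"))) {
    msg <- c(msg, "unknown organization mode")
  }
  if (nrow(object@variants)) {
    len <- vapply(object@variants$sequence, length, integer(1))
    if (any(len != object@peptideLength)) {
      msg <- c(msg, sprintf("variant(s) %s have wrong length",
                            paste(object@variants$name[len != object@peptideLength],
                                  collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Packaged lipopeptide knowledge base
#'
#' Versioned container of all [LpFamily] definitions plus the residue
#' alphabet and the table of predicted LPs whose lengths match no family
#' template.
#'
#' @slot families list of [LpFamily] objects, stable order.
#' @slot alphabet LP residue alphabet.
#' @slot predicted data.frame of predicted LPs (`name`, `derivedFrom`,
#'   `mechanism`, `sequence` list column).
#' @slot version schema version string.
#' @export
setClass("LpKnowledgeBase",
  representation(
    families = "list",
    alphabet = "character",
    predicted = "data.frame",
    version = "character"
  )
)

setValidity("LpKnowledgeBase", function(object) {
  nm <- vapply(object@families, function(f) f@name, character(1))
  if (anyDuplicated(nm)) {
    return(sprintf("duplicated family name(s): %s",
                   paste(nm[duplicated(nm)], collapse = ", ")))
  }
  for (f in object@families) {
    res <- unique(unlist(f@variants$sequence))
    bad <- setdiff(res, object@alphabet)
    if (length(bad)) {
      return(sprintf("family %s uses residues outside the alphabet: %s",
                     f@name, paste(bad, collapse = ", ")))
    }
  }
  TRUE
})

#' Synthetic-data generator configuration
#'
#' Parameters shared by all seeded generators. Defaults encode the study
#' conditions: 150-300 bp intergenic spacers within contiguous operons,
#' domain lengths typical of NRPS condensation (440 aa), adenylation
#' (450 aa), thiolation (80 aa) and thioesterase (230 aa) domains.
#'
#' @slot seed integer master seed; every generator derives a private stream
#'   from `(seed, call tag)`.
#' @slot nRefsPerSpecificity diverged reference copies per substrate.
#' @slot domainLength named integer vector of per-kind domain lengths.
#' @slot mutationRate per-site substitution probability in `[0, 1]`.
#' @slot spacerRange intergenic spacer bounds in bp.
#' @slot decoyGeneCount decoy genes planted per genome.
#' @slot peakJitter HSQC jitter standard deviations `(ppm 1H, ppm 13C)`.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nRefsPerSpecificity = "integer",
    domainLength = "integer",
    mutationRate = "numeric",
    spacerRange = "integer",
    decoyGeneCount = "integer",
    peakJitter = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0, 1]")
  if (length(object@spacerRange) != 2 || any(object@spacerRange < 1) ||
      any(object@spacerRange > 1e5) ||
      object@spacerRange[1] > object@spacerRange[2])
    msg <- c(msg, "spacerRange must be increasing bounds inside [1, 1e5]")
  if (!all(c("A", "C", "T", "TE", "E") %in% names(object@domainLength)))
    msg <- c(msg, "domainLength must name A, C, T, TE and E lengths")
  if (length(msg)) msg else TRUE
})

#' Parsed NRPS system
#'
#' Ordered modules of a (possibly multi-gene) lipopeptide synthetase,
#' concatenated in biosynthetic order: the starter-condensation (Cs) gene
#' first, the tandem-thioesterase gene last.
#'
#' @slot id system identifier.
#' @slot genes gene ids in biosynthetic order.
#' @slot modules data.frame, one row per module: `index`, `gene`, `cKind`
#'   (`Cs`, `LCL`, `CE` or `none`), `aSequence`, `hasT`.
#' @slot teTandem `TRUE` when the terminal gene ends in a TE-TE tandem
#'   (diagnostic for lipopeptide systems).
#' @slot concatenate joined protein sequence in biosynthetic order.
#' @export
setClass("NrpsSystem",
  representation(
    id = "character",
    genes = "character",
    modules = "data.frame",
    teTandem = "logical",
    concatenate = "character"
  )
)

setValidity("NrpsSystem", function(object) {
  if (nrow(object@modules) &&
      !identical(object@modules$index, seq_len(nrow(object@modules)))) {
    return("module indices must be 1..n in order")
  }
  TRUE
})

#' Mined lipopeptide BGC record
#'
#' One detected biosynthetic gene cluster: its parsed NRPS system, genomic
#' organization, flanking-gene synteny evidence and any exclusion flags.
#'
#' @slot genomeId source genome identifier.
#' @slot system the assembled [NrpsSystem].
#' @slot organization `"contiguous"` or `"bifurcate"`.
#' @slot interClusterDistance bp between the initiator cluster and the
#'   operon when both lie on one record; `NA` otherwise.
#' @slot spacers recorded intergenic spacers (bp) within the operon.
#' @slot synteny list with elements `upstreamRegulator`
#'   (`present_antisense` / `present_sense` / `absent`), `pleC`, `pleAB`,
#'   `secondRegulator`, `accessory`.
#' @slot exclusionFlags character vector of exclusion-rule hits (empty for
#'   retained clusters).
#' @export
setClass("BgcRecord",
  representation(
    genomeId = "character",
    system = "NrpsSystem",
    organization = "character",
    interClusterDistance = "numeric",
    spacers = "numeric",
    synteny = "list",
    exclusionFlags = "character"
  )
)

setMethod("show", "LpFamily", function(object) {
  cat(sprintf("LpFamily %s [%d:%d], %d variant(s), configs: %s; %s\n",
              object@name, object@peptideLength, object@macrocycleSize,
              nrow(object@variants),
              paste(vapply(object@moduleConfigs,
                           function(x) paste0("[", paste(x, collapse = "-"), "]"),
                           character(1)), collapse = " "),
              paste(object@organizations, collapse = "/")))
})

setMethod("show", "LpKnowledgeBase", function(object) {
  cat(sprintf("LpKnowledgeBase v%s: %d families, %d predicted LPs\n",
              object@version, length(object@families), nrow(object@predicted)))
  for (f in object@families) show(f)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig(seed=%d, mutationRate=%.3f, spacers=[%d,%d] bp, %d decoys)\n",
    object@seed, object@mutationRate, object@spacerRange[1],
    object@spacerRange[2], object@decoyGeneCount))
})

setMethod("show", "NrpsSystem", function(object) {
  cat(sprintf("NrpsSystem %s: %d gene(s), %d modules, TE tandem: %s\n",
              object@id, length(object@genes), nrow(object@modules),
              object@teTandem))
})

setMethod("show", "BgcRecord", function(object) {
  cat(sprintf("BgcRecord (%s): %s, %d modules%s%s\n",
              object@genomeId, object@organization, nrow(object@system@modules),
              if (length(object@exclusionFlags))
                paste0(", excluded: ", paste(object@exclusionFlags, collapse = ","))
              else "",
              if (!is.na(object@interClusterDistance))
                sprintf(", inter-cluster %d bp", as.integer(object@interClusterDistance))
              else ""))
})
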