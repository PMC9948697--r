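# Genome record I/O: minimal GenBank flat-file writer/reader (no installed R
# package parses/writes GenBank flat files offline), GFF3 via rtracklayer,
# protein FASTA via Biostrings, truth sidecar as JSON. Internal coordinates
# are 0-based half-open; GenBank output is 1-based inclusive.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

.wrapQualifier <- function(text, width = 58L) {
  starts <- seq(1L, nchar(text), by = width)
  substring(text, starts, pmin(starts + width - 1L, nchar(text)))
}

#' Write an [LpGenome] as a GenBank flat file
#'
#' One LOCUS per record; CDS features carry `/locus_tag`, `/product`,
#' `/note="role:<role>"` and `/translation` qualifiers. No ORIGIN sequence
#' block is emitted (nucleotide sequences of the synthetic genomes are
#' placeholders by design).
#'
#' @param genome an [LpGenome].
#' @param path output file.
#' @export
writeGenbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in genome@records) {
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                       rec$id, rec$length), con)
    writeLines(sprintf("DEFINITION  synthetic Pseudomonas-like record %s.",
                       rec$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rec$length), con)
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$locusTag[i]), con)
      writeLines(sprintf("                     /product=\"%s\"", f$product[i]), con)
      writeLines(sprintf("                     /note=\"role:%s\"", f$role[i]), con)
      tr <- .wrapQualifier(f$translation[i])
      tr[length(tr)] <- paste0(tr[length(tr)], "\"")
      writeLines(sprintf("                     /translation=\"%s", tr[1]), con)
      if (length(tr) > 1L)
        writeLines(sprintf("                     %s", tr[-1]), con)
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a GenBank flat file written in this dialect
#'
#' Parses LOCUS records and CDS features with `locus_tag`, `product`,
#' `note` and `translation` qualifiers back into an [LpGenome] (without
#' truth sidecar). Coordinates convert back to 0-based half-open.
#'
#' @param path GenBank flat file.
#' @param genomeId identifier for the reconstructed genome.
#' @return an [LpGenome].
#' @export
readGenbank <- function(path, genomeId = NULL) {
  lines <- readLines(path)
  records <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "LOCUS")) { i <- i + 1L; next }
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    recId <- toks[2]
    recLen <- as.integer(toks[3])
    i <- i + 1L
    feats <- list()
    while (i <= length(lines) && !startsWith(lines[i], "//")) {
      ln <- lines[i]
      if (grepl("^     CDS             ", ln)) {
        loc <- trimws(sub("^     CDS", "", ln))
        strand <- if (grepl("complement", loc)) "-" else "+"
        nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
        qual <- list()
        i <- i + 1L
        while (i <= length(lines) && grepl("^                     ", lines[i])) {
          q <- trimws(lines[i])
          if (startsWith(q, "/")) {
            kv <- sub("^/([a-z_]+)=\"(.*)$", "\\1\x01\\2", q)
            kv <- strsplit(kv, "\x01")[[1]]
            key <- kv[1]
            val <- if (length(kv) > 1) kv[2] else ""
            # continuation lines until closing quote
            while (!grepl("\"$", val) && i + 1L <= length(lines) &&
                   grepl("^                     [^/]", lines[i + 1L])) {
              i <- i + 1L
              val <- paste0(val, trimws(lines[i]))
            }
            qual[[key]] <- sub("\"$", "", val)
          }
          i <- i + 1L
        }
        feats[[length(feats) + 1L]] <- data.frame(
          locusTag = qual$locus_tag %||% NA_character_,
          type = "CDS", start = nums[1] - 1L, end = nums[2], strand = strand,
          role = sub("^role:", "", qual$note %||% ""),
          product = qual$product %||% "",
          translation = qual$translation %||% "",
          stringsAsFactors = FALSE)
      } else {
        i <- i + 1L
      }
    }
    records[[length(records) + 1L]] <- list(
      id = recId, length = recLen,
      features = if (length(feats)) do.call(rbind, feats) else .emptyFeatures())
    i <- i + 1L
  }
  if (!length(records)) stop("I/O error: no LOCUS records in ", path, call. = FALSE)
  if (is.null(genomeId)) genomeId <- sub("_ctg\\d+$", "", records[[1]]$id)
  new("LpGenome", id = genomeId, records = records, truth = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genome annotation as GFF3
#' @param genome an [LpGenome].
#' @param path output file.
#' @export
writeGff3 <- function(genome, path) {
  grl <- lapply(genome@records, function(rec) {
    f <- rec$features
    if (!nrow(f)) return(NULL)
    gr <- GRanges(seqnames = rec$id,
                  ranges = IRanges(start = f$start + 1L, end = f$end),
                  strand = f$strand)
    mcols(gr)$type <- "CDS"
    mcols(gr)$ID <- f$locusTag
    mcols(gr)$product <- f$product
    mcols(gr)$role <- f$role
    gr
  })
  gr <- do.call(c, Filter(Negate(is.null), grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome from GFF3 annotation plus a protein FASTA
#'
#' Adapter for the FASTA+GFF3 input route: CDS features are matched to
#' protein translations by `ID`/FASTA name.
#'
#' @param gffPath GFF3 file.
#' @param fastaPath protein FASTA whose names are the feature IDs.
#' @param genomeId genome identifier.
#' @return an [LpGenome].
#' @export
readGff3Genome <- function(gffPath, fastaPath, genomeId = "genome") {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  prot <- Biostrings::readAAStringSet(fastaPath)
  recIds <- as.character(unique(GenomicRanges::seqnames(gr)))
  records <- lapply(recIds, function(rid) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == rid]
    ids <- as.character(mcols(sub)$ID)
    feats <- data.frame(
      locusTag = ids, type = "CDS",
      start = GenomicRanges::start(sub) - 1L, end = GenomicRanges::end(sub),
      strand = as.character(GenomicRanges::strand(sub)),
      role = if (!is.null(mcols(sub)$role)) as.character(mcols(sub)$role) else "",
      product = if (!is.null(mcols(sub)$product))
        as.character(mcols(sub)$product) else "",
      translation = as.character(prot[ids]),
      stringsAsFactors = FALSE)
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
    list(id = rid, length = max(feats$end) + 500L, features = feats)
  })
  new("LpGenome", id = genomeId, records = records, truth = list())
}

#' Write protein FASTA of all annotated CDS
#' @param genome an [LpGenome].
#' @param path output file.
#' @export
writeProteinFasta <- function(genome, path) {
  f <- do.call(rbind, lapply(genome@records, `[[`, "features"))
  seqs <- Biostrings::AAStringSet(f$translation)
  names(seqs) <- f$locusTag
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the machine-readable truth sidecar
#' @param genome an [LpGenome].
#' @param path output JSON file.
#' @export
writeTruthJson <- function(genome, path) {
  jsonlite::write_json(genome@truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write the full synthetic-genome file set
#'
#' Emits `<id>.gbk`, `<id>.gff3`, `<id>.faa` and `<id>.truth.json` into a
#' directory.
#'
#' @param genome an [LpGenome].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
writeGenomeFiles <- function(genome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genbank = file.path(dir, paste0(genome@id, ".gbk")),
    gff3 = file.path(dir, paste0(genome@id, ".gff3")),
    fasta = file.path(dir, paste0(genome@id, ".faa")),
    truth = file.path(dir, paste0(genome@id, ".truth.json")))
  writeGenbank(genome, paths["genbank"])
  writeGff3(genome, paths["gff3"])
  writeProteinFasta(genome, paths["fasta"])
  writeTruthJson(genome, paths["truth"])
  paths
}
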