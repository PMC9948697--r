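# internal helpers: tagged RNG streams and residue/sequence utilities

# fixed seed anchoring the packaged reference universe (domain anchors,
# A-domain lineages, spectral library); independent of user SimConfig seeds
.LIBRARY_SEED <- 104729L

# 20 proteinogenic letters used for synthetic protein sequences
.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' @importFrom withr with_seed
NULL

# deterministic 31-bit seed from (seed, tag); polynomial rolling hash so that
# adding new generator tags never shifts existing streams
tagSeed <- function(seed, tag) {
  h <- as.numeric(seed %% 2147483647L)
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# run expr under a private RNG stream keyed by (seed, tag)
withTagSeed <- function(seed, tag, expr) {
  withr::with_seed(tagSeed(seed, tag), expr)
}

randomProtein <- function(length) {
  paste0(sample(.AA20, length, replace = TRUE), collapse = "")
}

# substitute each site independently with probability `rate`, drawing the
# replacement uniformly from the 19 other letters
mutateProtein <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  paste0(chars, collapse = "")
}

# fraction of identical sites between equal-length strings (used as the fast
# prefilter before alignment-based identity)
hammingIdentity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

assertAminoAcid <- function(x, what = "sequence") {
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVX*]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains non-amino-acid characters: %s",
                 what, paste(substr(x[bad], 1, 20), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
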