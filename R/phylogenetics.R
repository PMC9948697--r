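# Distance matrices, neighbor-joining with site-resampling bootstrap, and
# tree-vs-tree congruence (NRPS concatenate vs rpoD scale).

#' Identity-based distance matrix
#'
#' `d = 1 - fractional identity`, either from pairwise global alignment of
#' the supplied sequences or from a user identity function.
#'
#' @param sequences named character vector (>= 3 taxa, unique labels).
#' @param identityFn identity function of two sequences; default
#'   [adomainIdentity()]. Pass an identity function over aligned rows to
#'   reuse externally computed alignments.
#' @return symmetric `dist`-convertible matrix with zero diagonal, taxon
#'   labels as dimnames.
#' @export
distanceMatrix <- function(sequences, identityFn = adomainIdentity) {
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("sequences must be named with taxon labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("input error: duplicate taxon labels", call. = FALSE)
  if (length(sequences) < 3L) stop("need >= 3 taxa", call. = FALSE)
  n <- length(sequences)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 1 - identityFn(sequences[[i]], sequences[[j]])
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Neighbor-joining tree
#'
#' Standard NJ (ape); negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param dm symmetric distance matrix with labels (or `dist`).
#' @return ape `phylo` (unrooted).
#' @export
njTree <- function(dm) {
  m <- as.matrix(dm)
  if (any(!is.finite(m))) stop("input error: non-finite distances",
                               call. = FALSE)
  tree <- ape::nj(m)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Site-resampling bootstrap over NJ
#'
#' Columns of the alignment are resampled with replacement, an NJ tree is
#' rebuilt per replicate, and per-split support is the fraction of
#' replicate trees containing the split.
#'
#' @param aligned named character vector of EQUAL-length (aligned)
#'   sequences.
#' @param nReps bootstrap replicates (>= 1).
#' @param seed RNG seed (reproducible).
#' @return list: `tree` (NJ tree on the full alignment, with
#'   `node.label` holding support fractions) and `supports` (numeric per
#'   internal node).
#' @export
bootstrapSupport <- function(aligned, nReps = 100L, seed = 1L) {
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop("bootstrap requires aligned (equal-length) sequences", call. = FALSE)
  chars <- do.call(rbind, strsplit(aligned, ""))
  rownames(chars) <- names(aligned)
  distOf <- function(mat) {
    n <- nrow(mat)
    m <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- mean(mat[i, ] != mat[j, ])
      m[i, j] <- m[j, i] <- d
    }
    m
  }
  tree <- njTree(distOf(chars))
  boots <- withTagSeed(seed, "bootstrap-support", {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      njTree(distOf(chars[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- counts / nReps
  tree$node.label <- format(supports, trim = TRUE)
  list(tree = tree, supports = supports)
}

#' Congruence between two trees
#'
#' Restricted to the shared leaf set (with a warning when pruning).
#' Reports the Robinson-Foulds distance normalised by `2n - 6`, the
#' correlation of cophenetic (path-length) distances, and leaves ranked by
#' how much their greedy removal improves the RF distance (candidate
#' horizontally transferred systems).
#'
#' @param t1,t2 ape `phylo` trees.
#' @param maxDiscordant maximum leaves reported (default 5).
#' @return list: `normalizedRf` in `[0,1]`, `copheneticCorrelation`,
#'   `discordantLeaves` (data.frame `leaf`, `improvement`).
#' @export
congruence <- function(t1, t2, maxDiscordant = 5L) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("congruence undefined: fewer than 4 shared leaves", call. = FALSE)
  if (length(shared) < length(t1$tip.label) ||
      length(shared) < length(t2$tip.label)) {
    warning("pruning trees to the shared leaf set", call. = FALSE)
  }
  t1 <- ape::keep.tip(t1, shared)
  t2 <- ape::keep.tip(t2, shared)
  nrf <- function(a, b) {
    n <- length(a$tip.label)
    if (n < 4L) return(0)
    as.numeric(phangorn::RF.dist(a, b)) / (2 * n - 6)
  }
  rf <- nrf(t1, t2)
  c1 <- ape::cophenetic.phylo(t1)[shared, shared]
  c2 <- ape::cophenetic.phylo(t2)[shared, shared]
  cc <- stats::cor(c1[lower.tri(c1)], c2[lower.tri(c2)])
  # greedy leaf removal: which leaves explain the discordance
  discordant <- data.frame(leaf = character(), improvement = numeric(),
                           stringsAsFactors = FALSE)
  cur1 <- t1; cur2 <- t2; curRf <- rf
  for (k in seq_len(min(maxDiscordant, length(shared) - 4L))) {
    if (curRf <= 0) break
    tips <- cur1$tip.label
    gain <- vapply(tips, function(tp) {
      a <- ape::drop.tip(cur1, tp)
      b <- ape::drop.tip(cur2, tp)
      curRf - nrf(a, b)
    }, numeric(1))
    best <- names(gain)[order(-gain, names(gain))][1]
    if (gain[best] <= 0) break
    discordant <- rbind(discordant,
                        data.frame(leaf = best, improvement = gain[best],
                                   stringsAsFactors = FALSE))
    cur1 <- ape::drop.tip(cur1, best)
    cur2 <- ape::drop.tip(cur2, best)
    curRf <- curRf - gain[best]
  }
  rownames(discordant) <- NULL
  list(normalizedRf = rf, copheneticCorrelation = cc,
       discordantLeaves = discordant)
}

#' Read/write trees as newick
#'
#' Thin wrappers over ape for the package's external tree interface
#' (supports quoted labels; bootstrap values as internal node labels).
#'
#' @param tree ape `phylo`.
#' @param path newick file.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Read a distance matrix from TSV (square, labelled) or PHYLIP square
#' @param path file path.
#' @return labelled matrix.
#' @export
readDistanceTsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*\\d+\\s*$", first)) {
    # PHYLIP square dialect: first line = n, then label + n values per row
    body <- utils::read.table(path, skip = 1L, header = FALSE,
                              stringsAsFactors = FALSE)
    m <- as.matrix(body[, -1, drop = FALSE])
    dimnames(m) <- list(body[[1]], body[[1]])
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
  }
  storage.mode(m) <- "numeric"
  m
}
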