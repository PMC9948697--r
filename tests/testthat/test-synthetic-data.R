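test_that("reference sets are seeded, anchored and divergence-bounded", {
  cfg0 <- simConfig(seed = 3, mutationRate = 0, nRefsPerSpecificity = 2)
  refs0 <- makeReferenceSet(cfg0)
  expect_equal(nrow(refs0), 2L * 14L)
  # zero mutation: every copy equals its specificity anchor
  anchors <- lipomine:::specificityAnchors(450L)
  for (res in unique(refs0$specificity)) {
    expect_true(all(refs0$sequence[refs0$specificity == res] == anchors[[res]]))
  }
  # determinism: same config twice gives identical sequence sets
  expect_identical(makeReferenceSet(cfg0), refs0)
  expect_identical(makeReferenceSet(simConfig(seed = 3, mutationRate = 0.1)),
                   makeReferenceSet(simConfig(seed = 3, mutationRate = 0.1)))
  # anchors for different specificities are mutually < 40% identical
  am <- unlist(anchors)
  for (i in seq_along(am)[-1]) for (j in seq_len(i - 1)) {
    expect_lt(lipomine:::hammingIdentity(am[i], am[j]), 0.4)
  }
})

test_that("within-group identity matches a per-site substitution oracle", {
  mu <- 0.1
  refs <- makeReferenceSet(simConfig(seed = 5, mutationRate = mu,
                                     nRefsPerSpecificity = 4))
  ident <- unlist(lapply(split(refs$sequence, refs$specificity), function(s) {
    utils::combn(length(s), 2, function(ij)
      lipomine:::hammingIdentity(s[[ij[1]]], s[[ij[2]]]))
  }))
  # oracle: direct per-site Bernoulli simulation of two independent
  # mutation processes over n = 10,000 sites
  set.seed(42)
  n <- 10000L
  orig <- sample(lipomine:::.AA20, n, replace = TRUE)
  mutate <- function(x) {
    hit <- which(runif(n) < mu)
    x[hit] <- vapply(x[hit], function(ch)
      sample(setdiff(lipomine:::.AA20, ch), 1L), character(1))
    x
  }
  oracle <- mean(mutate(orig) == mutate(orig))
  expect_lt(abs(mean(ident) - oracle), 0.02)
})

test_that("BGC generation follows the family template and spacer bounds", {
  cfg <- simConfig(seed = 2, mutationRate = 0)
  bgc <- makeBgc("Viscosin", "contiguous", cfg)
  expect_length(bgc@genes, 3L)
  expect_equal(vapply(bgc@genes, function(g) length(g$moduleIndices),
                      integer(1)), c(2L, 4L, 3L))
  # terminal gene ends with the tandem TE
  lastDomains <- utils::tail(bgc@genes[[3]]$domains$kind, 2)
  expect_equal(lastDomains, c("TE", "TE"))
  # planted variant is the family's first characterized peptide
  expect_equal(bgc@truth$modules$specificity,
               familyVariants("Viscosin")$sequence[[1]])
  # spacers always within the configured range
  sp <- unlist(lapply(1:50, function(s)
    makeBgc("Viscosin", "contiguous", simConfig(seed = s))@spacers))
  expect_true(all(sp >= 150 & sp <= 300))
  expect_error(makeBgc("Amphisin", "bifurcate", cfg), "not allowed")
})

test_that("genomes are deterministic and carry a complete truth sidecar", {
  cfg <- simConfig(seed = 9, mutationRate = 0.05)
  g1 <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                   cfg, "det")
  g2 <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                   cfg, "det")
  f1 <- tempfile(); f2 <- tempfile()
  writeGenbank(g1, f1); writeGenbank(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  tr <- g1@truth$clusters[[1]]
  expect_equal(nrow(tr$modules), 9L)
  expect_true(all(c("index", "gene", "cKind", "specificity", "locusTag") %in%
                    names(tr$modules)))
  expect_true(all(nzchar(tr$modules$locusTag)))
})

test_that("GenBank round-trip reproduces coordinates and translations", {
  cfg <- simConfig(seed = 4, mutationRate = 0.02)
  g <- makeGenome(list(list(family = "Entolysin", organization = "bifurcate")),
                  cfg, "rt")
  path <- tempfile(fileext = ".gbk")
  writeGenbank(g, path)
  back <- readGenbank(path)
  expect_length(back@records, length(g@records))
  for (k in seq_along(g@records)) {
    a <- g@records[[k]]$features
    b <- back@records[[k]]$features
    expect_equal(b$start, a$start)
    expect_equal(b$end, a$end)
    expect_equal(b$strand, a$strand)
    expect_equal(b$translation, a$translation)
    expect_equal(b$locusTag, a$locusTag)
  }
})

test_that("dual-producer genomes plant two clusters; empty genomes none", {
  cfg <- simConfig(seed = 6, mutationRate = 0.05, decoyGeneCount = 5)
  dual <- makeGenome(list(list(family = "Tolaasin", organization = "contiguous"),
                          list(family = "Viscosin", organization = "contiguous")),
                     cfg, "dual")
  expect_length(dual@truth$clusters, 2L)
  empty <- makeGenome(list(), cfg, "none", decoyKinds = "plain")
  expect_length(empty@truth$clusters, 0L)
  expect_length(empty@truth$decoys, 5L)
})

test_that("HSQC generation is one peak per residue with seeded jitter", {
  ref <- referenceFingerprint("viscosin")
  expect_equal(nrow(ref), 9L)
  expect_true(all(ref$h_ppm >= 3.5 & ref$h_ppm <= 5.5))
  expect_true(all(ref$c_ppm >= 48 & ref$c_ppm <= 65))
  noJitter <- makeHsqc("viscosin", simConfig(seed = 1, peakJitter = c(0, 0)))
  expect_equal(noJitter, ref)
  expect_error(makeHsqc("not-a-compound"), "unknown variant")
  expect_identical(makeHsqc("viscosin", simConfig(seed = 8)),
                   makeHsqc("viscosin", simConfig(seed = 8)))
})

test_that("jittered peaks match their reference at the oracle rate", {
  jit <- c(0.01, 0.1)
  tol <- c(0.03, 0.4)
  # oracle: Monte-Carlo of the tolerance-ellipse acceptance probability
  set.seed(99)
  n <- 1e5
  pOracle <- mean((rnorm(n, 0, jit[1]) / tol[1])^2 +
                    (rnorm(n, 0, jit[2]) / tol[2])^2 <= 1)
  matched <- 0L; total <- 0L
  for (s in 1:30) {
    q <- makeHsqc("viscosin", simConfig(seed = s, peakJitter = jit))
    m <- matchPeaks(q, referenceFingerprint("viscosin"),
                    tolH = tol[1], tolC = tol[2])
    matched <- matched + m$nMatched
    total <- total + nrow(q)
  }
  se <- sqrt(pOracle * (1 - pOracle) / total)
  expect_lt(abs(matched / total - pOracle), max(4 * se, 0.02))
})
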