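test_that("windowed identity profiles agree with a brute-force recount", {
  a <- paste0(sample(lipomine:::.AA20, 200, replace = TRUE), collapse = "")
  prof <- windowedIdentity(a, a, window = 50)
  expect_true(all(prof$identity == 100))
  expect_true(all(prof$bin == "full"))
  # brute-force window recount over random gapped alignments
  set.seed(17)
  for (k in 1:10) {
    L <- sample(80:150, 1)
    pa <- sample(c(lipomine:::.AA20, "-"), L, replace = TRUE,
                 prob = c(rep(1, 20), 3))
    ps <- ifelse(runif(L) < 0.5, pa, sample(c(lipomine:::.AA20, "-"), L,
                                            replace = TRUE))
    w <- sample(10:40, 1)
    prof <- windowedIdentityFromAlignment(pa, ps, w)
    recount <- vapply(seq_len(L - w + 1L), function(s) {
      cols <- s:(s + w - 1L)
      mean(pa[cols] == ps[cols] & pa[cols] != "-") * 100
    }, numeric(1))
    expect_equal(prof$identity, recount)
    expect_true(all(prof$bin[prof$identity >= 100] == "full"))
    expect_true(all(prof$bin[prof$identity < 30] == "low"))
  }
  # all-gap row: every window scores zero
  allGap <- windowedIdentityFromAlignment(rep("-", 60),
                                          sample(lipomine:::.AA20, 60, TRUE),
                                          window = 50)
  expect_true(all(allGap$identity == 0))
  expect_error(windowedIdentityFromAlignment(rep("A", 10), rep("A", 10), 50),
               "window exceeds")
})

test_that("half-conserved sequences show the full-to-low transition", {
  set.seed(18)
  left <- paste0(sample(lipomine:::.AA20, 100, replace = TRUE), collapse = "")
  rightA <- paste0(sample(lipomine:::.AA20, 100, replace = TRUE), collapse = "")
  rightB <- paste0(sample(lipomine:::.AA20, 100, replace = TRUE), collapse = "")
  prof <- windowedIdentityFromAlignment(
    strsplit(paste0(left, rightA), "")[[1]],
    strsplit(paste0(left, rightB), "")[[1]], window = 50)
  expect_true(all(prof$identity[1:51] == 100))
  expect_lt(min(prof$identity[101:151]), 30)
})

test_that("module deletions are recovered as single events with exact spans", {
  xtl <- syntheticSystem(familyVariants("Xantholysin")$sequence[[1]],
                         "Xantholysin", id = "xtl")
  del <- dropModules(xtl, 5:8)
  res <- alignModules(xtl, del)
  dels <- res$events[res$events$kind == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$modules, "5,6,7,8")
  pso <- syntheticSystem(familyVariants("Putisolvin")$sequence[[2]],
                         "Putisolvin", id = "pso")
  del3 <- dropModules(pso, 6:8)
  expect_equal(nrow(del3@modules), 9L)
  res3 <- alignModules(pso, del3)
  d3 <- res3$events[res3$events$kind == "deletion", ]
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$modules, "6,7,8")
  # a system against itself carries no events
  self <- alignModules(xtl, xtl)
  expect_equal(nrow(self$events), 0L)
  expect_error(alignModules(xtl, systemFromAseqs(character())), "empty module")
})

test_that("random module-block deletions are recovered exactly (20 runs)", {
  set.seed(19)
  kb <- defaultKnowledgeBase()
  for (k in 1:20) {
    fam <- lpFamilies(kb)[[sample(13, 1)]]
    full <- syntheticSystem(fam@variants$sequence[[1]], familyName(fam),
                            id = familyName(fam))
    n <- nrow(full@modules)
    span <- sample(1:min(4, n - 2), 1)
    start <- sample(1:(n - span), 1)
    del <- dropModules(full, start:(start + span - 1L))
    res <- alignModules(full, del)
    dels <- res$events[res$events$kind == "deletion", ]
    expect_equal(nrow(dels), 1L, info = sprintf("run %d (%s %d:%d)", k,
                                                familyName(fam), start, span))
    expect_equal(dels$modules,
                 paste(start:(start + span - 1L), collapse = ","),
                 info = sprintf("run %d", k))
  }
})

test_that("exchanged modules are flagged only with flanking support", {
  asp <- syntheticSystem(familyVariants("Asplenin")$sequence[[1]],
                         "Asplenin", id = "asp")
  spec <- familyVariants("Asplenin")$sequence[[1]]
  # swap module 7 for a foreign Thr lineage
  swapped <- asp
  swapped@modules$aSequence[7] <- lipomine:::lineageSequence("Viscosin", 3,
                                                             "Thr")
  specB <- spec
  specB[7] <- "Thr"
  res <- alignModules(asp, swapped, specA = spec, specB = specB)
  ex <- res$events[res$events$kind == "exchange", ]
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$modules, "7,7")
  # the same swap at a terminal module is a substitution, not an exchange
  swappedEnd <- asp
  swappedEnd@modules$aSequence[13] <- lipomine:::lineageSequence("Viscosin",
                                                                 3, "Thr")
  specC <- spec
  specC[13] <- "Thr"
  resEnd <- alignModules(asp, swappedEnd, specA = spec, specB = specC)
  expect_equal(nrow(resEnd$events[resEnd$events$kind == "exchange", ]), 0L)
  expect_equal(nrow(resEnd$events[resEnd$events$kind == "substitution", ]), 1L)
})

test_that("adjacent duplications are detected at the configured threshold", {
  amph <- syntheticSystem(familyVariants("Amphisin")$sequence[[4]],
                          "Amphisin", id = "amph")
  dup <- amph
  # copy module 7 over module 8 with slight divergence: a planted
  # duplication of the Leu7 module
  dup@modules$aSequence[8] <- withr::with_seed(20,
    lipomine:::mutateProtein(dup@modules$aSequence[7], 0.03))
  events <- detectDuplications(dup, threshold = 0.9)
  expect_equal(events$modules, "7,8")
  # the untouched template has no near-identical adjacent pair
  expect_equal(nrow(detectDuplications(amph, threshold = 0.9)), 0L)
  # threshold zero reports every adjacent pair
  expect_equal(nrow(detectDuplications(amph, threshold = 0)),
               nrow(amph@modules) - 1L)
})
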