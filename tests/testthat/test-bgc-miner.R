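test_that("candidate screening finds exactly the planted NRPS genes", {
  cfg <- simConfig(seed = 21, mutationRate = 0.05, decoyGeneCount = 5)
  g <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                  cfg, "cand", decoyKinds = "plain")
  cand <- findCandidates(g)
  expect_length(cand, 3L)
  expect_setequal(vapply(cand, `[[`, character(1), "id"),
                  g@truth$clusters[[1]]$genes)
  g0 <- makeGenome(list(), cfg, "neg", decoyKinds = "plain")
  expect_length(findCandidates(g0), 0L)
})

test_that("dual-producer genomes yield candidates from both clusters", {
  cfg <- simConfig(seed = 22, mutationRate = 0.05, decoyGeneCount = 0)
  g <- makeGenome(list(list(family = "Tolaasin", organization = "contiguous"),
                       list(family = "Viscosin", organization = "contiguous")),
                  cfg, "dual")
  cand <- findCandidates(g)
  planted <- unlist(lapply(g@truth$clusters, `[[`, "genes"))
  expect_setequal(vapply(cand, `[[`, character(1), "id"), planted)
})

test_that("exclusion rules flag siderophore-like, E-domain and fragment decoys", {
  cfg <- simConfig(seed = 23, mutationRate = 0.05, decoyGeneCount = 3)
  g <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                  cfg, "excl",
                  decoyKinds = c("single_te", "standalone_e", "fragment"))
  filt <- applyExclusions(findCandidates(g))
  expect_length(filt$retained, 3L)  # the planted Viscosin genes
  flagOf <- function(tag) {
    hit <- Filter(function(x) x$id == tag, filt$excluded)
    if (length(hit)) hit[[1]]$flags else character()
  }
  decoys <- g@truth$decoys
  for (d in decoys) {
    expected <- switch(d$kind, single_te = "single_TE",
                       standalone_e = "standalone_E", fragment = "fragment")
    expect_true(expected %in% flagOf(d$locusTag), info = d$kind)
  }
  # retained genes carry no flags at all
  expect_false(any(vapply(filt$retained, function(x)
    !is.null(x$flags) && length(x$flags) > 0, logical(1))))
})

test_that("synteny scan reports the planted flanking roles", {
  cfg <- simConfig(seed = 24, mutationRate = 0.05)
  g <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                  cfg, "syn")
  filt <- applyExclusions(findCandidates(g))
  rep <- checkSynteny(filt$retained, g)
  expect_equal(rep$upstreamRegulator, "present_antisense")
  expect_true(rep$pleC)
  expect_true(rep$pleAB)
  expect_true(rep$secondRegulator)
  expect_equal(rep$accessory, "none")
  gt <- makeGenome(list(list(family = "Tolaasin", organization = "contiguous")),
                   cfg, "syn2")
  ft <- applyExclusions(findCandidates(gt))
  expect_equal(checkSynteny(ft$retained, gt)$accessory, "syrD_dab")
  gm <- makeGenome(list(list(family = "Thanafactin",
                             organization = "contiguous")), cfg, "syn3")
  fm <- applyExclusions(findCandidates(gm))
  repM <- checkSynteny(fm$retained, gm)
  expect_equal(repM$accessory, "mfs")
  expect_equal(repM$upstreamRegulator, "absent")
  expect_false(repM$pleAB)
})

test_that("organization resolution pairs split clusters and records spacers", {
  cfg <- simConfig(seed = 25, mutationRate = 0.05)
  ge <- makeGenome(list(list(family = "Entolysin", organization = "bifurcate")),
                   cfg, "org1")
  bgcs <- resolveOrganization(applyExclusions(findCandidates(ge))$retained, ge)
  expect_length(bgcs, 1L)
  expect_equal(bgcs[[1]]@organization, "bifurcate")
  expect_equal(nrow(bgcs[[1]]@system@modules), 14L)
  expect_true(is.na(bgcs[[1]]@interClusterDistance))
  gv <- makeGenome(list(list(family = "Viscosin", organization = "contiguous")),
                   cfg, "org2")
  bv <- resolveOrganization(applyExclusions(findCandidates(gv))$retained, gv)
  expect_equal(bv[[1]]@organization, "contiguous")
  expect_true(all(bv[[1]]@spacers >= 150 & bv[[1]]@spacers <= 300))
  expect_equal(bv[[1]]@spacers, as.numeric(gv@truth$clusters[[1]]$spacers))
})

test_that("an orphan initiator with no operon is flagged incomplete", {
  cfg <- simConfig(seed = 26, mutationRate = 0.05)
  bgc <- makeBgc("Xantholysin", "bifurcate", cfg)
  ini <- bgc@genes[[1]]
  cand <- list(list(record = "r1", id = "ini", start = 1000,
                    end = 1000 + nchar(ini$protein) * 3 + 3, strand = "+",
                    protein = ini$protein, domains = callDomains(ini$protein),
                    hasStop = FALSE))
  genome <- new("LpGenome", id = "orph",
                records = list(list(id = "r1", length = 2e5,
                                    features = lipomine:::.emptyFeatures())),
                truth = list())
  res <- resolveOrganization(cand, genome)
  expect_length(res, 1L)
  expect_true("incomplete" %in% res[[1]]@exclusionFlags)
})

test_that("mining is invariant under record order permutation", {
  cfg <- simConfig(seed = 27, mutationRate = 0.05)
  g <- makeGenome(list(list(family = "Poaeamide", organization = "bifurcate")),
                  cfg, "perm")
  res1 <- mineGenome(g)
  gFlip <- new("LpGenome", id = g@id, records = rev(g@records),
               truth = g@truth)
  res2 <- mineGenome(gFlip)
  expect_length(res1$bgcs, 1L)
  expect_length(res2$bgcs, 1L)
  expect_equal(res2$bgcs[[1]]@system@modules$aSequence,
               res1$bgcs[[1]]@system@modules$aSequence)
  expect_equal(res2$bgcs[[1]]@organization, res1$bgcs[[1]]@organization)
})
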