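test_that("pairwise identity is exact, symmetric and oracle-consistent", {
  expect_equal(adomainIdentity("MKLVA", "MKLVA"), 1)
  expect_error(adomainIdentity("MK1", "MKL"), "non-amino-acid")
  expect_error(adomainIdentity("", "MKL"), "empty")
  # alignment score agrees with an independent affine-gap DP oracle
  b62 <- local({ e <- new.env(); data("BLOSUM62", package = "Biostrings",
                                     envir = e); e$BLOSUM62 })
  set.seed(7)
  for (k in 1:6) {
    a <- paste0(sample(lipomine:::.AA20, 60, replace = TRUE), collapse = "")
    b <- if (k == 1) paste(rev(strsplit(a, "")[[1]]), collapse = "")
         else paste0(sample(lipomine:::.AA20, sample(40:80, 1),
                            replace = TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = b62, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), gotohScore(a, b, b62),
                 tolerance = 1e-8)
  }
  # symmetry over random pairs
  set.seed(8)
  for (k in 1:20) {
    a <- paste0(sample(lipomine:::.AA20, 50, replace = TRUE), collapse = "")
    b <- paste0(sample(lipomine:::.AA20, 55, replace = TRUE), collapse = "")
    expect_equal(adomainIdentity(a, b), adomainIdentity(b, a))
  }
  # identity on an unambiguous one-indel alignment: 49 matches / 50 columns
  a <- paste0(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  a <- substr(a, 1, 50)
  b <- paste0(substr(a, 1, 24), substr(a, 26, 50))
  expect_equal(adomainIdentity(a, b), 49 / 50)
})

test_that("classification is self-consistent and permutation-stable", {
  refs <- makeReferenceSet(simConfig(seed = 31, mutationRate = 0.1,
                                     nRefsPerSpecificity = 3))
  call <- classifySpecificity(refs$sequence[refs$id == "Leu_ref01"], refs)
  expect_equal(call$primary, "Leu")
  expect_equal(call$confidence, 1)
  set.seed(1)
  perm <- refs[sample(nrow(refs)), ]
  call2 <- classifySpecificity(refs$sequence[refs$id == "Leu_ref01"], perm)
  expect_equal(call2$primary, call$primary)
  expect_equal(call2$neighborId, call$neighborId)
  expect_error(classifySpecificity("MKL", refs[0, ]), "empty reference")
})

test_that("a Glu/Gln midpoint mutant is called ambiguous", {
  anchors <- lipomine:::specificityAnchors(450L)
  e <- strsplit(anchors$Glu, "")[[1]]
  q <- strsplit(anchors$Gln, "")[[1]]
  diffPos <- which(e != q)
  half <- diffPos[seq_len(floor(length(diffPos) / 2))]
  mid <- e
  mid[half] <- q[half]
  midSeq <- paste0(mid, collapse = "")
  # oracle distances confirm the construction is (near) equidistant
  dE <- lipomine:::hammingIdentity(midSeq, anchors$Glu)
  dQ <- lipomine:::hammingIdentity(midSeq, anchors$Gln)
  expect_lt(abs(dE - dQ), 0.01)
  refs <- makeReferenceSet(simConfig(seed = 32, mutationRate = 0,
                                     nRefsPerSpecificity = 1))
  call <- classifySpecificity(midSeq, refs)
  amb <- strsplit(call$ambiguitySet, ",")[[1]]
  expect_true(all(c("Glu", "Gln") %in% amb))
})

test_that("promiscuity and the unknown floor behave as configured", {
  anchors <- lipomine:::specificityAnchors(450L)
  refs <- makeReferenceSet(simConfig(seed = 33, mutationRate = 0,
                                     nRefsPerSpecificity = 1))
  ileLike <- withr::with_seed(3, lipomine:::mutateProtein(anchors$Ile, 0.2))
  call <- classifySpecificity(ileLike, refs)
  expect_equal(call$primary, "Ile")
  expect_setequal(strsplit(call$promiscuity, ",")[[1]], c("Val", "Leu"))
  junk <- withr::with_seed(4, lipomine:::randomProtein(450))
  expect_equal(classifySpecificity(junk, refs)$primary, "unknown")
})

test_that("leave-one-out recovery survives clade-level divergence", {
  # references within a specificity diverged to ~65% mutual identity
  refs <- makeReferenceSet(simConfig(seed = 34, mutationRate = 0.2,
                                     nRefsPerSpecificity = 4))
  hits <- 0L
  for (i in seq_len(nrow(refs))) {
    call <- classifySpecificity(refs$sequence[i], refs[-i, ])
    hits <- hits + (call$primary == refs$specificity[i])
  }
  expect_equal(hits, nrow(refs))
})

test_that("clade trees recover specificity monophyly and planted recruits", {
  refs <- makeReferenceSet(simConfig(seed = 35, mutationRate = 0.05,
                                     nRefsPerSpecificity = 3))
  sub <- refs[refs$specificity %in% c("Leu", "Val", "Ser", "Ile"), ]
  ct <- cladeTree(sub)
  expect_true(all(ct$monophyly))
  # a Val-labelled leaf built from the Ile anchor lands inside the Ile clade
  anchors <- lipomine:::specificityAnchors(450L)
  recruit <- data.frame(id = "planted_val", specificity = "Val",
                        sequence = withr::with_seed(9,
                          lipomine:::mutateProtein(anchors$Ile, 0.05)),
                        system = "planted", position = 1,
                        stringsAsFactors = FALSE)
  ct2 <- cladeTree(rbind(sub, recruit))
  expect_false(ct2$monophyly[["Ile"]])
  expect_false(ct2$monophyly[["Val"]])
  ileWithRecruit <- c(sub$id[sub$specificity == "Ile"], "planted_val")
  expect_true(lipomine:::.hasSplit(ct2$tree, ileWithRecruit))
})

test_that("the default reference database treats Thanafactin as an outgroup", {
  refs <- lpReferenceDomains()
  expect_false(any(refs$system == "Thanafactin"))
  full <- lpReferenceDomains(includeThanafactin = TRUE)
  expect_true(any(full$system == "Thanafactin"))
})
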