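test_that("distance matrices are identity-complements with guarded input", {
  seqs <- c(a = "MKLV", b = "MKLV", c = "MKLV")
  dm <- distanceMatrix(seqs)
  expect_true(all(dm == 0))
  s2 <- c(x = paste(rep("A", 100), collapse = ""),
          y = paste(c(rep("A", 90), rep("C", 10)), collapse = ""),
          z = paste(rep("C", 100), collapse = ""))
  dm2 <- distanceMatrix(s2)
  expect_equal(dm2["x", "y"], 0.10)
  expect_equal(dm2, t(dm2))
  expect_error(distanceMatrix(c(a = "MK", a = "ML", b = "MM")), "duplicate")
  expect_error(distanceMatrix(c(a = "MK", b = "ML")), ">= 3 taxa")
})

test_that("NJ recovers additive matrices exactly", {
  # 4-taxon additive matrix from a hand-built tree: branch lengths
  # a=2, b=3, c=4, d=5, internal=6
  dm <- matrix(c(0, 5, 12, 13,
                 5, 0, 13, 14,
                 12, 13, 0, 9,
                 13, 14, 9, 0), 4, 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- njTree(dm)
  gen <- ape::read.tree(text = "((a:2,b:3):6,c:4,d:5);")
  expect_equal(phangorn::RF.dist(tr, gen), 0)
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c", "d"),
                                         c("a", "b", "c", "d")], dm)
  # 3 taxa: the unique unrooted topology
  tr3 <- njTree(dm[1:3, 1:3])
  expect_equal(length(tr3$tip.label), 3L)
  # label permutation gives an isomorphic tree
  perm <- c("c", "a", "d", "b")
  expect_equal(phangorn::RF.dist(njTree(dm[perm, perm]), tr), 0)
  expect_error(njTree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("NJ recovers generating topologies over random additive trees", {
  set.seed(12)
  for (k in 1:50) {
    n <- sample(6:10, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- gen$edge.length + 0.1
    dm <- ape::cophenetic.phylo(gen)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), njTree(dm)), 0)
  }
})

test_that("bootstrap supports are seeded and saturate on clean clades", {
  # two clean clades: shared blocks with clade-specific columns
  blockA <- paste(rep("A", 30), collapse = "")
  blockB <- paste(rep("C", 30), collapse = "")
  noise <- function(seed) withr::with_seed(seed,
    paste(sample(c("G", "H"), 10, TRUE), collapse = ""))
  aligned <- c(t1 = paste0(blockA, noise(1)), t2 = paste0(blockA, noise(2)),
               t3 = paste0(blockB, noise(3)), t4 = paste0(blockB, noise(4)),
               t5 = paste0(blockB, noise(5)))
  # replicate trees of tiny alignments can hit the (warned) negative
  # branch-length clamp; that is expected here
  bs <- suppressWarnings(bootstrapSupport(aligned, nReps = 100, seed = 5))
  # the t3/t4/t5 clade is present in every replicate
  expect_true(any(bs$supports >= 0.99))
  bs2 <- suppressWarnings(bootstrapSupport(aligned, nReps = 100, seed = 5))
  expect_identical(bs$supports, bs2$supports)
  one <- suppressWarnings(bootstrapSupport(aligned, nReps = 1, seed = 6))
  expect_true(all(one$supports %in% c(0, 1)))
})

test_that("congruence of a tree with itself is perfect (fuzzed)", {
  set.seed(13)
  for (k in 1:10) {
    t <- ape::rtree(sample(5:12, 1))
    rep <- congruence(t, t)
    expect_equal(rep$normalizedRf, 0)
    expect_equal(rep$copheneticCorrelation, 1.0)
    expect_equal(nrow(rep$discordantLeaves), 0L)
  }
})

test_that("alternative 4-leaf resolutions are maximally discordant", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  rep <- congruence(t1, t2)
  expect_equal(rep$normalizedRf, 1.0)
  expect_error(congruence(ape::read.tree(text = "(a:1,b:1,c:1);"),
                          ape::read.tree(text = "(a:1,b:1,c:1);")),
               "fewer than 4")
})

test_that("a regrafted leaf is ranked first among discordant leaves", {
  for (s in 1:10) {
    set.seed(100 + s)
    t1 <- ape::rtree(12)
    t1$edge.length <- t1$edge.length + 0.5
    # regraft one leaf onto the most distant tip's edge
    coph <- ape::cophenetic.phylo(t1)
    moved <- t1$tip.label[1]
    target <- names(which.max(coph[moved, ]))
    t2 <- ape::drop.tip(t1, moved)
    where <- which(t2$tip.label == target)
    t2 <- ape::bind.tree(t2, ape::read.tree(text = paste0("(", moved, ":0.5);")),
                         where = where, position = 0.1)
    rep <- congruence(t1, t2)
    expect_gt(rep$normalizedRf, 0)
    expect_equal(rep$discordantLeaves$leaf[1], moved, info = paste("seed", s))
  }
})

test_that("newick and distance-matrix interfaces round-trip", {
  t <- ape::rtree(6)
  p <- tempfile(fileext = ".nwk")
  writeNewick(t, p)
  back <- readNewick(p)
  expect_equal(phangorn::RF.dist(t, back), 0)
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(m, tsv, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(readDistanceTsv(tsv), m)
  phy <- tempfile()
  writeLines(c("3", paste("a", 0, 1, 2), paste("b", 1, 0, 3),
               paste("c", 2, 3, 0)), phy)
  expect_equal(unname(readDistanceTsv(phy)), unname(m))
})
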