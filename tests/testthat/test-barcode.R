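test_that("K2P distance matches the closed form and deletion policy", {
  a <- strrep("A", 100)
  expect_equal(k2pDistance(a, a)$distance, 0)
  # 10 transitions in 100 sites: d = -log(0.8)/2
  b <- paste0(strrep("G", 10), strrep("A", 90))
  r <- k2pDistance(a, b)
  expect_equal(r$distance, -0.5 * log(0.8))
  expect_equal(r$comparableSites, 100)
  # gap/N sites are excluded and do not change d
  a2 <- paste0(strrep("A", 100), "-N")
  b2 <- paste0(strrep("G", 10), strrep("A", 90), "AC")
  r2 <- k2pDistance(a2, b2)
  expect_equal(r2$distance, r$distance)
  expect_equal(r2$comparableSites, 100)
  # pure transversions
  bq <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(k2pDistance(a, bq)$distance,
               -0.5 * log(1 - 0.1) - 0.25 * log(1 - 0.2))
  # saturation
  expect_error(k2pDistance(strrep("A", 4), strrep("G", 4)), "saturation")
  expect_error(k2pDistance("NN--", "ACGT"), "comparable")
  expect_error(k2pDistance("ACGT", "ACG"), "equal length")
})

test_that("K2P matrix agrees with independent oracles on random pairs", {
  bs <- simulateK2PSequences(
    seqSimConfig(groupSizes = c(6, 6), withinDivergence = 0.03,
                 betweenDivergence = 0.12), seed = 19)
  K <- k2pMatrix(bs)
  m <- wingmorph:::barcodeMatrix(bs)
  # site-counting oracle
  for (i in c(1, 5)) for (j in c(7, 12)) {
    expect_equal(K$distances[i, j], k2pOracle(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  }
  # ape::dist.dna K80 with pairwise deletion
  db <- ape::dist.dna(ape::as.DNAbin(sequences(bs)), model = "K80",
                      pairwise.deletion = TRUE)
  expect_equal(unname(K$distances), unname(as.matrix(db)), tolerance = 1e-12)
})

test_that("group distance summary recovers constructed closed forms", {
  # two groups of identical sequences, one transition between groups
  s <- c(g1_1 = strrep("A", 100), g1_2 = strrep("A", 100),
         g2_1 = paste0("G", strrep("A", 99)),
         g2_2 = paste0("G", strrep("A", 99)))
  bs <- BarcodeSet(s, c("g1", "g1", "g2", "g2"))
  gs <- groupDistanceSummary(bs, nBoot = 10, seed = 1)
  expect_equal(gs$within$mean, c(0, 0))
  expect_equal(gs$between$mean, -0.5 * log(1 - 0.02), tolerance = 1e-12)
  expect_equal(gs$barcodeGap, gs$between$mean)

  # all identical: zero gap
  s0 <- setNames(rep(strrep("ACGT", 25), 4), paste0("t", 1:4))
  gs0 <- groupDistanceSummary(BarcodeSet(s0, c("a", "a", "b", "b")),
                              nBoot = 5, seed = 1)
  expect_equal(gs0$barcodeGapPercent, 0)

  # singleton population: within reported as absent
  gs1 <- groupDistanceSummary(BarcodeSet(s0[1:3], c("a", "a", "b")),
                              nBoot = 5, seed = 1)
  expect_true(is.na(gs1$within$mean[gs1$within$population == "b"]))
})

test_that("NJ reproduces 3-taxon closed forms and additive matrices", {
  D <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- njTree(D)
  cp <- cophenetic(phy)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(cp, D)
  # closed-form pendant edges: a = (dAB + dAC - dBC)/2 = 1
  eA <- phy$edge.length[phy$edge[, 2] == which(phy$tip.label == "A")]
  expect_equal(eA, 1)

  # additive 6-taxon recovery, exact branch lengths
  set.seed(4)
  for (r in 1:5) {
    tr <- ape::rtree(6)
    Dt <- cophenetic(tr)
    rec <- njTree(Dt)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(rec)[rownames(Dt), colnames(Dt)] - Dt)),
              1e-10)
  }

  # identical rows join as a zero-length cherry
  D4 <- matrix(c(0, 0, 5, 6,
                 0, 0, 5, 6,
                 5, 5, 0, 3,
                 6, 6, 3, 0), 4,
               dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  p4 <- njTree(D4)
  cp4 <- cophenetic(p4)
  expect_equal(cp4["t1", "t2"], 0)

  # agreement with the reference implementation on noisy distances
  bs <- simulateK2PSequences(
    seqSimConfig(groupSizes = c(4, 4, 4), withinDivergence = 0.02,
                 betweenDivergence = 0.1), seed = 23)
  K <- k2pMatrix(bs)$distances
  expect_equal(ape::dist.topo(njTree(K), ape::nj(as.dist(K))), 0,
               ignore_attr = TRUE)

  # rooting on an outgroup
  pr <- njTree(K, outgroup = rownames(K)[1])
  expect_true(ape::is.rooted(pr))
  expect_error(njTree(K, outgroup = "nope"), "outgroup")
})

test_that("NJ on ultrametric matrices reproduces the UPGMA topology", {
  set.seed(9)
  h <- hclust(dist(matrix(rnorm(24), 6)), method = "average")
  Du <- as.matrix(cophenetic(h))
  nj <- njTree(Du)
  up <- upgmaTree(Du)$phylo
  expect_equal(ape::dist.topo(nj, ape::unroot(up)), 0, ignore_attr = TRUE)
})

test_that("bootstrap support is deterministic, bounded and signal-driven", {
  bs <- simulateK2PSequences(
    seqSimConfig(groupSizes = c(5, 5), length = 1000,
                 withinDivergence = 0.001, betweenDivergence = 0.2),
    seed = 31)
  b1 <- bootstrapSupport(bs, nReps = 60, seed = 5)
  b2 <- bootstrapSupport(bs, nReps = 60, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  # the deep split between the two clearly divergent groups: full support
  g1 <- specimenIds(bs)[populations(bs) == "pop1"]
  expect_true(isClade(b1$tree, g1))
  expect_gte(max(b1$support), 95)

  # taxon order permutation: the well-supported deep split is unchanged
  # (shallow within-group splits are ties and may resolve differently)
  perm <- sample(length(sequences(bs)))
  bsP <- BarcodeSet(sequences(bs)[perm], populations(bs)[perm])
  b3 <- bootstrapSupport(bsP, nReps = 60, seed = 5)
  expect_true(all(b3$support >= 0 & b3$support <= 100))
  expect_true(isClade(b3$tree, g1))
  expect_equal(max(b3$support), max(b1$support))
})
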