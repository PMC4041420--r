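test_that("tree simulation is seeded, ultrametric and unit depth", {
  tr <- simulateTree(50, seed = 5)
  tr2 <- simulateTree(50, seed = 5)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_equal(max(depths), 1)
  expect_lt(diff(range(depths)), 1e-9)     # ultrametric
  cherry <- simulateTree(2, seed = 1)
  expect_equal(unname(ape::node.depth.edgelength(cherry)[1:2]),
               c(1, 1))
})

test_that("continuous trait simulation respects variance, lambda and the
           root", {
  tr <- simulateTree(40, seed = 2)
  x0 <- simulateContinuousTrait(tr, 0, 0.4, 1, seed = 3)
  expect_true(all(x0 == 0.4))
  ## lambda = 0: tips are i.i.d. with variance = depth * sigma2
  draws <- sapply(1:300, function(i)
    simulateContinuousTrait(tr, 1, 0, 0, seed = 1000 + i)[1:40])
  tipvar <- apply(draws, 1, var)
  expect_equal(mean(tipvar), 1, tolerance = 0.15)
  covs <- cov(t(draws))
  offd <- covs[upper.tri(covs)]
  expect_lt(mean(abs(offd)), 0.15)
  ## lambda = 1 on a fixed small tree: sample covariance tracks V
  tr5 <- simulateTree(5, seed = 9)
  V <- treeVcv(tr5)
  d5 <- sapply(1:2000, function(i)
    simulateContinuousTrait(tr5, 1, 0, 1, seed = 5000 + i)[1:5])
  expect_equal(cov(t(d5)), V[rownames(cov(t(d5))), colnames(cov(t(d5)))],
               tolerance = 0.12, ignore_attr = TRUE)
})

test_that("the OU trait is stationary around its optimum", {
  tr <- simulateTree(150, seed = 7)
  x <- simulateOUTrait(tr, sigma2 = 2 * 1.5 * 0.12^2, optimum = 0.5,
                       theta = 1.5, seed = 8)
  tips <- x[1:150]
  expect_lt(abs(mean(tips) - 0.5), 0.08)
  expect_lt(abs(sd(tips) - 0.12), 0.05)
  expect_error(simulateOUTrait(tr, 1, 0.5, -1), "theta")
})

test_that("presence simulation honours its limits and records events", {
  tr <- simulateTree(30, seed = 11)
  ## no gains from an absent root: everything stays absent
  s0 <- simulatePresence(tr, twoStateModel(1e-12, 1), rootState = 0,
                         seed = 12)
  expect_true(all(s0$tipStates == 0))
  expect_equal(nrow(s0$events), 0)
  ## no losses from a present root: everything stays present
  s1 <- simulatePresence(tr, twoStateModel(1, 1e-12), rootState = 1,
                         seed = 13)
  expect_true(all(s1$tipStates == 1))
  ## determinism
  sA <- simulatePresence(tr, twoStateModel(0.5, 1), seed = 14)
  sB <- simulatePresence(tr, twoStateModel(0.5, 1), seed = 14)
  expect_identical(sA, sB)
})

test_that("event counts on one branch are Poisson-consistent", {
  ## symmetric rates make the jump process Poisson with rate g + l... at
  ## rate r per state, total events on a branch of length t ~ Poisson(rt)
  tr <- ape::read.tree(text = "(a:2,b:0.001);")
  r <- 1.3
  counts <- sapply(1:800, function(i) {
    s <- simulatePresence(tr, twoStateModel(r, r), rootState = 0,
                          seed = 20000 + i)
    sum(s$events$node == 1)   # events on a's branch
  })
  expect_equal(mean(counts), r * 2, tolerance = 0.1)
  expect_equal(var(counts), r * 2, tolerance = 0.35)
})

test_that("coupled rates shift events toward the matching GC side", {
  tr <- simulateTree(80, seed = 31)
  gc <- simulateOUTrait(tr, 2 * 1.5 * 0.12^2, 0.5, 1.5, seed = 32)
  sim <- simulatePresence(tr, twoStateModel(0.01, 0.02), rootState = 1,
                          seed = 33, gcValues = gc, coupling = 60,
                          lossCoupling = 60, gcRef = 0.5,
                          link = "exponential")
  ## tips well below the threshold should mostly lack the species
  lo <- sim$tipStates[gc[1:80] < 0.42]
  hi <- sim$tipStates[gc[1:80] > 0.58]
  if (length(lo) >= 3) expect_lt(mean(lo), 0.5)
  if (length(hi) >= 3) expect_gt(mean(hi), 0.5)
  succeed()
})

test_that("gene sets hit their GC target and ribosomal bias direction", {
  g <- simulateGenes(0.6, nGenes = 30, codonsPerGene = 400,
                     nRibosomal = 6, ribosomalBias = 5, seed = 41)
  ## GC3 of the unbiased genes tracks the target (the ribosomal subset
  ## deliberately concentrates on preferred codons)
  gc3 <- mean(sapply(g$sequence[!g$isRibosomal], function(s) {
    b <- strsplit(s, "")[[1]]
    third <- b[seq(3, length(b), 3)]
    mean(third %in% c("G", "C"))
  }))
  expect_lt(abs(gc3 - 0.6), 0.02)
  encs <- sapply(g$sequence, function(s) encPrime(codonCounts(s)))
  d <- encDiff(encs, g$isRibosomal)
  expect_gt(d, 0)
  ## without differential bias the difference hovers near zero
  g0 <- simulateGenes(0.5, nGenes = 30, codonsPerGene = 400,
                      nRibosomal = 6, ribosomalBias = 1, seed = 42)
  encs0 <- sapply(g0$sequence, function(s) encPrime(codonCounts(s)))
  expect_lt(abs(encDiff(encs0, g0$isRibosomal)), 0.02)
})

test_that("ribosomal bias produces positive ENC'_diff consistently", {
  hits <- sapply(1:20, function(i) {
    g <- simulateGenes(0.5, nGenes = 20, codonsPerGene = 300,
                       nRibosomal = 5, ribosomalBias = 5,
                       seed = 6000 + i)
    encs <- sapply(g$sequence, function(s)
      suppressWarnings(encPrime(codonCounts(s))))
    encDiff(encs, g$isRibosomal) > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tRNA genes inherit the reference when substitution is off", {
  tr <- simulateTree(10, seed = 51)
  pres <- list(GAA = simulatePresence(tr, twoStateModel(1, 1e-12),
                                      rootState = 1, seed = 52))
  tg <- simulateTrnaGenes(tr, pres, seed = 53, subRate = 0,
                          injections = c(hgt_same_anticodon = 0L))
  expect_equal(length(unique(tg$genes$sequence)), 1L)
  ## every gene carries its species anticodon at the fixed positions
  expect_true(all(substr(tg$genes$sequence, 35, 37) == "GAA"))
})

test_that("injected copies pass the 80% self-score rule against their
           donors", {
  fx <- suppressWarnings(
    simulateFixture(simulationConfig(masterSeed = 8L, nTips = 80L)))
  inj <- fx$injections
  expect_gt(nrow(inj), 0)
  for (i in seq_len(nrow(inj))) {
    q <- fx$genes$sequence[fx$genes$organism == inj$recipient[i] &
                             fx$genes$anticodon == inj$species[i]]
    q <- q[length(q)]  # the injected copy
    d <- fx$genes$sequence[fx$genes$geneId == inj$donorGene[i]]
    expect_gte(alignScore(q, d), 0.8 * alignScore(q, q))
  }
})

test_that("operon maps co-place pairs and respect the unannotated
           fraction", {
  genes <- data.frame(
    organism = rep(c("a", "b"), each = 3),
    geneId = paste0(rep(c("a", "b"), each = 3), "|",
                    rep(c("CUC", "CUG", "GAA"), 2)),
    anticodon = rep(c("CUC", "CUG", "GAA"), 2),
    sequence = NA, stringsAsFactors = FALSE)
  om <- simulateOperons(genes, pairs = list(c("CUC", "CUG")),
                        unannotatedFraction = 0, seed = 61)
  shared <- table(om$operonId)
  expect_equal(sum(shared == 2), 2L)    # one pair operon per organism
  expect_equal(nrow(om), 6L)
  om2 <- simulateOperons(genes, pairs = list(),
                         unannotatedFraction = 0.5, seed = 62)
  expect_equal(nrow(om2), 3L)
  cov <- operonCoverage(om2, genes)
  expect_equal(mean(cov$coverage), 0.5, tolerance = 0.2)
})

test_that("the full fixture is deterministic and internally consistent", {
  cfg <- simulationConfig(masterSeed = 5L, nTips = 60L)
  fx1 <- suppressWarnings(simulateFixture(cfg))
  fx2 <- suppressWarnings(simulateFixture(cfg))
  expect_identical(as.matrix(fx1$presence), as.matrix(fx2$presence))
  expect_identical(fx1$genes, fx2$genes)
  expect_identical(fx1$trueEvents, fx2$trueEvents)
  ## gene table consistent with the presence matrix
  m <- as.matrix(fx1$presence)
  for (i in seq_len(nrow(fx1$genes))) {
    expect_equal(m[fx1$genes$organism[i], fx1$genes$anticodon[i]], 1L)
  }
  ## traits cover every organism with normalized columns
  expect_setequal(fx1$traits$organism, organisms(fx1$presence))
  expect_equal(mean(fx1$traits$gc.z), 0, tolerance = 1e-9)
})
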