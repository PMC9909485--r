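test_that("preprocessing applies the detection filter and log transform", {
  mat <- rbind(
    G1 = c(0, 0, 0, 5),      # detected once
    G2 = c(1, 2, 3, 4),      # detected in all
    G3 = c(0, 1, 0, 2))      # detected twice
  lx <- preprocessExpression(mat, minDetectedSamples = 2L)
  expect_identical(rownames(lx), c("G2", "G3"))
  expect_equal(unname(lx["G3", 1]), -4)   # TPM 0 -> log10(1e-4) exactly
  expect_equal(unname(lx["G2", 4]), log10(4 + 1e-4))

  # threshold is inclusive: detection in exactly min samples survives
  expect_identical(rownames(preprocessExpression(mat,
    minDetectedSamples = 1L)), c("G1", "G2", "G3"))
  expect_error(preprocessExpression(mat, minDetectedSamples = 5L),
               "empty-result")
})

test_that("survivor count matches a brute-force recount on random data", {
  set.seed(4)
  mat <- matrix(stats::rbinom(200 * 50, 1, 0.5) * stats::rexp(200 * 50),
                200, 50, dimnames = list(sprintf("G%03d", 1:200), NULL))
  lx <- preprocessExpression(mat, minDetectedSamples = 25L)
  expected <- sum(apply(mat, 1L, function(r) sum(r > 0) >= 25))
  expect_equal(nrow(lx), expected)
})

test_that("scale-free fit recognizes an exact power-law degree sequence", {
  # inverse-CDF construction of a Pareto connectivity sample
  n <- 2000L
  u <- (seq_len(n) - 0.5) / n
  k <- 1 * (1 - u)^(-1 / 1.5)   # density ~ k^(-2.5)
  fit <- scaleFreeFit(k)
  expect_gte(fit$r2, 0.95)
  expect_lt(fit$slope, 0)
})

test_that("soft-power selection falls back with a warning and decays meanK", {
  set.seed(6)
  sim <- simulateTissueExperiment(plantedModuleSpec(6, nmod = 2, size = 30,
                                                   nNoise = 40,
                                                   nSamples = 100))
  lx <- preprocessExpression(sim$se, minDetectedSamples = 1L)
  expect_warning(sft <- pickSoftPower(lx, powers = 1:10, r2Target = 0.99),
                 "not reached")
  expect_false(sft$reachedTarget)
  expect_true(sft$power %in% 1:10)
  # mean connectivity strictly decreases as the power increases
  expect_true(all(diff(sft$fitTable$meanK) < 0))
})

test_that("signed adjacency maps correlations onto [0,1] with closed forms", {
  s <- seq(0, 1, length.out = 10)
  lx <- rbind(up = s, up2 = 2 * s + 1, down = -s,
              flat = rep(0.5, 10))
  expect_warning(A <- signedAdjacency(lx, 12), "zero-variance")
  expect_equal(A["up", "up2"], 1)            # cor +1
  expect_equal(A["up", "down"], 0)           # cor -1
  expect_equal(A["up", "flat"], 0.5^12)      # cor set to 0
  expect_equal(unname(diag(A)), rep(1, 4))
  expect_true(all(A >= 0 & A <= 1))
})

test_that("signed adjacency preserves the ordering of correlations", {
  set.seed(12)
  lx <- matrix(stats::rnorm(8 * 60), 8, 60)
  C <- stats::cor(t(lx))
  A <- signedAdjacency(lx, 7)
  up <- upper.tri(C)
  expect_equal(order(C[up]), order(A[up]))
})

test_that("TOM reproduces hand computations and the brute-force oracle", {
  # 2-gene network: no shared neighbours, TOM equals the adjacency
  for (a in c(0.2, 0.7)) {
    A <- matrix(c(1, a, a, 1), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
    expect_equal(tomSimilarity(A)["x", "y"], a)
  }
  # identity adjacency has no off-diagonal overlap
  I5 <- diag(5)
  dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_equal(tomSimilarity(I5), I5)

  set.seed(15)
  for (i in 1:20) {
    A <- randomAdjacency(sample(3:8, 1))
    expect_equal(tomSimilarity(A), bruteTOM(A), tolerance = 1e-12)
  }

  bad <- randomAdjacency(4)
  bad[1, 2] <- 0.9; bad[2, 1] <- 0.1
  expect_error(tomSimilarity(bad), "symmetric")
})

test_that("TOM values are similarities: symmetric, unit diagonal, in [0,1]", {
  set.seed(16)
  for (i in 1:10) {
    tom <- tomSimilarity(randomAdjacency(sample(4:10, 1)))
    expect_true(isSymmetric(unname(tom), tol = 1e-12))
    expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("planted modules are recovered and pure noise yields none", {
  sim <- simulateTissueExperiment(plantedModuleSpec(1))
  lx <- preprocessExpression(sim$se, minDetectedSamples = 1L)
  tom <- tomSimilarity(signedAdjacency(lx, 12))
  mod <- detectModules(tom, lx)
  expect_equal(length(moduleSizes(mod)), 2L)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(moduleLabels(mod),
                                   trueModuleLabels(sim$se))
  expect_gte(ari, 0.9)

  # independent genes: everything unassigned
  nullSpec <- plantedModuleSpec(2, nmod = 0, size = 0, nNoise = 120)
  simN <- simulateTissueExperiment(nullSpec)
  lxN <- preprocessExpression(simN$se, minDetectedSamples = 1L)
  modN <- detectModules(tomSimilarity(signedAdjacency(lxN, 12)), lxN)
  expect_equal(length(moduleSizes(modN)), 0L)
  expect_true(all(moduleLabels(modN) == "unassigned"))
})

test_that("module labels are invariant to gene order", {
  sim <- simulateTissueExperiment(plantedModuleSpec(3, size = 35,
                                                    nNoise = 50,
                                                    nSamples = 150))
  lx <- preprocessExpression(sim$se, minDetectedSamples = 1L)
  tom <- tomSimilarity(signedAdjacency(lx, 12))
  mod <- detectModules(tom, lx)
  set.seed(33)
  perm <- sample(nrow(lx))
  modP <- detectModules(tom[perm, perm], lx[perm, , drop = FALSE])
  expect_identical(moduleLabels(modP)[names(moduleLabels(mod))],
                   moduleLabels(mod))
})

test_that("module colour names follow decreasing size order", {
  labels <- c(rep("a", 5), rep("b", 9), rep("c", 2))
  names(labels) <- sprintf("G%02d", seq_along(labels))
  out <- orAtlas:::relabelBySize(labels)
  expect_identical(unname(out[names(labels)[labels == "b"]][1]),
                   "turquoise")
  expect_identical(unname(out[names(labels)[labels == "a"]][1]), "blue")
  expect_identical(unname(out[names(labels)[labels == "c"]][1]), "brown")
})

test_that("eigengenes are dominant, oriented, unit-norm directions", {
  set.seed(41)
  n <- 60L
  common <- stats::rnorm(n)
  # module of identical genes: eigengene proportional to the shared profile
  lx <- rbind(A = common, B = common, C = common)
  e <- eigengeneMatrix(lx, stats::setNames(rep("m", 3), c("A", "B", "C")))
  expect_equal(nrow(e), 1L)
  expect_equal(sum(e^2), 1)
  expect_gt(stats::cor(e[1, ], common), 0.999999)

  # PC1 optimality versus a power-iteration oracle
  lx2 <- matrix(stats::rnorm(10 * n), 10, n,
                dimnames = list(sprintf("g%d", 1:10), NULL))
  lx2[1:6, ] <- lx2[1:6, ] + matrix(stats::rnorm(n, sd = 2), 6, n,
                                    byrow = TRUE)
  lab2 <- stats::setNames(c(rep("m", 6), rep("unassigned", 4)),
                          rownames(lx2))
  e2 <- eigengeneMatrix(lx2, lab2)["m", ]
  Z <- t(scale(t(lx2[1:6, ])))
  ref <- powerIterationPC(Z)
  expect_gt(abs(stats::cor(e2, ref)), 1 - 1e-8)

  # flipping every input changes nothing observable after orientation
  e3 <- eigengeneMatrix(-lx2, lab2)["m", ]
  expect_gt(abs(stats::cor(e2, e3)), 1 - 1e-8)
  expect_gt(stats::cor(e3, colMeans(t(scale(t(-lx2[1:6, ]))))), 0)
})

test_that("module merging joins near-identical eigengenes and fixes points", {
  set.seed(51)
  n <- 80L
  z <- stats::rnorm(n)
  lx <- rbind(
    matrix(rep(z, 6), 6, n, byrow = TRUE) + stats::rnorm(6 * n, sd = 0.1),
    matrix(rep(z, 6), 6, n, byrow = TRUE) + stats::rnorm(6 * n, sd = 0.1),
    matrix(stats::rnorm(6 * n), 6, n))
  rownames(lx) <- sprintf("g%02d", 1:18)
  labels <- stats::setNames(rep(c("blue", "brown", "turquoise"), each = 6),
                            rownames(lx))
  mod <- new("CoexpressionModules", labels = labels,
             eigengenes = eigengeneMatrix(lx, labels),
             mergeHistory = orAtlas:::emptyMergeHistory(),
             power = 6, cutHeight = 0.9)
  merged <- mergeModules(mod, lx, mergeHeight = 0.25)
  sz <- moduleSizes(merged)
  expect_equal(length(sz), 2L)
  expect_equal(unname(sz[1]), 12L)
  expect_equal(nrow(merged@mergeHistory), 1L)

  # mergeHeight = 0 is the identity
  same <- mergeModules(mod, lx, mergeHeight = 0)
  expect_identical(moduleLabels(same), labels)

  # result is independent of module enumeration order
  perm <- c(7:12, 13:18, 1:6)
  modP <- new("CoexpressionModules", labels = labels[perm],
              eigengenes = eigengeneMatrix(lx[perm, ], labels[perm]),
              mergeHistory = orAtlas:::emptyMergeHistory(),
              power = 6, cutHeight = 0.9)
  mergedP <- mergeModules(modP, lx[perm, ], mergeHeight = 0.25)
  expect_identical(moduleLabels(mergedP)[names(labels)],
                   moduleLabels(merged))
})

test_that("TOM edge export respects the cutoff and matches a recount", {
  set.seed(61)
  tom <- tomSimilarity(randomAdjacency(12))
  # cutoff near 1 on a bounded TOM gives no edges
  expect_equal(nrow(exportTOMEdges(tom, 1 - 1e-9)), 0L)
  # cutoff 0 keeps every pair
  expect_equal(nrow(exportTOMEdges(tom, 0)), 12 * 11 / 2)
  edges <- exportTOMEdges(tom, 0.4)
  expect_equal(nrow(edges), sum(tom[upper.tri(tom)] > 0.4))
  expect_true(all(edges$tom > 0.4))
  # SIF export, one line per edge
  f <- tempfile(fileext = ".sif")
  writeSIF(edges, f)
  expect_length(readLines(f), nrow(edges))
})

test_that("tissue fold profiles reference the grand mean of tissue means", {
  mat <- rbind(A = rep(6, 8),
               B = c(8, 8, 0, 0, 0, 0, 0, 0))
  labels <- rep(c("t1", "t2", "t3", "t4"), each = 2)
  prof <- tissueFoldProfile(mat, labels = labels)
  expect_equal(unname(prof["A", ]), rep(0, 4))
  # per-tissue means {8,0,0,0}: reference 2, so t1 is log2(~4) and the
  # zero tissues are pseudocount-floored near log2(1e-4 / 2)
  expect_equal(prof["B", "t1"], log2(8.0001 / 2.0001))
  expect_equal(prof["B", "t2"], log2(1e-4 / 2.0001))
  expect_lt(prof["B", "t2"], -14)

  # ratio invariance: doubling all TPM barely moves the profile
  prof2 <- tissueFoldProfile(mat * 2, labels = labels)
  expect_lt(max(abs(prof2["A", ] - prof["A", ])), 1e-4)
  expect_lt(abs(prof2["B", "t1"] - prof["B", "t1"]), 1e-4)
})
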