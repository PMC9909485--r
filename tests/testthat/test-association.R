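test_that("one-vs-rest Wilcoxon matches exact enumeration and handles ties", {
  # {1,2,3} vs {4,5,6}: rank sum 6 is the most extreme of C(6,3) = 20
  # assignments, so the two-sided exact p is 2/20 = 0.1
  v <- c(1, 2, 3, 4, 5, 6)
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(wilcoxonOneVsRest(v, lab, "a"), 0.1)
  expect_equal(wilcoxonOneVsRest(v, lab, "a"), exactWilcoxonP(v[1:3], v[4:6]))

  # identical multisets show no shift
  v <- c(5, 7, 9, 5, 7, 9)
  expect_equal(wilcoxonOneVsRest(v, lab, "a"), 1)

  # constant input is degenerate, p = 1
  expect_equal(wilcoxonOneVsRest(rep(2, 6), lab, "a"), 1)

  expect_error(wilcoxonOneVsRest(1:3, rep("a", 3), "a"), "non-empty")
})

test_that("fold change follows the pseudocount-guarded mean ratio", {
  lab <- rep(c("t", "r"), each = 4)
  v <- c(rep(50, 4), rep(2, 4))
  expect_equal(foldChange(v, lab, "t", 1e-4), 50.0001 / 2.0001)
  # identical groups give 1
  expect_equal(foldChange(rep(3, 8), lab, "t"), 1)
  # all-zero gene gives pseudocount/pseudocount = 1
  expect_equal(foldChange(rep(0, 8), lab, "t"), 1)
})

test_that("LDA AUC covers separation, ties, and degenerate variance", {
  lab <- rep(c("t", "r"), each = 3)
  expect_equal(ldaAuc(c(10, 11, 12, 1, 2, 3), lab, "t"), 1)
  # zero pooled variance: AUC from the class constants
  expect_equal(ldaAuc(c(5, 5, 5, 1, 1, 1), lab, "t"), 1)
  expect_equal(ldaAuc(c(1, 1, 1, 5, 5, 5), lab, "t"), 0)
  expect_equal(ldaAuc(rep(4, 6), lab, "t"), 0.5)
})

test_that("LDA AUC equals the pair-counting Mann-Whitney AUC (or complement)", {
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(3:25, 1)
    n0 <- sample(3:40, 1)
    x <- round(stats::rnorm(n1, sample(0:2, 1)), 1)  # rounding makes ties
    y <- round(stats::rnorm(n0), 1)
    v <- c(x, y)
    lab <- rep(c("t", "r"), c(n1, n0))
    mw <- pairCountAUC(x, y)
    expected <- if (mean(x) > mean(y)) mw
                else if (mean(x) < mean(y)) 1 - mw else 0.5
    expect_equal(ldaAuc(v, lab, "t"), expected)
  }
})

test_that("LDA AUC agrees with a fitted LDA + ROC oracle", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:50) {
    n1 <- sample(5:20, 1)
    n0 <- sample(5:30, 1)
    x <- stats::rnorm(n1, sample(c(-1, 0, 1), 1))
    y <- stats::rnorm(n0)
    d <- data.frame(v = c(x, y), cls = rep(c("t", "r"), c(n1, n0)))
    fit <- MASS::lda(cls ~ v, data = d)
    score <- stats::predict(fit, d)$posterior[, "t"]
    ref <- as.numeric(pROC::auc(pROC::roc(d$cls, score, levels = c("r", "t"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ldaAuc(d$v, d$cls, "t"), ref, tolerance = 1e-8)
  }
})

test_that("permuted labels give a null AUC near one half", {
  set.seed(23)
  n <- 1000L
  aucs <- vapply(1:200, function(i) {
    v <- stats::rnorm(n)
    lab <- sample(rep(c("t", "r"), c(200, 800)))
    ldaAuc(v, lab, "t")
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("association calling recovers planted markers with consistent flags", {
  spec <- demoSimSpec(nTissues = 4, samplesPerTissue = 100, nMarkers = 4,
                      nNullOR = 40, seed = 5L)
  sim <- simulateTissueExperiment(spec)
  assoc <- callAssociations(sim$se)
  rec <- markerRecovery(assoc, sim$truth)
  expect_equal(rec$sensitivity, 1)
  expect_gte(rec$specificity, 0.99)

  tab <- assocTable(assoc)
  cfg <- assoc@criteria
  expect_identical(tab$passes,
                   tab$p_value < cfg$pMax & tab$fold_change >= cfg$fcMin &
                     tab$lda_auc >= cfg$aucMin)
  expect_true(all(tab$lda_auc >= 0 & tab$lda_auc <= 1))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))

  # unreachable fold threshold kills every call
  none <- callAssociations(sim$se,
    criteria = associationCriteria(fcMin = Inf))
  expect_equal(sum(assocTable(none)$passes), 0L)
})

test_that("tightening any threshold can only shrink the pass set", {
  spec <- demoSimSpec(nTissues = 3, samplesPerTissue = 60, nMarkers = 6,
                      markerFold = 30, nNullOR = 20, seed = 9L)
  sim <- simulateTissueExperiment(spec)
  loose <- callAssociations(sim$se,
    criteria = associationCriteria(pMax = 1e-5, fcMin = 5, aucMin = 0.7))
  tight <- callAssociations(sim$se,
    criteria = associationCriteria(pMax = 1e-8, fcMin = 10, aucMin = 0.8))
  passLoose <- with(assocTable(loose), paste(gene, tissue)[passes])
  passTight <- with(assocTable(tight), paste(gene, tissue)[passes])
  expect_true(all(passTight %in% passLoose))
})

test_that("one-vs-rest statistics ignore how the rest is partitioned", {
  set.seed(31)
  v <- stats::rgamma(90, 2)
  lab1 <- rep(c("t", "r1", "r2"), each = 30)
  lab2 <- rep(c("t", "x1", "x2"), c(30, 10, 50))
  for (f in list(wilcoxonOneVsRest, foldChange, ldaAuc))
    expect_equal(f(v, lab1, "t"), f(v, lab2, "t"))
})

test_that("raising a planted shift never lowers fold change or AUC", {
  base <- c(rep(1, 10), rep(1, 30))
  lab <- rep(c("t", "r"), c(10, 30))
  folds <- c(2, 5, 10, 50)
  fc <- vapply(folds, function(f)
    foldChange(base * ifelse(lab == "t", f, 1), lab, "t"), numeric(1L))
  expect_true(all(diff(fc) >= 0))
  shifts <- c(0, 0.5, 1, 2)
  set.seed(2)
  noise <- stats::rnorm(40, sd = 0.3)
  auc <- vapply(shifts, function(s)
    ldaAuc(noise + ifelse(lab == "t", s, 0), lab, "t"), numeric(1L))
  expect_true(all(diff(auc) >= 0))
})

test_that("tissue z-scores standardize per-tissue medians", {
  mat <- rbind(
    A = c(10, 10, 0, 0, 0, 0),   # expressed only in tissue a
    B = rep(4, 6),               # constant
    C = c(0, 0, 0, 0, 10, 10))
  labels <- rep(c("a", "b", "c"), each = 2)
  z <- tissueZscore(mat, labels = labels)
  expect_equal(dim(z), c(3L, 3L))
  expect_equal(unname(rowSums(z)), rep(0, 3))
  expect_equal(unname(which.max(z["A", ])), 1L)
  expect_equal(unname(z["B", ]), rep(0, 3))
  # medians {0, 0, 10} standardize (sample sd) to -0.577, -0.577, 1.155
  expect_equal(unname(z["C", ]), c(-0.5773503, -0.5773503, 1.1547005),
               tolerance = 1e-6)
})
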