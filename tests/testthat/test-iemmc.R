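test_that("initial populations are balanced, diverse and reproducible", {
  cfg <- iemmcConfig(seed = 4)
  pop <- initPopulation(40, cfg)
  expect_length(pop, cfg$popSize)
  l <- floor(0.2 * 40)
  for (a in pop) expect_lte(abs(sum(a$y)), l)
  dists <- c()
  for (i in seq_along(pop)) for (j in seq_len(i - 1))
    dists <- c(dists, iemmc:::.hamming(pop[[i]]$y, pop[[j]]$y))
  expect_true(all(dists > 40 / 10))
  pop2 <- initPopulation(40, cfg)
  expect_identical(pop, pop2)

  # impossible suppression threshold is reported, not looped forever
  expect_error(initPopulation(10, iemmcConfig(ts = 10, seed = 1)),
               "reduce ts")
})

test_that("clonal selection copies the best, proportionally to rank", {
  pop <- lapply(c(0.9, 0.5, 0.7, 0.2, 0.8), function(f)
    list(y = c(1, -1), J = -log(f), F = f, evaluated = TRUE))
  clones <- cloneSelect(pop, 3)
  Fs <- vapply(clones, `[[`, numeric(1), "F")
  expect_equal(sum(Fs == 0.9), 3)   # best: 3 copies
  expect_equal(sum(Fs == 0.8), 2)
  expect_equal(sum(Fs == 0.7), 1)
  expect_true(all(vapply(clones, function(cl) all(cl$y %in% c(-1, 1)),
                         logical(1))))
})

test_that("pair-flip mutation conserves the label sum", {
  set.seed(7)
  for (i in 1:20) {
    y <- iemmc:::.randomBalancedY(30, 6)
    y2 <- iemmc:::mutateLabels(y, sample(1:5, 1))
    expect_equal(sum(y2), sum(y))
    expect_true(any(y2 != y))
  }
  expect_error(iemmc:::mutateLabels(rep(1, 5), 1), "single class")
})

test_that("hypermutation keeps the parent unless affinity improves", {
  gd <- genClusterData(20, 2, separation = 6, dims = 2, seed = 2)
  K <- kernelMatrix(gd$X, "rbf_printed", 3)
  truth <- blobTruth(gd)
  parent <- evaluateAntibody(K, truth, C = 1, l = 4)
  child <- hypermutate(parent, f = 2, K, C = 1, seed = 5)
  expect_gte(child$F, parent$F)
  child2 <- hypermutate(parent, f = 2, K, C = 1, seed = 5)
  expect_identical(child, child2)
})

test_that("reselection is elitist and receptor editing spares the memory", {
  ys <- list(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1),
             c(-1, 1, 1, -1), c(-1, 1, -1, 1), c(1, 1, 1, -1))
  mk <- function(f, i) list(y = ys[[i]], J = -log(f), F = f, evaluated = TRUE)
  pop <- list(mk(0.3, 1), mk(0.6, 2), mk(0.1, 3), mk(0.5, 4))
  out <- reselect(pop, list(mk(0.9, 5)), list(mk(0.7, 6)), popSize = 4)
  Fs <- vapply(out, `[[`, numeric(1), "F")
  expect_equal(max(Fs), 0.9)
  expect_length(out, 4)
  # an evaluated duplicate outranks its stale copy
  dup <- reselect(pop, list(mk(0.95, 1)), list(), popSize = 4)
  expect_equal(max(vapply(dup, `[[`, numeric(1), "F")), 0.95)

  edited <- receptorEdit(out, fraction = 0.5, n = 4, l = 2,
                         memorySize = 1, seed = 3)
  eF <- vapply(edited, `[[`, numeric(1), "F")
  expect_equal(max(eF, na.rm = TRUE), 0.9)       # best untouched
  expect_true(sum(!vapply(edited, `[[`, logical(1), "evaluated")) >= 1)
  expect_identical(receptorEdit(out, 0, 4, 2, 1, 3), out)
})

test_that("antibody evaluation is idempotent and balance-preserving", {
  gd <- genClusterData(24, 2, separation = 6, dims = 2, seed = 3)
  K <- kernelMatrix(gd$X, "rbf_printed", 3)
  set.seed(1)
  y <- iemmc:::.randomBalancedY(24, 4)
  e1 <- evaluateAntibody(K, y, C = 1, l = 4)
  e2 <- evaluateAntibody(K, e1$y, C = 1, l = 4)
  expect_equal(e2$J, e1$J, tolerance = 1e-12)
  expect_identical(e2$y, e1$y)
  expect_lte(abs(sum(e1$y)), 4)
  # a correct labeling scores strictly better than a scrambled one
  truth <- blobTruth(gd)
  Jt <- evaluateAntibody(K, truth, C = 1, l = 4)
  set.seed(9)
  scr <- sample(truth)
  expect_gt(Jt$F, innerSolve(K, scr, 1)@F)
})

test_that("the immune loop recovers separated blobs and is monotone", {
  gd <- genClusterData(60, 2, separation = 6, dims = 2, seed = 7)
  truth <- blobTruth(gd)
  fit <- runIEMMC(gd$X, iemmcConfig(seed = 1))
  expect_equal(signAgreement(fit$y, truth), 1)
  expect_true(all(diff(fit$history$bestF) >= -1e-12))
  expect_lte(abs(sum(fit$y)), fit$l)
  fit2 <- runIEMMC(gd$X, iemmcConfig(seed = 1))
  expect_identical(fit$y, fit2$y)
  expect_identical(fit$history, fit2$history)
})

test_that("kmeans-seeded initialization also recovers the partition", {
  gd <- genClusterData(40, 2, separation = 6, dims = 2, seed = 8)
  fit <- runIEMMC(gd$X, iemmcConfig(init = "kmeans", seed = 2))
  expect_equal(signAgreement(fit$y, blobTruth(gd)), 1)
})

test_that("recursive bipartition reduces to a single run for k = 2", {
  gd <- genClusterData(30, 2, separation = 6, dims = 2, seed = 9)
  cfg <- iemmcConfig(seed = 5)
  lab <- recursiveMulticlass(gd$X, 2, cfg)
  fit <- runIEMMC(gd$X, cfg)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_identical(lab == 1L, fit$y > 0)
})

test_that("recursive bipartition returns k non-empty clusters", {
  gd <- genClusterData(90, 3, separation = 8, dims = 3, seed = 10)
  lab <- recursiveMulticlass(gd$X, 3, iemmcConfig(seed = 6))
  expect_equal(sort(unique(lab)), 1:3)
  expect_true(all(table(lab) > 0))
  mc <- matchClusters(lab, gd$labels)
  expect_gte(mc$agreement, 0.95)
})
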