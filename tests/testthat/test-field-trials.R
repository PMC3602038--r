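test_that("a flat field yields a negligible spatial component", {
  ft <- generateFieldTrial(fieldTrialPlan(nEnvs = 1, spatialAmplitude = 0),
                           seed = 1)
  f <- fitSpatialSurface(ft$plots)
  expect_lt(max(abs(f$spatial)), 0.3)         # below the noise scale
  expect_equal(mean(f$spatial), 0, tolerance = 1e-8)
  expect_equal(f$corrected, ft$plots$value - f$spatial)
})

test_that("a planted smooth surface is recovered on the trial grid", {
  ft <- generateFieldTrial(fieldTrialPlan(nEnvs = 1, spatialAmplitude = 1,
                                          noiseSd = 0.3), seed = 11)
  p <- ft$plots
  f <- fitSpatialSurface(p)
  truth <- ft$truth$spatial(p$row, p$column)
  expect_gt(cor(f$spatial, truth - mean(truth)), 0.9)
})

test_that("a surface in the spline null space is fit exactly at zero noise", {
  set.seed(2)
  grid <- expand.grid(row = 1:6, column = 1:6)
  grid$variety <- sample(rep(sprintf("v%d", 1:6), 6))
  truth <- 0.5 * grid$row - 0.3 * grid$column
  grid$value <- 2 + truth
  f <- fitSpatialSurface(grid, k = c(4, 4))
  expect_lt(max(abs(f$spatial - (truth - mean(truth)))), 1e-8)
})

test_that("spatial recovery holds across 20 seeded simulations", {
  cors <- vapply(1:20, function(s) {
    ft <- generateFieldTrial(fieldTrialPlan(nEnvs = 1), seed = 100 + s)
    p <- ft$plots
    f <- fitSpatialSurface(p)
    truth <- ft$truth$spatial(p$row, p$column)
    cor(f$spatial, truth - mean(truth))
  }, numeric(1))
  expect_gt(median(cors), 0.9)
})

test_that("variety effects are recovered without bias", {
  ests <- lapply(1:8, function(s) {
    ft <- generateFieldTrial(fieldTrialPlan(nEnvs = 1, nVarieties = 10),
                             seed = 300 + s)
    f <- fitSpatialSurface(ft$plots)
    g <- ft$truth$G
    # coefficients are relative to the first variety level
    ref <- sort(names(g))[1]
    est <- f$varietyEffects[sort(names(g))[-1]]
    tru <- g[sort(names(g))[-1]] - g[[ref]]
    mean(est - tru)
  })
  expect_lt(abs(mean(unlist(ests))), 0.05)
})

test_that("spatial fitting validates its inputs", {
  bad <- data.frame(row = 1:10, column = 1, variety = "v1",
                    value = rnorm(10))
  expect_error(fitSpatialSurface(bad), "two varieties")
  tiny <- data.frame(row = rep(1:2, 2), column = rep(1:2, each = 2),
                     variety = c("a", "b", "a", "b"), value = rnorm(4))
  expect_error(fitSpatialSurface(tiny), "basis")
})

test_that("environment scaling yields unit-sd columns", {
  ft <- generateFieldTrial(fieldTrialPlan(nEnvs = 3), seed = 5)
  ct <- correctTrial(ft$plots)
  m <- scaleByEnvironment(ct)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(dim(m), c(45L, 3L))
  # already-unit-sd column is unchanged
  m2 <- scaleByEnvironment(data.frame(env = "e1",
                                      variety = rownames(m),
                                      value = m[, 1]),
                           valueColumn = "value")
  expect_equal(unname(m2[, 1]), unname(m[, 1]), tolerance = 1e-12)
  # zero-variance environment is an error
  zero <- data.frame(env = "e", variety = c("a", "b"), value = c(1, 1))
  expect_error(scaleByEnvironment(zero, valueColumn = "value"),
               "zero variance")
})

test_that("GGE decomposition reconstructs and apportions inertia", {
  # rank-1 pattern: pure genotype effect
  m <- cbind(e1 = c(1, 2, 3, 4), e2 = c(2, 3, 4, 5))
  rownames(m) <- paste0("g", 1:4)
  g <- ggeDecompose(m, nAxes = 1)
  expect_equal(varianceExplained(g)[1], 100)
  expect_equal(sum(varianceExplained(g)), 100)

  set.seed(42)
  m3 <- matrix(rnorm(9), 3, dimnames = list(paste0("g", 1:3),
                                            paste0("e", 1:3)))
  g3 <- ggeDecompose(m3, nAxes = 2)
  recon <- genotypeScores(g3) %*% t(environmentLoadings(g3))
  centered <- sweep(m3, 2, colMeans(m3))
  expect_lt(max(abs(recon - centered)), 1e-10)
  expect_equal(sum(varianceExplained(g3)), 100, tolerance = 1e-9)
  # axes orthogonal
  cross <- crossprod(genotypeScores(g3)[, 1], genotypeScores(g3)[, 2])
  expect_lt(abs(cross), 1e-8)
  # relabeling genotypes leaves variance explained unchanged
  perm <- c(3, 1, 2)
  gp <- ggeDecompose(m3[perm, ])
  expect_equal(varianceExplained(gp), varianceExplained(g3))
  expect_warning(ggeDecompose(m, nAxes = 5), "truncated")
})

test_that("GGE axis 1 recovers planted genotype ordering", {
  ft <- generateFieldTrial(fieldTrialPlan(gSd = 0.6, gxeSd = 0.1), seed = 3)
  ct <- correctTrial(ft$plots)
  g <- ggeDecompose(scaleByEnvironment(ct))
  ax1 <- genotypeScores(g)[, 1]
  tru <- ft$truth$G[names(ax1)]
  expect_gt(abs(cor(ax1, tru, method = "spearman")), 0.95)
})

test_that("ideal-cultivar ranking prefers low stable genotypes", {
  # construction: g1 constantly lowest, g5 low mean but unstable
  m <- rbind(g1 = c(1, 1, 1, 1),
             g2 = c(3, 3, 3, 3),
             g3 = c(4, 4, 4, 4),
             g4 = c(5, 5, 5, 5),
             g5 = c(0.5, 3.5, 0.5, 3.5))
  colnames(m) <- paste0("e", 1:4)
  g <- ggeDecompose(m)
  rk <- rankIdealCultivars(g, direction = "low")
  expect_equal(rk$genotype[1], "g1")
  # equal-level pair: stability breaks the tie
  m2 <- rbind(gA = c(-1, -1), gB = c(-2, 0), gC = c(1, 1), gD = c(2, 0))
  colnames(m2) <- c("e1", "e2")
  g2 <- ggeDecompose(m2)
  rk2 <- rankIdealCultivars(g2, direction = "low")
  lv <- setNames(rk2$level, rk2$genotype)
  expect_equal(unname(lv["gA"]), unname(lv["gB"]), tolerance = 1e-9)
  expect_lt(which(rk2$genotype == "gA"), which(rk2$genotype == "gB"))
  # high direction reverses the ends
  expect_equal(rankIdealCultivars(g, direction = "high")$genotype[1], "g4")
})

test_that("a single environment ranks by level with zero instability", {
  m <- matrix(c(3, 1, 2), ncol = 1,
              dimnames = list(c("a", "b", "c"), "e1"))
  g <- ggeDecompose(m, nAxes = 1)
  rk <- rankIdealCultivars(g, nAxes = 1)
  expect_equal(rk$instability, rep(0, 3), tolerance = 1e-9)
  expect_equal(rk$genotype, c("b", "c", "a"))
})

test_that("variety contrasts report Welch p, CIs and relative decrease", {
  expect_equal(relativeDecrease(2.5, 2.9), 100 * (1 - 2.5 / 2.9))
  expect_error(relativeDecrease(1, 0), "undefined")
  set.seed(9)
  a <- rnorm(6, 2.0, 0.3)
  b <- rnorm(6, 3.0, 0.5)
  vc <- varietyContrast(a, b)
  expect_equal(vc$pValue, t.test(a, b)$p.value)
  expect_true(vc$ciA[["lower"]] <= vc$meanA &&
                vc$meanA <= vc$ciA[["upper"]])
  expect_equal(vc$relativeDecrease, 100 * (1 - mean(a) / mean(b)))
  # identical groups
  same <- varietyContrast(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$pValue, 1)
  expect_equal(same$relativeDecrease, 0)
})

test_that("relative decrease is antisymmetric under group swap", {
  set.seed(10)
  for (i in 1:10) {
    a <- runif(1, 0.5, 5)
    b <- runif(1, 0.5, 5)
    d <- relativeDecrease(a, b)
    dSwap <- relativeDecrease(b, a)
    expect_equal(dSwap, 100 * (1 - 1 / (1 - d / 100)), tolerance = 1e-9)
  }
})
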