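test_that("stacked-pair fixtures hit the requested separation", {
  p <- genStackedPairPDB(3.4, nFrames = 3, seed = 1)
  traj <- readMultiModelPDB(p)
  d <- stackingDistance(traj, "M", 1, "M", 2)
  expect_equal(d, rep(3.4, 3), tolerance = 1e-6)
  p2 <- genStackedPairPDB(5.0, nFrames = 2, seed = 1)
  d2 <- stackingDistance(readMultiModelPDB(p2), "M", 1, "M", 2)
  expect_equal(classifyStacked(d2), c(0L, 0L))
  # jittered distances concentrate on the target
  p3 <- genStackedPairPDB(3.4, nFrames = 2000, jitterSD = 0.1, seed = 2)
  d3 <- stackingDistance(readMultiModelPDB(p3), "M", 1, "M", 2)
  expect_equal(mean(d3), 3.4, tolerance = 0.02)
})

test_that("hbond fixtures place the triad at the exact geometry", {
  for (cs in list(c(3.4, 170, 1), c(3.6, 170, 0), c(3.4, 134, 0))) {
    p <- genHbondPDB(cs[1], cs[2], nFrames = 1)
    traj <- readMultiModelPDB(p)
    expect_equal(detectHbond(traj, triadSpec), as.integer(cs[3]),
                 info = paste(cs, collapse = "/"))
    xyz <- traj@coords[, , 1]
    expect_equal(sqrt(sum((xyz[1, ] - xyz[3, ])^2)), cs[1], tolerance = 1e-3)
    expect_equal(dhaAngle(xyz[1, ], xyz[2, ], xyz[3, ]), cs[2],
                 tolerance = 0.1)
  }
})

test_that("coupled binaries honor marginals and exact pairwise joints", {
  X <- genCoupledBinaries(20000, c(u = 0.5, v = 0.5, w = 0.2),
                          data.frame(a = "u", b = "v", phi = 0),
                          seed = 1)
  expect_equal(mean(X[, "u"] & X[, "v"]), 0.25, tolerance = 0.01)
  expect_equal(colMeans(X), c(u = 0.5, v = 0.5, w = 0.2), tolerance = 0.015)
  # bit-reproducible under a fixed seed
  X2 <- genCoupledBinaries(20000, c(u = 0.5, v = 0.5, w = 0.2),
                           data.frame(a = "u", b = "v", phi = 0), seed = 1)
  expect_identical(X, X2)
})

test_that("infeasible couplings are rejected with the Frechet interval", {
  expect_equal(phiFeasibleInterval(0.9, 0.1)[["max"]], 1 / 9,
               tolerance = 1e-12)
  err <- tryCatch(
    genCoupledBinaries(100, c(a = 0.9, b = 0.1),
                       data.frame(a = "a", b = "b", phi = 0.5)),
    error = conditionMessage)
  expect_match(err, "infeasible")
  expect_match(err, "0.1111")
  expect_error(
    genCoupledBinaries(100, c(a = 0.5, b = 0.5, c = 0.5),
                       data.frame(a = c("a", "a"), b = c("b", "c"),
                                  phi = c(0.2, 0.2))),
    "at most one")
})

test_that("generator and phi estimator round-trip", {
  X <- genCoupledBinaries(20000, c(a = 0.5, b = 0.5),
                          data.frame(a = "a", b = "b", phi = 0.5), seed = 3)
  expect_equal(phiCoefficient(X[, "a"], X[, "b"]), 0.5, tolerance = 0.05)
})

test_that("factorial datasets carry the injected ground truth", {
  des <- studyDesign(replicates = 30)
  d0 <- genFactorialDataset(des, noise = "lognormal", sigma = 1, seed = 1)
  expect_equal(nrow(d0), 720)
  expect_equal(attr(d0, "groundTruth")$noise, "lognormal")
  d1 <- genFactorialDataset(des, mainEffects = list(
    wobble = c(GU_wobble = 3)), noise = "normal", sigma = 0.1, seed = 1)
  gap <- diff(tapply(d1$response, d1$wobble, mean))
  expect_equal(abs(unname(gap)), 3, tolerance = 0.05)
  i2 <- list("wobble:plus1_codon" = matrix(
    c(2, 0, 0, 0), 2, 2,
    dimnames = list(c("GU_wobble", "GC_watson_crick"), c("GCU", "CGU"))))
  d2 <- genFactorialDataset(des, interactions = i2, noise = "normal",
                            sigma = 0.1, seed = 2)
  cellMeans <- tapply(d2$response,
                      interaction(d2$wobble, d2$plus1_codon), mean)
  expect_equal(unname(cellMeans[["GU_wobble.GCU"]]), 2, tolerance = 0.1)
  expect_equal(unname(cellMeans[["GC_watson_crick.CGU"]]), 0,
               tolerance = 0.1)
})

test_that("lognormal replicate noise defeats classical-ANOVA normality", {
  des <- studyDesign(replicates = 30)
  fails <- vapply(1:100, function(s) {
    d <- genFactorialDataset(des, noise = "lognormal", sigma = 1, seed = s)
    fit <- aov(response ~ a_site_n1n2 * wobble * plus1_codon, data = d)
    shapiroWilk(sample(residuals(fit), 500))$p < 0.05
  }, TRUE)
  expect_gte(mean(fails), 0.9)
})

test_that("neighborhood occupancy plans are recovered from the geometry", {
  occ <- setNames(rep(0.5, 26), letters[1:26])
  occ["g"] <- 0.3
  traj <- genNeighborhoodTrajectory(defaultCondition, occ, nFrames = 5000,
                                    seed = 6)
  g <- meanInteraction(binarizeSeries(evaluateContact(
    traj, defaultCatalogue()[["g"]])))
  expect_lt(abs(g - 0.3), 0.03)
})

test_that("an all-on plan yields an all-ones binarized fingerprint", {
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 1,
                                    nFrames = 10, seed = 1)
  bins <- vapply(defaultCatalogue()@contacts, function(ct)
    meanInteraction(binarizeSeries(evaluateContact(traj, ct))), 1)
  expect_equal(unname(bins), rep(1, 26))
})

test_that("contacts driven by one latent switch are phi-coupled", {
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 0.5,
                                    nFrames = 2000, seed = 2,
                                    couple = list(c("g", "t")))
  bg <- binarizeSeries(evaluateContact(traj, defaultCatalogue()[["g"]]))
  bt <- binarizeSeries(evaluateContact(traj, defaultCatalogue()[["t"]]))
  expect_gt(phiCoefficient(bg@values, bt@values), 0.95)
})

test_that("trajectory generation is bit-reproducible under a fixed seed", {
  t1 <- genNeighborhoodTrajectory(defaultCondition, 0.5, nFrames = 20,
                                  seed = 9)
  t2 <- genNeighborhoodTrajectory(defaultCondition, 0.5, nFrames = 20,
                                  seed = 9)
  expect_identical(t1@coords, t2@coords)
  t3 <- genNeighborhoodTrajectory(defaultCondition, 0.5, nFrames = 20,
                                  seed = 10)
  expect_false(identical(t1@coords, t3@coords))
})

test_that("every study condition generates and evaluates cleanly", {
  des <- unique(studyDesign(1)[, 1:3])
  cat26 <- defaultCatalogue()
  for (i in seq_len(nrow(des))) {
    traj <- genNeighborhoodTrajectory(as.list(des[i, ]), 0.5, nFrames = 30,
                                      seed = i)
    vals <- vapply(cat26@contacts, function(ct)
      meanInteraction(binarizeSeries(evaluateContact(traj, ct))), 1)
    expect_true(all(is.finite(vals)), info = paste(des[i, ], collapse = "/"))
  }
})
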