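test_that("equilibration trimming follows both published policies", {
  s <- interactionSeries("g", "stack", rnorm(12000, 4, 0.2))
  t1 <- trimEquilibration(s, dropFirstN = 2000)
  expect_equal(length(t1), 10000)
  expect_true(t1@trimmed)
  s2 <- interactionSeries("g", "stack", seq_len(60))
  t2 <- trimEquilibration(s2, keepFinalFraction = 2 / 3)
  expect_equal(t2@values, as.numeric(21:60))  # final 40 of 60 retained
  expect_equal(trimEquilibration(s2, dropFirstN = 0)@values, s2@values)
  expect_error(trimEquilibration(s2, dropFirstN = 60), "argument error")
  expect_error(trimEquilibration(s2), "argument error")
  expect_error(trimEquilibration(s2, dropFirstN = 1,
                                 keepFinalFraction = 0.5), "argument error")
})

test_that("trimming then averaging matches a hand-indexed oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    v <- rnorm(n)
    s <- interactionSeries("x", "stack", v)
    k <- sample.int(n - 1, 1)
    expect_equal(meanInteraction(trimEquilibration(s, dropFirstN = k)),
                 mean(v[(k + 1):n]))
    f <- runif(1, 0.1, 1)
    kept <- floor(n * f)
    expect_equal(
      meanInteraction(trimEquilibration(s, keepFinalFraction = f)),
      mean(v[(n - kept + 1):n]))
  }
})

test_that("contact evaluation yields per-frame series of the right kind", {
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 1,
                                    nFrames = 5, seed = 2)
  cat26 <- defaultCatalogue()
  sG <- evaluateContact(traj, cat26[["g"]])
  expect_s4_class(sG, "InteractionSeries")
  expect_equal(length(sG), 5)
  expect_equal(sG@values, rep(3.4, 5), tolerance = 1e-9)  # constant geometry
  sT <- evaluateContact(traj, cat26[["t"]])
  expect_true(all(sT@values >= 1))  # hbond count, always formed
  bad <- contactDef("zz", "stack", list(chain = "Z", resno = 9),
                    list(chain = "M", resno = 1), "A_site")
  expect_error(evaluateContact(traj, bad), "contact 'zz'")
})

test_that("an hbond contact toggling mid-trajectory gives the frame pattern", {
  # frames 2-4 of 5 satisfied, via per-frame triad geometry
  frames <- lapply(c(90, 180, 180, 170, 60),
                   function(a) triadCoords(3.0, a))
  traj <- makeTraj(triadAtoms, frames)
  ct <- contactDef("hb", "hbond", list(chain = "M", resno = 1),
                   list(chain = "M", resno = 2), "A_site",
                   candidates = list(triadSpec))
  s <- evaluateContact(traj, ct)
  oracle <- vapply(seq_len(5), function(i)
    detectHbond(traj, triadSpec, frames = i), 1L)
  expect_equal(s@values, c(0, 1, 1, 1, 0))
  expect_equal(s@values, as.numeric(oracle))
})

test_that("series means and binarization behave as documented", {
  s <- interactionSeries("x", "binary", c(0, 1, 1, 1, 0), trimmed = TRUE)
  expect_equal(meanInteraction(s), 0.6)
  expect_equal(meanInteraction(interactionSeries("x", "stack", rep(3.9, 4))),
               3.9)
  expect_equal(meanInteraction(interactionSeries("x", "binary",
                                                 rep(0, 4))), 0)
  expect_error(meanInteraction(interactionSeries("x", "stack", numeric())),
               "argument error")
  b <- binarizeSeries(interactionSeries("x", "stack", c(4.4, 4.6, 3.0),
                                        trimmed = TRUE))
  expect_equal(b@values, c(1, 0, 1))
  expect_equal(b@kind, "binary")
  bh <- binarizeSeries(interactionSeries("x", "hbond", c(0, 2, 1)))
  expect_equal(bh@values, c(0, 1, 1))
  expect_equal(binarizeSeries(interactionSeries("x", "binary",
                                                rep(0, 3)))@values, rep(0, 3))
})

test_that("binarized means are occupancies in [0, 1]", {
  set.seed(9)
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 0.4,
                                    nFrames = 300, seed = 9)
  for (lab in c("a", "g", "t", "z")) {
    m <- meanInteraction(binarizeSeries(evaluateContact(
      traj, defaultCatalogue()[[lab]])))
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("site H-bond strength reduces per nucleotide then per site", {
  cat26 <- defaultCatalogue()
  trajOn <- genNeighborhoodTrajectory(defaultCondition, occupancy = 1,
                                      nFrames = 20, seed = 4)
  # every contact always formed -> frequency reduction is exactly 1
  expect_equal(siteHbondStrength(trajOn, "A_site", cat26), 1)
  expect_equal(siteHbondStrength(trajOn, "CAR_site", cat26), 1)
  # count reduction equals the mean per-nucleotide total candidate count
  tab <- catalogueTable(cat26)
  cnt <- siteHbondStrength(trajOn, "CAR_site", cat26, reduction = "count")
  perNt <- vapply(paste0("M", 4:6), function(g) {
    cts <- cat26@contacts[tab$kind == "hbond" & tab$group == g]
    sum(vapply(cts, function(ct)
      meanInteraction(evaluateContact(trajOn, ct)), 1))
  }, 1)
  expect_equal(cnt, mean(perNt))

  # linearity: halving every occupancy halves the frequency strength
  trajHalf <- genNeighborhoodTrajectory(defaultCondition, occupancy = 0.5,
                                        nFrames = 4000, seed = 8)
  expect_equal(siteHbondStrength(trajHalf, "CAR_site", cat26), 0.5,
               tolerance = 0.05)

  # never formed -> 0; catalogue without grouped hbonds -> config error
  trajOff <- genNeighborhoodTrajectory(defaultCondition, occupancy = 0.001,
                                       nFrames = 10, seed = 4)
  expect_lte(siteHbondStrength(trajOff, "A_site", cat26), 0.1)
  stacksOnly <- contactCatalogue(cat26@contacts[1:10])
  expect_error(siteHbondStrength(trajOn, "A_site", stacksOnly),
               "configuration error")
})

test_that("site strength is invariant to contact order within the site", {
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 0.6,
                                    nFrames = 100, seed = 12)
  cat26 <- defaultCatalogue()
  set.seed(21)
  shuffled <- contactCatalogue(cat26@contacts[c(1:10, sample(11:26))])
  expect_equal(siteHbondStrength(traj, "CAR_site", cat26),
               siteHbondStrength(traj, "CAR_site", shuffled))
})

test_that("the study design is the full 24 x 30 factorial", {
  d <- studyDesign()
  expect_equal(nrow(d), 720)
  expect_equal(nrow(unique(d[c("a_site_n1n2", "wobble", "plus1_codon")])), 24)
  expect_equal(length(unique(d$simulation_id)), 720)
  expect_equal(nrow(studyDesign(replicates = 3)), 72)
})

test_that("fingerprints assemble one vector per simulation", {
  des <- studyDesign(replicates = 3)
  des <- des[des$a_site_n1n2 %in% c("UG", "UA") &
               des$wobble == "GU_wobble" & des$plus1_codon == "GCU", ]
  sims <- lapply(seq_len(nrow(des)), function(i) list(
    traj = genNeighborhoodTrajectory(
      as.list(des[i, 1:3]), occupancy = 0.5, nFrames = 40, seed = 100 + i),
    condition = as.list(des[i, c(1:4)])))
  names(sims) <- des$simulation_id
  se <- buildFingerprints(sims, trim = list(dropFirstN = 10))
  expect_equal(dim(se), c(26, 6))
  expect_equal(rownames(se), letters[1:26])
  expect_true(all(is.finite(SummarizedExperiment::assay(se, "mean"))))
  tab <- fingerprintTable(se)
  expect_equal(nrow(tab), 26 * 6)
  expect_true(all(c("simulation_id", "a_site_n1n2", "wobble", "plus1_codon",
                    "replicate", "contact", "mean_value") %in% names(tab)))
})

test_that("a constant trajectory's fingerprint equals one frame's values", {
  traj <- genNeighborhoodTrajectory(defaultCondition, occupancy = 1,
                                    nFrames = 6, seed = 3)
  sims <- list(s1 = list(traj = traj, condition = list(replicate = 1)))
  se <- buildFingerprints(sims)
  one <- vapply(defaultCatalogue()@contacts, function(ct)
    evaluateContact(traj, ct)@values[1], 1)
  expect_equal(unname(SummarizedExperiment::assay(se, "mean")[, 1]), one,
               tolerance = 1e-9)
})

test_that("variance scaling flags zero-variance contacts", {
  m <- matrix(rnorm(26 * 4), 26, 4, dimnames = list(letters[1:26], NULL))
  m[3, ] <- 7  # constant contact
  colnames(m) <- paste0("s", 1:4)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(mean = m),
    rowData = S4Vectors::DataFrame(catalogueTable(defaultCatalogue())),
    colData = S4Vectors::DataFrame(replicate = 1:4))
  sc <- scaleFingerprints(se)
  expect_false(SummarizedExperiment::rowData(sc)$scaled[3])
  expect_equal(SummarizedExperiment::assay(sc, "scaled")[3, ],
               SummarizedExperiment::assay(sc, "mean")[3, ])
  sds <- apply(SummarizedExperiment::assay(sc, "scaled")[-3, ], 1, sd)
  expect_equal(unname(sds), rep(1, 25))
})
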