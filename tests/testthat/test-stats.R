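test_that("Shapiro-Wilk wrapper screens normality and rejects bad input", {
  set.seed(1)
  hits <- vapply(1:100, function(i) shapiroWilk(rnorm(500))$p > 0.05, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_lt(shapiroWilk(rexp(500)^2)$p, 0.05)
  expect_error(shapiroWilk(rnorm(2)), "argument error")
  expect_error(shapiroWilk(rep(1, 10)), "degenerate")
})

test_that("Bonferroni correction scales and clips", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  p <- runif(7)
  expect_equal(bonferroni(p, m = 1), p)
  expect_true(all(bonferroni(p) >= p))       # never decreases
  expect_true(all(bonferroni(p, 100) <= 1))  # clipped
})

test_that("ART alignment strips all effects but the target", {
  des <- studyDesign(replicates = 4)
  fac <- c("a_site_n1n2", "wobble", "plus1_codon")
  # zero noise, pure wobble effect
  d <- des
  d$response <- ifelse(d$wobble == "GU_wobble", 2, 0)
  aw <- artAlign(d, "response", fac, "wobble")
  # aligned = centered wobble effect pattern, reproduced exactly
  expect_equal(aw, d$response - mean(d$response), tolerance = 1e-12)
  # aligning for a different effect strips the wobble pattern entirely
  ap <- artAlign(d, "response", fac, "plus1_codon")
  expect_equal(ap, rep(0, nrow(d)), tolerance = 1e-12)
  ai <- artAlign(d, "response", fac, "a_site_n1n2:plus1_codon")
  expect_equal(ai, rep(0, nrow(d)), tolerance = 1e-12)
})

test_that("alignment matches a directly coded ART oracle on a 2x2x2 toy", {
  set.seed(3)
  toy <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                     C = c("c1", "c2"), rep = 1:5,
                     stringsAsFactors = FALSE)
  toy$response <- rnorm(nrow(toy))
  # independent oracle: explicit cell-mean arithmetic
  cell <- interaction(toy$A, toy$B, toy$C)
  resid <- toy$response - ave(toy$response, cell)
  mu <- mean(tapply(toy$response, cell, mean))
  mA <- tapply(tapply(toy$response, cell, mean),
               sub("\\..*", "", levels(cell)), mean)
  oracleA <- resid + mA[toy$A] - mu
  got <- artAlign(toy, "response", c("A", "B", "C"), "A")
  expect_equal(unname(got), as.numeric(oracleA), tolerance = 1e-12)
  # estimation identity: on a balanced design both the residuals and the
  # effect estimates sum to zero, so every aligned response sums to zero
  for (eff in c("A", "B", "C", "A:B", "B:C", "A:C"))
    expect_equal(sum(artAlign(toy, "response", c("A", "B", "C"), eff)), 0,
                 tolerance = 1e-9)
})

test_that("the factorial ANOVA on ranks matches aov on balanced designs", {
  set.seed(8)
  des <- studyDesign(replicates = 6)
  d <- genFactorialDataset(des, noise = "lognormal", sigma = 1, seed = 8)
  fl <- lapply(d[c("a_site_n1n2", "wobble", "plus1_codon")], factor)
  y <- rank(d$response)
  ours <- decodex:::.factorialAnova(y, fl)
  ref <- summary(aov(y ~ a_site_n1n2 * wobble * plus1_codon,
                     data = cbind(data.frame(y = y), d[names(fl)])))[[1]]
  refF <- ref[["F value"]][seq_len(nrow(ours))]
  expect_equal(ours$F, refF, tolerance = 1e-10)
  expect_equal(ours$p, ref[["Pr(>F)"]][seq_len(nrow(ours))],
               tolerance = 1e-10)
})

test_that("ART-ANOVA invariances hold", {
  des <- studyDesign(replicates = 5)
  fac <- c("a_site_n1n2", "wobble", "plus1_codon")
  d <- genFactorialDataset(des, mainEffects = list(
    wobble = c(GU_wobble = 1)), noise = "lognormal", seed = 2)
  base <- artAnova(d, "response", fac)
  # permuting replicates within cells leaves every F unchanged
  set.seed(4)
  cell <- interaction(d[fac])
  perm <- d[order(cell), ]
  perm$response <- unlist(lapply(split(d$response, cell), sample),
                          use.names = FALSE)
  permuted <- artAnova(perm, "response", fac)
  expect_equal(sort(permuted$F), sort(base$F), tolerance = 1e-9)
  # affine transformation of the response leaves rank-based F unchanged
  d2 <- d; d2$response <- 5 * d$response + 11
  expect_equal(artAnova(d2, "response", fac)$F, base$F, tolerance = 1e-9)
  # Bonferroni column is min(1, 6p) for the 6-effect family
  expect_equal(base$p_bonferroni, pmin(1, 6 * base$p))
})

test_that("ART reduces to rank ANOVA for a single-factor design", {
  set.seed(6)
  d <- data.frame(g = rep(c("x", "y", "z"), each = 10),
                  replicate = rep(1:10, 3))
  d$response <- rnorm(30) + ifelse(d$g == "z", 1, 0)
  ours <- artAnova(d, "response", "g")
  r <- rank(d$response)
  ref <- summary(aov(r ~ g, data = d))[[1]]
  expect_equal(ours$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(ours$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("unbalanced designs are accepted and empty cells rejected", {
  des <- studyDesign(replicates = 3)
  d <- genFactorialDataset(des, noise = "normal", seed = 5)
  d <- d[-c(1, 2, 40), ]  # unbalance a few cells
  out <- artAnova(d, "response", c("a_site_n1n2", "wobble", "plus1_codon"),
                  effects = "wobble")
  expect_true(is.finite(out$F) && out$p >= 0 && out$p <= 1)
  dEmpty <- d[!(d$a_site_n1n2 == "AG" & d$wobble == "GU_wobble" &
                  d$plus1_codon == "GCU"), ]
  expect_error(artAnova(dEmpty, "response",
                        c("a_site_n1n2", "wobble", "plus1_codon")),
               "design error")
})

test_that("phi equals the 2x2 closed form and Pearson r", {
  expect_equal(phiCoefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(phiCoefficient(x, y), 0.6)
  expect_equal(phiCoefficient(x, y), cor(x, y), tolerance = 1e-12)
  expect_error(phiCoefficient(c(1, 1, 1), c(1, 0, 1)), "undefined")
  set.seed(10)
  z <- rbinom(20000, 1, 0.5)
  expect_lt(abs(phiCoefficient(z, rbinom(20000, 1, 0.5))), 0.03)
})

test_that("the covariation matrix is symmetric with unit diagonal", {
  set.seed(2)
  runs <- lapply(1:3, function(i) {
    m <- matrix(rbinom(5 * 200, 1, 0.5), 200, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
    m[, 2] <- m[, 1]       # duplicated contact
    m[, 5] <- 0            # constant contact
    m
  })
  phi <- covariationMatrix(runs)
  expect_equal(dim(phi), c(5, 5))
  expect_equal(phi, t(phi))
  expect_equal(phi["c1", "c2"], 1)
  expect_true(all(is.na(phi["c5", ])))
  expect_equal(attr(phi, "undefined"), "c5")
  expect_equal(unname(diag(phi)[1:4]), rep(1, 4))
  expect_true(all(abs(phi[!is.na(phi)]) <= 1))
  perRun <- covariationMatrix(runs, pooling = "per_run_mean")
  expect_equal(perRun["c1", "c2"], 1)
  expect_equal(perRun, t(perRun))
})

test_that("stratified site correlation reports r, p and Bonferroni", {
  x <- rnorm(30)
  tab <- siteCorrelation(x, -x, rep("all", 30))
  expect_equal(tab$r, -1)
  set.seed(13)
  a <- rnorm(60); b <- rnorm(60)
  strata <- rep(c("s1", "s2"), each = 30)
  tab2 <- siteCorrelation(a, b, strata)
  expect_equal(nrow(tab2), 2)
  expect_true(all(abs(tab2$r) < 0.5))
  expect_equal(tab2$p_bonferroni, pmin(1, 2 * tab2$p))
  # near-deterministic positive association
  y <- a + rnorm(60, 0, 1e-6)
  expect_gt(min(siteCorrelation(a, y, strata)$r), 0.999)
  expect_warning(siteCorrelation(a, b, c(rep("s1", 58), "tiny", "tiny")),
                 "skipped")
})
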