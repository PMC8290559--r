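test_that("Wald ratios follow their definitions", {
  h <- makeHarmonized(bx = 0.2, by = 0.1, sy = 0.01)
  # single-SNP frame needs >= 1 record only for ratio computation
  r <- waldRatios(makeHarmonized(c(0.2, -0.2), c(0.1, -0.1), c(0.01, 0.01)))
  expect_equal(r$theta, c(0.5, 0.5))
  expect_equal(r$se, c(0.05, 0.05))
  expect_equal(r$w, c(400, 400))
  set.seed(12)
  h2 <- makeHarmonized(rnorm(10, 0.1, 0.03), rnorm(10, 0.05, 0.03),
                       runif(10, 0.005, 0.02))
  r2 <- waldRatios(h2)
  expect_equal(r2$w, 1 / r2$se^2, tolerance = 1e-12)
  hz <- makeHarmonized(c(0.1, 0), c(0.1, 0.1), c(0.01, 0.01))
  expect_error(waldRatios(hz), "s002")
})

test_that("IVW reproduces the proportional toy exactly", {
  iv <- mrIVW(proportionalToy())
  expect_equal(betaHat(iv$estimate), 0.5, tolerance = 1e-12)
  expect_equal(stdErr(iv$estimate), 1 / sqrt(1400), tolerance = 1e-9)
  expect_equal(iv$heterogeneity@qStat, 0, tolerance = 1e-20)
  expect_equal(pValue(iv$heterogeneity), 1)
  expect_error(mrIVW(makeHarmonized(0.1, 0.1, 0.01)), "at least 2")
})

test_that("IVW equals the weighted-regression-through-origin closed form", {
  set.seed(42)
  for (i in 1:100) {
    J <- sample(3:50, 1)
    bx <- rnorm(J, 0.05, 0.05); bx[abs(bx) < 1e-3] <- 0.01
    by <- rnorm(J, 0.02, 0.03)
    sy <- runif(J, 0.005, 0.03)
    h <- makeHarmonized(bx, by, sy)
    expect_equal(betaHat(mrIVW(h)$estimate), wlsOriginOracle(bx, by, sy),
                 tolerance = 1e-10)
  }
})

test_that("IVW is sign-equivariant in the exposure orientation", {
  set.seed(5)
  bx <- rnorm(8, 0.05, 0.03); by <- rnorm(8, 0.02, 0.02)
  sy <- runif(8, 0.005, 0.02)
  a <- mrIVW(makeHarmonized(bx, by, sy))
  b <- mrIVW(makeHarmonized(-bx, by, sy))
  expect_equal(betaHat(b$estimate), -betaHat(a$estimate), tolerance = 1e-12)
  expect_equal(stdErr(b$estimate), stdErr(a$estimate), tolerance = 1e-12)
})

test_that("Cochran's Q matches hand computation and scales as 1/c^2", {
  r <- data.frame(snp_id = c("a", "b"), theta = c(0.4, 0.6),
                  se = c(0.1, 0.1), w = c(100, 100))
  q <- cochranQ(r, 0.5)
  expect_equal(q@qStat, 2.0, tolerance = 1e-12)
  expect_equal(q@pval, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-9)
  # identical ratios: Q = 0, p = 1
  r0 <- data.frame(snp_id = c("a", "b"), theta = c(0.5, 0.5),
                   se = c(0.1, 0.2), w = c(100, 25))
  expect_equal(cochranQ(r0, 0.5)@qStat, 0)
  expect_equal(cochranQ(r0, 0.5)@pval, 1)
  # rescaling all SEs by c rescales Q by 1/c^2
  rc <- r; rc$se <- r$se * 2; rc$w <- 1 / rc$se^2
  expect_equal(cochranQ(rc, 0.5)@qStat, q@qStat / 4, tolerance = 1e-12)
})

test_that("Egger recovers exact proportional and affine data", {
  eg0 <- mrEgger(proportionalToy())
  expect_equal(betaHat(eg0$slope), 0.5, tolerance = 1e-10)
  expect_equal(betaHat(eg0$intercept), 0, tolerance = 1e-10)
  eg <- mrEgger(affineToy())
  expect_equal(betaHat(eg$slope), 0.5, tolerance = 1e-10)
  expect_equal(betaHat(eg$intercept), 0.02, tolerance = 1e-10)
  expect_error(mrEgger(makeHarmonized(c(0.1, 0.2), c(0.1, 0.1),
                                      c(0.01, 0.01))), "at least 3")
  expect_error(mrEgger(makeHarmonized(c(0.1, 0.1, -0.1),
                                      c(0.1, 0.2, 0.1), rep(0.01, 3))),
               "collinear")
})

test_that("Egger matches the weighted-regression closed form", {
  set.seed(7)
  for (i in 1:50) {
    J <- sample(4:30, 1)
    bx <- rnorm(J, 0.08, 0.05)
    by <- rnorm(J, 0.03, 0.03)
    sy <- runif(J, 0.005, 0.03)
    h <- makeHarmonized(bx, by, sy)
    flip <- bx < 0
    fit <- lm(ifelse(flip, -by, by) ~ abs(bx), weights = 1 / sy^2)
    eg <- mrEgger(h)
    expect_equal(betaHat(eg$slope), unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(betaHat(eg$intercept), unname(coef(fit)[1]),
                 tolerance = 1e-10)
  }
})

test_that("the weighted median interpolates cumulative weight midpoints", {
  # oracle: brute-force interpolation of theta against S_j - w'_j/2
  wmOracle <- function(theta, w) {
    o <- order(theta); theta <- theta[o]; w <- w[o] / sum(w)
    p <- cumsum(w) - w / 2
    approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
  }
  # thetas (0.1, 0.5, 0.9), normalized weights (0.2, 0.6, 0.2) -> 0.5
  h <- makeHarmonized(bx = c(1, 1, 1) * 0.1,
                      by = c(0.01, 0.05, 0.09),
                      sy = 0.1 * c(1 / sqrt(0.2), 1 / sqrt(0.6), 1 / sqrt(0.2)) * 0.1)
  wm <- mrWeightedMedian(h, nBoot = 50, seed = 1)
  r <- waldRatios(h)
  expect_equal(r$theta, c(0.1, 0.5, 0.9), tolerance = 1e-12)
  expect_equal(r$w / sum(r$w), c(0.2, 0.6, 0.2), tolerance = 1e-12)
  expect_equal(betaHat(wm), 0.5, tolerance = 1e-12)
  expect_equal(betaHat(wm), wmOracle(r$theta, r$w), tolerance = 1e-12)
  # all ratios equal c: estimate c regardless of weights
  he <- makeHarmonized(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12),
                       c(0.01, 0.03, 0.02))
  expect_equal(betaHat(mrWeightedMedian(he, 50, seed = 2)), 0.3,
               tolerance = 1e-12)
})

test_that("weighted-median bootstrap is reproducible with a fixed seed", {
  set.seed(3)
  h <- makeHarmonized(rnorm(8, 0.1, 0.02), rnorm(8, 0.05, 0.02),
                      runif(8, 0.005, 0.02))
  a <- mrWeightedMedian(h, 300, seed = 11)
  b <- mrWeightedMedian(h, 300, seed = 11)
  expect_identical(stdErr(a), stdErr(b))
  expect_error(mrWeightedMedian(h, 300), "seed")
})

test_that("multivariable MR recovers exact constructions and the oracle", {
  set.seed(21)
  J <- 20
  b1 <- rnorm(J, 0.1, 0.04); b2 <- rnorm(J, 0, 0.05)
  sy <- runif(J, 0.005, 0.02)
  by <- 0.5 * b1
  est <- mrMVMR(cbind(x1 = b1, x2 = b2), by, sy)
  expect_equal(betaHat(est$x1), 0.5, tolerance = 1e-10)
  expect_equal(betaHat(est$x2), 0, tolerance = 1e-10)
  # random instances against lm with no intercept
  for (i in 1:50) {
    K <- sample(2:4, 1); Ji <- K + sample(5:30, 1)
    X <- matrix(rnorm(Ji * K, 0.05, 0.05), Ji, K,
                dimnames = list(NULL, paste0("e", 1:K)))
    y <- rnorm(Ji, 0.02, 0.05); syi <- runif(Ji, 0.005, 0.03)
    fit <- lm(y ~ X - 1, weights = 1 / syi^2)
    got <- vapply(mrMVMR(X, y, syi), betaHat, numeric(1))
    expect_equal(unname(got), unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("single-exposure MVMR nests the IVW point estimate", {
  set.seed(15)
  bx <- rnorm(10, 0.1, 0.03); by <- rnorm(10, 0.05, 0.02)
  sy <- runif(10, 0.005, 0.02)
  h <- makeHarmonized(bx, by, sy)
  mv <- mrMVMR(cbind(x = bx), by, sy)
  expect_equal(betaHat(mv$x), betaHat(mrIVW(h)$estimate), tolerance = 1e-12)
})

test_that("MVMR rejects rank-deficient and under-identified designs", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(mrMVMR(X, rnorm(4), rep(0.01, 4)), "rank-deficient|dependent")
  expect_error(mrMVMR(cbind(a = rnorm(2), b = rnorm(2)), rnorm(2),
                      rep(0.01, 2)), "more instruments")
})

test_that("estimate objects stay internally consistent", {
  iv <- mrIVW(affineToy())$estimate
  expect_equal(pValue(iv),
               2 * pnorm(-abs(betaHat(iv) / stdErr(iv))), tolerance = 1e-9)
  expect_lt(iv@ciLow, iv@orPoint)
  expect_gt(iv@ciHigh, iv@orPoint)
  expect_equal(iv@orPoint, exp(betaHat(iv)), tolerance = 1e-12)
})
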