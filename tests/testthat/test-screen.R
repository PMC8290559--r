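cfgT <- function(...) screenConfig(seed = 7, ...)

test_that("BH adjustment matches the worked example and handles edge cases", {
  expect_equal(fdrAdjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdrAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(2024)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdrAdjust(p), bruteForceBH(p), tolerance = 1e-12)
  }
})

test_that("tier classification follows the q-then-p rule", {
  cfg <- cfgT()
  expect_equal(classifyTier(0.001, 0.04, cfg), "significant")
  expect_equal(classifyTier(0.01, 0.2, cfg), "suggestive")
  expect_equal(classifyTier(0.5, 0.8, cfg), "null")
  # raising the FDR level never removes a significant call
  set.seed(10)
  p <- runif(50, 0, 0.2); q <- fdrAdjust(p)
  t1 <- classifyTier(p, q, cfgT(fdrAlpha = 0.05))
  t2 <- classifyTier(p, q, cfgT(fdrAlpha = 0.10))
  expect_true(all(t2[t1 == "significant"] == "significant"))
})

test_that("concordance is sign agreement with zero discordant", {
  mk <- function(b, m) MREstimate(m, b, 0.1, 0.5, 5L)
  expect_true(concordantEstimates(list(
    ivw = mk(-0.26, "ivw"), weighted_median = mk(-0.31, "weighted_median"),
    egger_slope = mk(-0.45, "egger_slope"))))
  expect_false(concordantEstimates(list(
    ivw = mk(-0.2, "ivw"), egger_slope = mk(0.1, "egger_slope"))))
  expect_false(concordantEstimates(list(
    ivw = mk(0, "ivw"), weighted_median = mk(0.2, "weighted_median"))))
  expect_error(concordantEstimates(list(
    weighted_median = mk(0.1, "weighted_median"))), "ivw")
  expect_true(is.na(concordantEstimates(list(ivw = mk(0.3, "ivw")))))
})

test_that("the screen excludes ineligible exposures with reasons", {
  sim <- simulateExposome(10, 0.2, jSnps = 6, seed = 3)
  # cripple exposure 1: keep only 2 genome-wide-significant instruments
  v <- variants(sim$exposures[[1]])
  v$pval[3:6] <- 0.5
  sim$exposures[[1]] <- SummaryStats(traitId(sim$exposures[[1]]), v,
                                     nTotal = 361194)
  # exposure 2 duplicated under exposure 3's id
  sim$exposures[[2]] <- SummaryStats(traitId(sim$exposures[[3]]),
                                     variants(sim$exposures[[2]]),
                                     nTotal = 361194)
  res <- suppressMessages(
    runScreen(sim$exposures[c(3, 2, 1, 4:10)], sim$outcomes,
              cfg = cfgT(pressoNsim = 100, wmNboot = 50)))
  rec <- res$records
  ex1 <- rec[rec$exposure_id == "exp0001", ]
  expect_true(all(!ex1$eligible))
  expect_true(all(ex1$reason == "too_few_instruments"))
  dup <- rec[rec$exposure_id == traitId(sim$exposures[[3]]) & !rec$eligible, ]
  expect_equal(unique(dup$reason), "duplicated")
  expect_equal(nrow(rec), 20L)  # every exposure x outcome emitted
})

test_that("a binary exposure below the case floor is excluded", {
  sim <- simulateExposome(10, 0, jSnps = 6, seed = 4)
  v <- variants(sim$exposures[[5]])
  mu <- 0.002
  v$beta <- v$beta * mu * (1 - mu); v$se <- v$se * mu * (1 - mu)
  sim$exposures[[5]] <- SummaryStats("rare_binary", v,
                                     traitType = "binary_linear",
                                     caseFraction = mu, nTotal = 361194,
                                     nCases = 180)
  res <- suppressMessages(
    runScreen(sim$exposures, sim$outcomes,
              cfg = cfgT(pressoNsim = 100, wmNboot = 50)))
  rb <- res$records[res$records$exposure_id == "rare_binary", ]
  expect_equal(unique(rb$reason), "too_few_cases")
})

test_that("binary-linear exposures are transformed before estimation", {
  sim <- simulateExposome(10, 1,
                          effectDist = function(n) rep(0.35, n),
                          jSnps = 8, seed = 6)
  # re-encode exposure 1 on the linear scale; the screen must recover
  # the same IVW estimate as the untransformed run
  mu <- 0.25
  v <- variants(sim$exposures[[1]])
  vLin <- v
  vLin$beta <- v$beta * mu * (1 - mu); vLin$se <- v$se * mu * (1 - mu)
  expLin <- SummaryStats(traitId(sim$exposures[[1]]), vLin,
                         traitType = "binary_linear", caseFraction = mu,
                         nTotal = 361194, nCases = 90000)
  cfg <- cfgT(pressoNsim = 100, wmNboot = 50)
  resQ <- suppressMessages(runScreen(sim$exposures[1], sim$outcomes["p90"],
                                     cfg = cfg))
  resL <- suppressMessages(runScreen(list(expLin), sim$outcomes["p90"],
                                     cfg = cfg))
  expect_equal(resL$records$beta_ivw, resQ$records$beta_ivw,
               tolerance = 1e-10)
  expect_equal(resL$records$pval_ivw, resQ$records$pval_ivw,
               tolerance = 1e-10)
})

test_that("the screen is deterministic given inputs and seed", {
  sim <- simulateExposome(12, 0.25, jSnps = 8, seed = 5)
  cfg <- cfgT(pressoNsim = 100, wmNboot = 50)
  r1 <- suppressMessages(runScreen(sim$exposures, sim$outcomes, cfg = cfg))
  r2 <- suppressMessages(runScreen(sim$exposures, sim$outcomes, cfg = cfg))
  expect_identical(r1$records, r2$records)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeTable(r1$records, p1); writeTable(r2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("FDR is computed within each outcome separately", {
  sim <- simulateExposome(20, 0.25, jSnps = 8, seed = 9)
  res <- suppressMessages(runScreen(sim$exposures, sim$outcomes,
                                    cfg = cfgT(pressoNsim = 100,
                                               wmNboot = 50)))
  rec <- res$records
  for (ot in c("p90", "p99")) {
    sel <- rec$outcome == ot & rec$eligible
    expect_equal(rec$q_fdr[sel], fdrAdjust(rec$pval_ivw[sel]),
                 tolerance = 1e-12)
  }
})

test_that("validation merging reproduces the component decision patterns", {
  cfg <- cfgT()
  mkRec <- function(id, outcome, tier, conc = TRUE, power = NA) {
    data.frame(exposure_id = id, outcome = outcome, eligible = TRUE,
               tier = tier, concordant = conc, power = power,
               stringsAsFactors = FALSE)
  }
  screen <- rbind(
    mkRec("robust_noval", "p90", "significant"),
    mkRec("robust_noval", "p99", "suggestive"),
    mkRec("killed_by_val", "p90", "significant"),
    mkRec("killed_by_val", "p99", "significant"),
    mkRec("saved_by_val", "p90", "significant"),
    mkRec("saved_by_val", "p99", "null"),
    mkRec("weak", "p90", "suggestive"),
    mkRec("weak", "p99", "null"))
  validation <- rbind(
    mkRec("killed_by_val", "val", "null", power = 0.9),
    mkRec("saved_by_val", "val", "significant", power = 0.6))
  out <- mergeValidation(screen, validation, cfg)
  row <- function(id) out[out$exposure_id == id, ]
  # robust in both outcomes, concordant, no validation data -> component,
  # flagged unvalidated
  expect_true(row("robust_noval")$component)
  expect_equal(row("robust_noval")$flag, "unvalidated")
  # null validation at high power overrides the screen -> excluded
  expect_false(row("killed_by_val")$component)
  expect_equal(row("killed_by_val")$flag, "excluded_validation")
  # significant validation rescues a single-outcome hit -> component
  expect_true(row("saved_by_val")$component)
  expect_equal(row("saved_by_val")$flag, "validated")
  # suggestive-only exposures inherit their (non-significant) status
  expect_false(row("weak")$component)
  # validation exposures absent from the screen only warn
  expect_warning(
    mergeValidation(screen, rbind(validation,
                                  mkRec("stranger", "val", "null")), cfg),
    "stranger")
})

test_that("low-power null validation does not exclude", {
  cfg <- cfgT()
  screen <- data.frame(
    exposure_id = rep("x", 2), outcome = c("p90", "p99"),
    eligible = TRUE, tier = c("significant", "suggestive"),
    concordant = TRUE, stringsAsFactors = FALSE)
  validation <- data.frame(exposure_id = "x", outcome = "val",
                           eligible = TRUE, tier = "null",
                           concordant = TRUE, power = 0.4,
                           stringsAsFactors = FALSE)
  out <- mergeValidation(screen, validation, cfg)
  expect_true(out$component)
  expect_equal(out$flag, "unvalidated")
})

test_that("YAML configuration files load into a ScreenConfig", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 42", "fdr_alpha: 0.1", "presso_nsim: 500",
               "exposures:", "  - a.tsv", "  - b.tsv"), path)
  loaded <- loadScreenConfig(path)
  expect_s3_class(loaded$config, "ScreenConfig")
  expect_equal(loaded$config$seed, 42L)
  expect_equal(loaded$config$fdrAlpha, 0.1)
  expect_equal(loaded$config$pressoNsim, 500)
  expect_equal(loaded$config$pMax, 5e-8)   # untouched default
  expect_equal(loaded$files$exposures, c("a.tsv", "b.tsv"))
})
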