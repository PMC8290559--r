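#' @include AllClasses.R sumstats.R utils.R estimators.R
NULL

#' Ground-truth parameters for simulated MR data
#'
#' Encodes the generative two-sample MR model: instrument effects
#' \eqn{\gamma_j} drawn from a half-normal \eqn{|N(0, \sigma_\gamma^2)|}
#' truncated away from zero (instruments coded to the
#' exposure-increasing allele, as after genome-wide selection),
#' observed exposure betas \eqn{\hat\beta_{Xj} \sim N(\gamma_j,
#' se_X^2)}, pleiotropic effects \eqn{\alpha_j \sim N(\mu_\alpha,
#' \sigma_\alpha^2)} (optionally correlated with \eqn{\gamma_j} to break
#' the InSIDE assumption), and outcome betas \eqn{\hat\beta_{Yj} \sim
#' N(\theta \gamma_j + \alpha_j, se_Y^2)}.
#'
#' @param theta true causal effect (log OR per exposure SD).
#' @param sigmaGamma SD of instrument effects (> 0); the default 0.03
#'   with the default exposure SE yields realistic genome-wide-
#'   significant instruments explaining about 1\% of exposure variance
#'   over 30 SNPs.
#' @param sigmaAlpha SD of pleiotropic effects (0 = no pleiotropy).
#' @param muAlpha mean pleiotropy; nonzero = directional. Requires
#'   sigmaAlpha > 0.
#' @param insideViolation make pleiotropy correlated with instrument
#'   strength (violating InSIDE).
#' @param outlierMag named numeric vector: names are instrument indices,
#'   values the pleiotropy added to those SNPs' outcome effects (planted
#'   outliers / invalid instruments).
#' @param caseFraction outcome case fraction recorded as metadata.
#' @param seed integer seed; identical truth + seed reproduce datasets
#'   exactly.
#' @return list of class \code{"SimTruth"}.
#' @export
simTruth <- function(theta = 0, sigmaGamma = 0.03, sigmaAlpha = 0,
                     muAlpha = 0, insideViolation = FALSE,
                     outlierMag = NULL, caseFraction = 0.3065, seed = 1) {
  if (sigmaGamma <= 0) stop("sigmaGamma must be > 0")
  if (muAlpha != 0 && sigmaAlpha == 0)
    stop("directional pleiotropy (muAlpha != 0) requires sigmaAlpha > 0 ",
         "(no-pleiotropy regime cannot carry a mean shift)")
  if (caseFraction <= 0 || caseFraction >= 1)
    stop("caseFraction must lie in (0, 1)")
  structure(list(theta = theta, sigmaGamma = sigmaGamma,
                 sigmaAlpha = sigmaAlpha, muAlpha = muAlpha,
                 insideViolation = insideViolation,
                 outlierMag = outlierMag, caseFraction = caseFraction,
                 seed = as.integer(seed)),
            class = "SimTruth")
}

.NONPALINDROMIC <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                            "G", "A", "C", "A", "G", "T", "C", "T"),
                          ncol = 2, byrow = TRUE)

.truncNorm <- function(n, sd, lower) {
  # |x| > lower, rejection sampling (vectorized refills)
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) <= lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) <= lower
  }
  x
}

.zP <- function(beta, se) pmax(2 * stats::pnorm(-abs(beta / se)), PVAL_FLOOR)

.variantFrame <- function(ids, pos0, alleleRows, eaf, beta, se, n) {
  data.frame(snp_id = ids, chrom = "1",
             pos = pos0 + seq_along(ids) * 1000L,
             effect_allele = .NONPALINDROMIC[alleleRows, 1L],
             other_allele = .NONPALINDROMIC[alleleRows, 2L],
             eaf = eaf, beta = beta, se = se, pval = .zP(beta, se),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate one exposure-outcome summary-statistics pair
#'
#' Draws instrument effects, observed exposure and outcome betas, and
#' per-SNP p-values under the generative model of a
#' \code{\link{simTruth}}; effect-allele frequencies are Uniform(0.05,
#' 0.95), alleles are non-palindromic and identically oriented in both
#' datasets, and the LD matrix is the identity (instruments already
#' independent, as after clumping at r2 < 0.001).
#'
#' @param truth a \code{\link{simTruth}}.
#' @param jSnps number of instruments (>= 4).
#' @param seX,seY per-SNP standard errors (scalars or length-J vectors);
#'   defaults 0.003 and 0.01 correspond to exposure and outcome GWAS of
#'   roughly UK Biobank and longevity-consortium scale.
#' @param nExposure,nOutcome,nCasesOutcome sample sizes recorded as
#'   metadata.
#' @param exposureId,outcomeId trait identifiers.
#' @param seed seed overriding \code{truth$seed} (for replicate loops).
#' @return list with \code{exposure} and \code{outcome}
#'   \linkS4class{SummaryStats}, \code{ld} (\linkS4class{LDMatrix}),
#'   and \code{gamma} (the true instrument effects).
#' @export
simulatePair <- function(truth, jSnps, seX = 0.003, seY = 0.01,
                         nExposure = 361194, nOutcome = 36745,
                         nCasesOutcome = 11262, exposureId = "exposure",
                         outcomeId = "outcome", seed = truth$seed) {
  stopifnot(inherits(truth, "SimTruth"))
  if (jSnps < 4) stop("jSnps must be >= 4")
  seX <- rep_len(seX, jSnps); seY <- rep_len(seY, jSnps)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)

  # instruments are coded to the exposure-increasing allele (the
  # conventional orientation after genome-wide selection), so gamma > 0
  gamma <- abs(.truncNorm(jSnps, truth$sigmaGamma, 2 * max(seX)))
  eaf <- stats::runif(jSnps, 0.05, 0.95)
  alleleRows <- sample.int(nrow(.NONPALINDROMIC), jSnps, replace = TRUE)
  bx <- stats::rnorm(jSnps, gamma, seX)

  alpha <- if (truth$sigmaAlpha > 0) {
    if (truth$insideViolation) {
      rho <- 0.7
      truth$muAlpha + rho * truth$sigmaAlpha * gamma / truth$sigmaGamma +
        sqrt(1 - rho^2) * stats::rnorm(jSnps, 0, truth$sigmaAlpha)
    } else stats::rnorm(jSnps, truth$muAlpha, truth$sigmaAlpha)
  } else numeric(jSnps)
  if (!is.null(truth$outlierMag)) {
    idx <- as.integer(names(truth$outlierMag))
    alpha[idx] <- alpha[idx] + truth$outlierMag
  }
  by <- stats::rnorm(jSnps, truth$theta * gamma + alpha, seY)

  ids <- sprintf("%s_snp%03d", exposureId, seq_len(jSnps))
  exposure <- SummaryStats(exposureId,
    .variantFrame(ids, 0L, alleleRows, eaf, bx, seX, nExposure),
    traitType = "quantitative", nTotal = nExposure)
  outcome <- SummaryStats(outcomeId,
    .variantFrame(ids, 0L, alleleRows, eaf, by, seY, nOutcome),
    traitType = "binary_logistic", nTotal = nOutcome,
    nCases = nCasesOutcome)
  list(exposure = exposure, outcome = outcome, ld = LDMatrix(ids),
       gamma = gamma)
}

#' Simulate a binary exposure analyzed on the linear scale
#'
#' Generates an exposure whose underlying effects live on the log
#' odds-ratio scale and stores them as a linear-model GWAS of a binary
#' trait would report them: betas and SEs multiplied by
#' \eqn{\mu(1-\mu)}, with \code{traitType = "binary_linear"} and the
#' case fraction recorded, so that \code{\link{linearToLogodds}} exactly
#' recovers the log-OR dataset.
#'
#' @param truth a \code{\link{simTruth}}.
#' @param jSnps number of instruments.
#' @param mu case fraction of the binary exposure.
#' @param ... further arguments passed to \code{\link{simulatePair}}.
#' @return list with \code{linear} (the binary_linear
#'   \linkS4class{SummaryStats}) and \code{logodds} (the underlying
#'   log-OR-scale dataset).
#' @export
simulateLinearBinary <- function(truth, jSnps, mu, ...) {
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)")
  pair <- simulatePair(truth, jSnps, ...)
  under <- pair$exposure
  v <- variants(under)
  f <- mu * (1 - mu)
  vLin <- v
  vLin$beta <- v$beta * f
  vLin$se <- v$se * f
  linear <- SummaryStats(traitId(under), vLin, traitType = "binary_linear",
                         caseFraction = mu, nTotal = under@nTotal,
                         nCases = round(mu * under@nTotal))
  logodds <- SummaryStats(traitId(under), v, traitType = "binary_logistic",
                          caseFraction = mu, nTotal = under@nTotal,
                          nCases = round(mu * under@nTotal))
  list(linear = linear, logodds = logodds)
}

#' Simulate a whole exposome with known ground truth
#'
#' Generates \code{eExposures} independent exposures, a fixed fraction
#' of them truly causal with effects drawn from \code{effectDist}, and
#' two shared longevity-like outcome datasets: a primary one
#' (90th-percentile survival, 11,262 cases / 25,483 controls) and a
#' noisier secondary one (99th-percentile, 3,484 cases; outcome SEs
#' scaled up accordingly). Each exposure contributes its own instruments
#' (unique snp_ids), drawn on a named substream of the master seed so
#' any single exposure is reproducible in isolation.
#'
#' @param eExposures number of exposures (>= 10).
#' @param causalFraction fraction of truly causal exposures in [0, 1];
#'   the causal count is exactly \code{round(eExposures *
#'   causalFraction)}.
#' @param effectDist function(n) drawing n true effects; default draws
#'   log ORs of magnitude 0.35 with random sign.
#' @param truthDefaults \code{\link{simTruth}} template supplying the
#'   pleiotropy regime and instrument-strength parameters.
#' @param jSnps instruments per exposure.
#' @param seX,seY90 exposure and primary-outcome per-SNP SEs; the
#'   secondary outcome's SEs are scaled by the effective-sample-size
#'   ratio (about 1.6).
#' @param seed master seed.
#' @return list with \code{exposures} (list of
#'   \linkS4class{SummaryStats}), \code{outcomes} (named list
#'   \code{p90}, \code{p99}), \code{truth} (data.frame
#'   \code{exposure_id}, \code{theta}, \code{causal}), and \code{ld}
#'   (NULL: instruments are simulated independent).
#' @export
simulateExposome <- function(eExposures = 200, causalFraction = 0.1,
                             effectDist = function(n)
                               sample(c(-0.35, 0.35), n, replace = TRUE),
                             truthDefaults = simTruth(),
                             jSnps = 30, seX = 0.003, seY90 = 0.01,
                             seed = 1) {
  if (eExposures < 10) stop("eExposures must be >= 10")
  if (causalFraction < 0 || causalFraction > 1)
    stop("causalFraction must lie in [0, 1]")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))

  # longevity-GWAS-like outcome metadata
  n90 <- 11262 + 25483; mu90 <- 11262 / n90
  n99 <- 3484 + 25483; mu99 <- 3484 / n99
  neff <- function(nc, nt) 4 / (1 / nc + 1 / (nt - nc))
  seY99 <- seY90 * sqrt(neff(11262, n90) / neff(3484, n99))

  nCausal <- round(eExposures * causalFraction)
  set.seed(substreamSeed(seed, "assignment"))
  causalIdx <- if (nCausal > 0) sort(sample.int(eExposures, nCausal))
               else integer(0)
  thetas <- numeric(eExposures)
  if (nCausal > 0) thetas[causalIdx] <- effectDist(nCausal)

  exposures <- vector("list", eExposures)
  out90 <- out99 <- vector("list", eExposures)
  for (e in seq_len(eExposures)) {
    id <- sprintf("exp%04d", e)
    sseed <- substreamSeed(seed, id)
    set.seed(sseed)
    gamma <- abs(.truncNorm(jSnps, truthDefaults$sigmaGamma, 2 * seX))
    eaf <- stats::runif(jSnps, 0.05, 0.95)
    alleleRows <- sample.int(nrow(.NONPALINDROMIC), jSnps, replace = TRUE)
    bx <- stats::rnorm(jSnps, gamma, seX)
    alpha <- if (truthDefaults$sigmaAlpha > 0)
      stats::rnorm(jSnps, truthDefaults$muAlpha, truthDefaults$sigmaAlpha)
      else numeric(jSnps)
    by90 <- stats::rnorm(jSnps, thetas[e] * gamma + alpha, seY90)
    by99 <- stats::rnorm(jSnps, thetas[e] * gamma + alpha, seY99)

    ids <- sprintf("%s_s%03d", id, seq_len(jSnps))
    exposures[[e]] <- SummaryStats(id,
      .variantFrame(ids, (e - 1L) * 100000L, alleleRows, eaf, bx,
                    rep(seX, jSnps), 361194),
      traitType = "quantitative", nTotal = 361194)
    out90[[e]] <- .variantFrame(ids, (e - 1L) * 100000L, alleleRows, eaf,
                                by90, rep(seY90, jSnps), n90)
    out99[[e]] <- .variantFrame(ids, (e - 1L) * 100000L, alleleRows, eaf,
                                by99, rep(seY99, jSnps), n99)
  }

  outcomes <- list(
    p90 = SummaryStats("longevity_p90", do.call(rbind, out90),
                       traitType = "binary_logistic", nTotal = n90,
                       nCases = 11262),
    p99 = SummaryStats("longevity_p99", do.call(rbind, out99),
                       traitType = "binary_logistic", nTotal = n99,
                       nCases = 3484))
  truth <- data.frame(
    exposure_id = sprintf("exp%04d", seq_len(eExposures)),
    theta = thetas, causal = thetas != 0, stringsAsFactors = FALSE)
  list(exposures = exposures, outcomes = outcomes, truth = truth,
       ld = NULL)
}

#' Simulate a block-structured LD matrix
#'
#' Builds an \linkS4class{LDMatrix} whose variants fall into consecutive
#' blocks with constant within-block r2 and zero between-block r2 --
#' a minimal correlation structure for exercising greedy clumping.
#'
#' @param snpIds variant identifiers.
#' @param blockSizes integer block sizes summing to
#'   \code{length(snpIds)}.
#' @param withinR2 within-block squared correlation(s), recycled over
#'   blocks.
#' @return An \linkS4class{LDMatrix}.
#' @export
simulateLDBlocks <- function(snpIds, blockSizes, withinR2 = 0.8) {
  if (sum(blockSizes) != length(snpIds))
    stop("blockSizes must sum to length(snpIds)")
  withinR2 <- rep_len(withinR2, length(blockSizes))
  n <- length(snpIds)
  m <- diag(n)
  at <- 0L
  for (b in seq_along(blockSizes)) {
    idx <- at + seq_len(blockSizes[b])
    m[idx, idx] <- withinR2[b]
    diag(m)[idx] <- 1
    at <- at + blockSizes[b]
  }
  LDMatrix(snpIds, m)
}
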