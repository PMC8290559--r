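#' @import methods
NULL

VARIANT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

.validVariants <- function(v) {
  msgs <- character()
  missing_cols <- setdiff(VARIANT_COLS, names(v))
  if (length(missing_cols))
    return(paste("variants missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(v$snp_id))
    msgs <- c(msgs, "snp_id values must be unique")
  if (nrow(v)) {
    if (!all(v$se > 0, na.rm = TRUE) || anyNA(v$se))
      msgs <- c(msgs, "se must be > 0 for every variant")
    if (!all(v$pval > 0 & v$pval <= 1, na.rm = TRUE) || anyNA(v$pval))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    bad_eaf <- !is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)
    if (any(bad_eaf))
      msgs <- c(msgs, "eaf, when present, must lie in (0, 1)")
    ok_allele <- v$effect_allele %in% c("A", "C", "G", "T") &
      v$other_allele %in% c("A", "C", "G", "T")
    if (!all(ok_allele))
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    if (any(v$effect_allele == v$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}

#' GWAS summary statistics for one trait
#'
#' Container for per-variant association summary statistics (one row per
#' SNP: identifier, position, alleles, effect-allele frequency, beta, SE,
#' p-value, sample size) together with trait-level metadata: the trait
#' type, the case fraction \eqn{\mu} for binary traits analyzed with a
#' linear model, and sample sizes.
#'
#' @slot traitId character trait identifier.
#' @slot traitType one of \code{"quantitative"}, \code{"binary_linear"}
#'   (binary trait analyzed on the linear scale, as in linear-mixed-model
#'   GWAS of case/control phenotypes), or \code{"binary_logistic"}
#'   (effects already on the log odds-ratio scale).
#' @slot caseFraction case fraction \eqn{\mu \in (0,1)}; required exactly
#'   when \code{traitType == "binary_linear"}, \code{NA} otherwise unless
#'   supplied as metadata.
#' @slot nTotal total GWAS sample size.
#' @slot nCases number of cases, or \code{NA} for quantitative traits.
#' @slot variants \code{data.frame} with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pval}, \code{n}; \code{snp_id} unique.
#' @slot dropLog named integer vector counting rows dropped at read time,
#'   by reason.
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(
    traitId = "character",
    traitType = "character",
    caseFraction = "numeric",
    nTotal = "numeric",
    nCases = "numeric",
    variants = "data.frame",
    dropLog = "integer"
  ),
  prototype(
    caseFraction = NA_real_, nCases = NA_real_,
    dropLog = integer(0)
  )
)

setValidity("SummaryStats", function(object) {
  msgs <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msgs <- c(msgs, "traitId must be a single non-empty string")
  if (!object@traitType %in% c("quantitative", "binary_linear", "binary_logistic"))
    msgs <- c(msgs, "traitType must be quantitative, binary_linear or binary_logistic")
  if (object@traitType == "binary_linear" &&
      (is.na(object@caseFraction) ||
       object@caseFraction <= 0 || object@caseFraction >= 1))
    msgs <- c(msgs, "binary_linear traits require caseFraction in (0, 1)")
  if (object@traitType == "quantitative" && !is.na(object@caseFraction))
    msgs <- c(msgs, "caseFraction must be absent for quantitative traits")
  if (!is.na(object@nCases) && object@nCases > object@nTotal)
    msgs <- c(msgs, "nCases must not exceed nTotal")
  vm <- .validVariants(object@variants)
  if (!isTRUE(vm)) msgs <- c(msgs, vm)
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SummaryStats object
#'
#' @param traitId trait identifier.
#' @param variants data.frame of per-variant associations (see
#'   \linkS4class{SummaryStats} for required columns).
#' @param traitType trait type.
#' @param caseFraction case fraction, required for \code{binary_linear}.
#' @param nTotal total sample size; defaults to the maximum per-variant n.
#' @param nCases case count or NA.
#' @param dropLog named integer vector of read-time drop counts.
#' @return A \linkS4class{SummaryStats} object.
#' @export
SummaryStats <- function(traitId, variants, traitType = "quantitative",
                         caseFraction = NA_real_, nTotal = NULL,
                         nCases = NA_real_, dropLog = integer(0)) {
  variants <- as.data.frame(variants)[, VARIANT_COLS]
  variants$chrom <- as.character(variants$chrom)
  rownames(variants) <- NULL
  if (is.null(nTotal))
    nTotal <- if (nrow(variants)) max(variants$n) else NA_real_
  new("SummaryStats", traitId = traitId, traitType = traitType,
      caseFraction = as.numeric(caseFraction), nTotal = as.numeric(nTotal),
      nCases = as.numeric(nCases), variants = variants, dropLog = dropLog)
}

#' Pairwise linkage-disequilibrium matrix
#'
#' Symmetric matrix of pairwise squared correlations (\eqn{r^2}) between
#' variants, used by greedy clumping to prune instruments to a mutually
#' independent set.
#'
#' @slot snpIds ordered variant identifiers.
#' @slot r2 symmetric numeric matrix of squared correlations in [0, 1]
#'   with unit diagonal.
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(snpIds = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  msgs <- character()
  if (nrow(m) != length(object@snpIds) || ncol(m) != length(object@snpIds))
    msgs <- c(msgs, "r2 dimensions must match snpIds length")
  else {
    if (!isTRUE(all.equal(m, t(m), tolerance = 0, check.attributes = FALSE)))
      msgs <- c(msgs, "r2 must be exactly symmetric")
    if (any(m < 0 | m > 1))
      msgs <- c(msgs, "r2 values must lie in [0, 1]")
    if (length(object@snpIds) && any(diag(m) != 1))
      msgs <- c(msgs, "r2 diagonal must be all 1")
  }
  if (anyDuplicated(object@snpIds))
    msgs <- c(msgs, "snpIds must be unique")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an LDMatrix
#' @param snpIds variant identifiers.
#' @param r2 symmetric matrix of squared correlations; defaults to the
#'   identity (mutually independent variants).
#' @return An \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(snpIds, r2 = NULL) {
  if (is.null(r2)) {
    r2 <- diag(length(snpIds))
  }
  dimnames(r2) <- list(snpIds, snpIds)
  new("LDMatrix", snpIds = as.character(snpIds), r2 = r2)
}

#' Harmonized exposure-outcome instrument set
#'
#' Per-SNP exposure and outcome effects aligned to the exposure's effect
#' allele, after resolving allele swaps, strand flips and palindromic
#' SNPs, plus a complete per-instrument action log.
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot records data.frame with columns \code{snp_id}, \code{beta_x},
#'   \code{se_x}, \code{beta_y}, \code{se_y}, \code{eaf_x}, \code{eaf_y}.
#' @slot actions data.frame (\code{snp_id}, \code{action}) with exactly one
#'   row per candidate instrument; actions are \code{kept_direct},
#'   \code{kept_swapped}, \code{kept_strand_flipped},
#'   \code{kept_palindromic_aligned}, \code{dropped_palindromic_ambiguous},
#'   \code{dropped_missing}, \code{dropped_incompatible}.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(
    exposureId = "character", outcomeId = "character",
    records = "data.frame", actions = "data.frame"
  ))

HARMONIZE_ACTIONS <- c("kept_direct", "kept_swapped", "kept_strand_flipped",
                       "kept_palindromic_aligned",
                       "dropped_palindromic_ambiguous", "dropped_missing",
                       "dropped_incompatible")

setValidity("HarmonizedSet", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y", "eaf_x", "eaf_y")
  if (!all(need %in% names(r)))
    msgs <- c(msgs, "records missing required columns")
  else {
    if (nrow(r) < 1L)
      msgs <- c(msgs, "at least one harmonized record is required")
    if (nrow(r) && (any(r$se_x <= 0) || any(r$se_y <= 0)))
      msgs <- c(msgs, "se_x and se_y must be > 0")
  }
  if (!all(object@actions$action %in% HARMONIZE_ACTIONS))
    msgs <- c(msgs, "unknown harmonization action")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

HarmonizedSet <- function(exposureId, outcomeId, records, actions) {
  rownames(records) <- NULL
  rownames(actions) <- NULL
  new("HarmonizedSet", exposureId = exposureId, outcomeId = outcomeId,
      records = records, actions = actions)
}

#' A causal-effect estimate from one MR method
#'
#' Holds one method's causal estimate on the log odds-ratio (or outcome
#' unit) scale with its standard error, the exponentiated point estimate
#' and Wald 95\% confidence interval, the p-value, and the number of
#' instruments used.
#'
#' @slot method one of \code{ivw}, \code{egger_slope}, \code{egger_intercept},
#'   \code{weighted_median}, \code{presso_corrected}, \code{mvmr}.
#' @slot betaHat point estimate on the log scale.
#' @slot se standard error of \code{betaHat}.
#' @slot orPoint,ciLow,ciHigh exp(betaHat) and exp(betaHat +/- 1.96 se).
#' @slot pval two-sided p-value under the method's reference distribution.
#' @slot nSnps number of instruments used.
#' @exportClass MREstimate
setClass("MREstimate",
  representation(
    method = "character", betaHat = "numeric", se = "numeric",
    orPoint = "numeric", ciLow = "numeric", ciHigh = "numeric",
    pval = "numeric", nSnps = "integer"
  ))

MR_METHODS <- c("ivw", "egger_slope", "egger_intercept", "weighted_median",
                "presso_corrected", "mvmr")

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (!object@method %in% MR_METHODS)
    msgs <- c(msgs, "unknown method")
  if (object@se < 0) msgs <- c(msgs, "se must be >= 0")
  if (object@se > 0 &&
      !(object@ciLow < object@orPoint && object@orPoint < object@ciHigh))
    msgs <- c(msgs, "CI must bracket the point estimate")
  if (is.na(object@pval) || object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an MREstimate
#'
#' The odds-ratio point and 95\% CI are derived as \code{exp(betaHat)} and
#' \code{exp(betaHat +/- 1.96 se)}; the p-value must be supplied by the
#' estimator under its own reference distribution.
#'
#' @param method method label.
#' @param betaHat,se estimate and standard error on the log scale.
#' @param pval two-sided p-value.
#' @param nSnps number of instruments.
#' @return An \linkS4class{MREstimate}.
#' @export
MREstimate <- function(method, betaHat, se, pval, nSnps) {
  new("MREstimate", method = method, betaHat = betaHat, se = se,
      orPoint = exp(betaHat), ciLow = exp(betaHat - 1.96 * se),
      ciHigh = exp(betaHat + 1.96 * se),
      pval = max(pval, 1e-300), nSnps = as.integer(nSnps))
}

#' Cochran's Q heterogeneity test result
#'
#' @slot qStat Cochran's Q statistic.
#' @slot df degrees of freedom (number of instruments minus one).
#' @slot pval upper-tail chi-square p-value.
#' @exportClass HeterogeneityResult
setClass("HeterogeneityResult",
  representation(qStat = "numeric", df = "integer", pval = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  if (object@qStat < 0) return("qStat must be >= 0")
  expect <- stats::pchisq(object@qStat, object@df, lower.tail = FALSE)
  if (abs(object@pval - expect) > 1e-9)
    return("pval inconsistent with chi-square upper tail")
  TRUE
})

HeterogeneityResult <- function(qStat, df) {
  new("HeterogeneityResult", qStat = qStat, df = as.integer(df),
      pval = stats::pchisq(qStat, df, lower.tail = FALSE))
}

#' MR-PRESSO result
#'
#' Global residual-sum-of-squares pleiotropy test, per-SNP outlier tests
#' with Bonferroni adjustment, detected outliers, and the outlier-corrected
#' IVW estimate when outliers were removed.
#'
#' @slot rssObs observed residual sum of squares.
#' @slot globalP empirical global p-value (add-one rule, never below
#'   1/(nSim+1)).
#' @slot nSim number of simulation replicates.
#' @slot perSnp data.frame (\code{snp_id}, \code{p_raw}, \code{p_adj}).
#' @slot outliers snp_ids with Bonferroni-adjusted p < 0.05.
#' @slot corrected \linkS4class{MREstimate} with method
#'   \code{presso_corrected}, or \code{NULL} when no outliers were found.
#' @exportClass PressoResult
setClass("PressoResult",
  representation(
    rssObs = "numeric", globalP = "numeric", nSim = "integer",
    perSnp = "data.frame", outliers = "character", corrected = "ANY"
  ))

setValidity("PressoResult", function(object) {
  msgs <- character()
  if (object@rssObs < 0) msgs <- c(msgs, "rssObs must be >= 0")
  if (object@globalP < 1 / (object@nSim + 1) - 1e-12)
    msgs <- c(msgs, "globalP below add-one floor 1/(nSim+1)")
  if (!all(object@outliers %in% object@perSnp$snp_id))
    msgs <- c(msgs, "outliers must be a subset of tested SNPs")
  J <- nrow(object@perSnp)
  if (J && any(abs(object@perSnp$p_adj - pmin(1, object@perSnp$p_raw * J)) > 1e-12))
    msgs <- c(msgs, "p_adj must equal min(1, p_raw * J)")
  if (!is.null(object@corrected) && !is(object@corrected, "MREstimate"))
    msgs <- c(msgs, "corrected must be an MREstimate or NULL")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
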