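#' @include AllClasses.R
NULL

#' Exposure eligibility for the screen
#'
#' An exposure enters the screen only if (for categorical/binary traits)
#' it has at least \code{minCases} cases and if it supplies at least
#' \code{minSnps} independent genome-wide-significant instruments after
#' clumping.
#'
#' @param stats exposure \linkS4class{SummaryStats}.
#' @param nIndependentSnps number of independent instruments after
#'   clumping.
#' @param minCases minimum case count for binary exposures (default 250).
#' @param minSnps minimum number of independent instruments (default 3).
#' @return list with \code{eligible} (logical) and \code{reason}
#'   (\code{"ok"}, \code{"too_few_cases"} or \code{"too_few_instruments"}).
#' @export
exposureEligible <- function(stats, nIndependentSnps, minCases = 250,
                             minSnps = 3) {
  if (traitType(stats) != "quantitative" && !is.na(stats@nCases) &&
      stats@nCases < minCases)
    return(list(eligible = FALSE, reason = "too_few_cases"))
  if (nIndependentSnps < minSnps)
    return(list(eligible = FALSE, reason = "too_few_instruments"))
  list(eligible = TRUE, reason = "ok")
}

#' Select candidate instruments
#'
#' Retains variants with association p-value strictly below \code{pMax}
#' and minor allele frequency strictly above \code{mafMin}, preserving
#' input order. Variants with missing eaf cannot demonstrate the MAF
#' condition and are excluded.
#'
#' @param stats exposure \linkS4class{SummaryStats}.
#' @param pMax genome-wide significance threshold (default 5e-8, strict <).
#' @param mafMin minor-allele-frequency threshold (default 0.01, strict >).
#' @return data.frame of retained variant rows.
#' @export
selectInstruments <- function(stats, pMax = 5e-8, mafMin = 0.01) {
  v <- variants(stats)
  if (nrow(v) == 0L) return(v)
  maf <- pmin(v$eaf, 1 - v$eaf)
  keep <- v$pval < pMax & !is.na(maf) & maf > mafMin
  v[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value
#' (ties broken by lexicographically smaller snp_id), emits it, and
#' removes every remaining variant with squared correlation
#' \code{r2 >= r2Max} to it. The emitted set is pairwise independent at
#' \code{r2 < r2Max} and invariant to input row order when p-values are
#' distinct.
#'
#' @param candidates data.frame of variant rows (as from
#'   \code{\link{selectInstruments}}).
#' @param ld an \linkS4class{LDMatrix} covering all candidates, or
#'   \code{NULL} to assume pairwise independence (logged loudly).
#' @param r2Max LD threshold (default 0.001).
#' @return data.frame of retained independent variants, in selection
#'   order.
#' @export
clump <- function(candidates, ld = NULL, r2Max = 0.001) {
  if (nrow(candidates) == 0L) return(candidates)
  if (is.null(ld)) {
    message("clump: no LD matrix supplied; ASSUMING pairwise r2 = 0 ",
            "(all candidates treated as independent)")
    return(candidates)
  }
  missing <- setdiff(candidates$snp_id, snpIds(ld))
  if (length(missing))
    stop("candidates missing from LD matrix: ",
         paste(missing, collapse = ", "))
  r2 <- ld@r2[candidates$snp_id, candidates$snp_id, drop = FALSE]
  remaining <- order(candidates$pval, candidates$snp_id)
  picked <- integer(0)
  while (length(remaining)) {
    top <- remaining[1L]
    picked <- c(picked, top)
    remaining <- remaining[r2[top, remaining] < r2Max]
  }
  candidates[picked, , drop = FALSE]
}

#' Read a pairwise LD matrix from tab-separated text
#'
#' Expects a square matrix with a header row and a leading identifier
#' column, both carrying snp_ids; symmetry, unit diagonal and the [0,1]
#' range are validated on load.
#'
#' @param path file path.
#' @return An \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  LDMatrix(ids, m)
}

#' Variance in the exposure explained by the instruments
#'
#' For per-SD betas on a standardized trait,
#' \eqn{R^2 = \sum_j 2 p_j (1 - p_j) \beta_j^2} with \eqn{p_j} the
#' effect-allele frequency; capped just below 1.
#'
#' @param instruments data.frame of variant rows with \code{eaf} and
#'   \code{beta}.
#' @return R-squared in [0, 1).
#' @export
varianceExplained <- function(instruments) {
  if (nrow(instruments) == 0L) return(0)
  if (anyNA(instruments$eaf))
    stop("missing eaf for SNP(s): ",
         paste(instruments$snp_id[is.na(instruments$eaf)], collapse = ", "))
  r2 <- sum(2 * instruments$eaf * (1 - instruments$eaf) * instruments$beta^2)
  min(r2, 1 - 1e-12)
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = ((n - k - 1)/k) (R^2 / (1 - R^2))}; a strong instrument set
#' is conventionally F > 10 (strict).
#'
#' @param r2 total variance explained, in [0, 1).
#' @param n exposure GWAS sample size.
#' @param k number of instruments.
#' @return list with \code{f} and logical \code{strong} (F > 10).
#' @export
fStatistic <- function(r2, n, k) {
  if (k < 1) stop("k must be >= 1")
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (n <= k + 1) stop("sample size n must exceed k + 1")
  f <- ((n - k - 1) / k) * (r2 / (1 - r2))
  list(f = f, strong = f > 10)
}

#' Statistical power of an MR test on a binary outcome
#'
#' Normal-approximation power of the two-sided IVW Wald test at level
#' \code{alpha} against a hypothesized odds ratio, given the outcome
#' sample size, case fraction and instrument R-squared:
#' \deqn{power = \Phi(\sqrt{n R^2 \mu (1-\mu)} \, |\log OR| - z_{1-\alpha/2}).}
#' At OR = 1 this equals \eqn{\alpha/2} (one rejection tail).
#'
#' @param n outcome GWAS sample size.
#' @param mu outcome case fraction.
#' @param r2 variance in the exposure explained by the instruments.
#' @param orHyp hypothesized odds ratio per exposure SD.
#' @param alpha two-sided type-I error rate (default 0.05).
#' @return detection probability in [alpha/2, 1].
#' @export
powerBinary <- function(n, mu, r2, orHyp, alpha = 0.05) {
  stopifnot(n > 0, mu > 0, mu < 1, r2 >= 0, r2 < 1, orHyp > 0,
            alpha > 0, alpha < 1)
  stats::pnorm(sqrt(n * r2 * mu * (1 - mu)) * abs(log(orHyp)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Instrument diagnostics bundle
#'
#' Convenience wrapper computing total R-squared, the joint F-statistic
#' (and the mean per-SNP F), and power at a hypothesized OR, for a set of
#' selected instruments.
#'
#' @param instruments data.frame of instrument rows (per-SD betas).
#' @param nExposure exposure GWAS sample size.
#' @param nOutcome,muOutcome outcome sample size and case fraction.
#' @param orHyp hypothesized odds ratio for the power calculation.
#' @param alpha type-I error rate.
#' @return list with \code{r2_total}, \code{k}, \code{n}, \code{f_stat},
#'   \code{f_mean_per_snp}, \code{strong}, \code{power}.
#' @export
instrumentDiagnostics <- function(instruments, nExposure, nOutcome,
                                  muOutcome, orHyp = 0.8, alpha = 0.05) {
  k <- nrow(instruments)
  r2 <- varianceExplained(instruments)
  fs <- fStatistic(r2, nExposure, k)
  # mean per-SNP F: each SNP alone, k = 1
  per <- vapply(seq_len(k), function(j) {
    rj <- 2 * instruments$eaf[j] * (1 - instruments$eaf[j]) *
      instruments$beta[j]^2
    ((nExposure - 2) / 1) * (rj / (1 - rj))
  }, numeric(1))
  list(r2_total = r2, k = k, n = nExposure, f_stat = fs$f,
       f_mean_per_snp = mean(per), strong = fs$strong,
       power = powerBinary(nOutcome, muOutcome, r2, orHyp, alpha))
}
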