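#' @include AllClasses.R estimators.R
NULL

.looIVW <- function(bx, by, sy) {
  # leave-one-out IVW estimates, vectorized
  w <- 1 / sy^2
  num <- sum(bx * by * w); den <- sum(bx^2 * w)
  (num - bx * by * w) / (den - bx^2 * w)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. For each
#' instrument j the leave-one-out IVW estimate
#' \eqn{\hat\theta_{(-j)}} defines a standardized residual
#' \eqn{r_j = (\beta_{Yj} - \hat\theta_{(-j)} \beta_{Xj}) / se_{Yj}};
#' the observed RSS is compared against a parametric-bootstrap null
#' distribution: replicates redraw \eqn{\beta_{Xj}^* \sim N(\beta_{Xj},
#' se_{Xj}^2)} and \eqn{\beta_{Yj}^* \sim N(\hat\theta \beta_{Xj},
#' se_{Yj}^2)} from the fitted common causal line (full-sample IVW
#' \eqn{\hat\theta}), and the full leave-one-out statistic is recomputed
#' on each replicate so simulated and observed RSS carry the same
#' estimation noise. Empirical p-values use the add-one rule (never below
#' 1/(nSim+1)); per-SNP outlier p-values are Bonferroni-adjusted by J and
#' instruments with adjusted p < 0.05 are flagged as outliers and removed
#' to form the corrected IVW estimate. Simulation draws use a seeded
#' substream per SNP, so results are bit-reproducible and invariant to
#' SNP order.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 4 instruments.
#' @param nSim simulation replicates (default 1000, minimum 100).
#' @param seed integer seed (required).
#' @param outlierAlpha adjusted-p threshold declaring an outlier
#'   (default 0.05).
#' @return A \linkS4class{PressoResult}.
#' @export
pressoTest <- function(h, nSim = 1000, seed, outlierAlpha = 0.05) {
  if (missing(seed)) stop("an explicit seed is required")
  if (nSim < 100) stop("nSim must be at least 100")
  r <- records(h)
  J <- nrow(r)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments, got ", J)

  thetaLoo <- .looIVW(r$beta_x, r$beta_y, r$se_y)
  res <- (r$beta_y - thetaLoo * r$beta_x) / r$se_y
  rssObs <- sum(res^2)
  wv <- 1 / r$se_y^2
  thetaFull <- sum(r$beta_x * r$beta_y * wv) / sum(r$beta_x^2 * wv)

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  # per-SNP substream keyed by snp_id: outlier calls are invariant to
  # the order instruments arrive in
  bxs <- bys <- matrix(0, nSim, J)
  for (j in seq_len(J)) {
    set.seed(substreamSeed(seed, r$snp_id[j]))
    bxs[, j] <- stats::rnorm(nSim, r$beta_x[j], r$se_x[j])
    bys[, j] <- stats::rnorm(nSim, thetaFull * r$beta_x[j], r$se_y[j])
  }
  # recompute the leave-one-out IVW on every simulated replicate so the
  # null RSS carries the same estimation noise as the observed one
  w <- matrix(1 / r$se_y^2, nSim, J, byrow = TRUE)
  num <- rowSums(bxs * bys * w); den <- rowSums(bxs^2 * w)
  thetaLooStar <- (num - bxs * bys * w) / (den - bxs^2 * w)
  resStar2 <- ((bys - thetaLooStar * bxs) *
                 matrix(1 / r$se_y, nSim, J, byrow = TRUE))^2
  rssStar <- rowSums(resStar2)
  globalP <- (sum(rssStar >= rssObs) + 1) / (nSim + 1)
  pRaw <- (colSums(resStar2 >= rep(res^2, each = nSim)) + 1) / (nSim + 1)
  pAdj <- pmin(1, pRaw * J)
  out <- r$snp_id[pAdj < outlierAlpha]

  corrected <- NULL
  if (length(out) && J - length(out) >= 2)
    corrected <- pressoCorrected(h, out)

  new("PressoResult", rssObs = rssObs, globalP = globalP,
      nSim = as.integer(nSim),
      perSnp = data.frame(snp_id = r$snp_id, p_raw = pRaw, p_adj = pAdj,
                          stringsAsFactors = FALSE),
      outliers = out, corrected = corrected)
}

#' Outlier-corrected IVW estimate
#'
#' Re-runs the IVW estimator (identical contract to \code{\link{mrIVW}})
#' on the instruments remaining after removing the detected outliers,
#' labeled \code{presso_corrected}.
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @param outlierIds snp_ids to remove (must be a strict subset of the
#'   instruments).
#' @return An \linkS4class{MREstimate}.
#' @export
pressoCorrected <- function(h, outlierIds) {
  r <- records(h)
  bad <- setdiff(outlierIds, r$snp_id)
  if (length(bad))
    stop("outliers not among instruments: ", paste(bad, collapse = ", "))
  keep <- !(r$snp_id %in% outlierIds)
  if (sum(keep) < 2)
    stop("fewer than 2 instruments remain after outlier removal")
  h2 <- HarmonizedSet(h@exposureId, h@outcomeId, r[keep, , drop = FALSE],
                      h@actions)
  est <- mrIVW(h2)$estimate
  MREstimate("presso_corrected", betaHat(est), stdErr(est), pValue(est),
             sum(keep))
}
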