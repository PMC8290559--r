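#' @include AllClasses.R
NULL

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for instrument j is \eqn{\theta_j = \beta_{Yj} /
#' \beta_{Xj}} with first-order delta-method standard error
#' \eqn{se_j = se_{Yj} / |\beta_{Xj}|} and inverse-variance weight
#' \eqn{w_j = 1/se_j^2}.
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @return data.frame (\code{snp_id}, \code{theta}, \code{se}, \code{w}).
#' @export
waldRatios <- function(h) {
  r <- records(h)
  zero <- r$beta_x == 0
  if (any(zero))
    stop("zero exposure beta for SNP(s): ",
         paste(r$snp_id[zero], collapse = ", "))
  data.frame(snp_id = r$snp_id,
             theta = r$beta_y / r$beta_x,
             se = r$se_y / abs(r$beta_x),
             w = r$beta_x^2 / r$se_y^2,
             stringsAsFactors = FALSE)
}

.ivwCore <- function(bx, by, sy) {
  w <- 1 / sy^2
  den <- sum(bx^2 * w)
  theta <- sum(bx * by * w) / den
  list(theta = theta, seFixed = 1 / sqrt(den),
       q = sum(w * (by - theta * bx)^2))
}

#' Inverse-variance-weighted estimate with heterogeneity
#'
#' The principal estimator: weighted regression of outcome betas on
#' exposure betas through the origin with weights \eqn{1/se_{Yj}^2},
#' equivalently the inverse-variance-weighted mean of the Wald ratios.
#' The reported standard error uses multiplicative random effects floored
#' at the fixed-effect value, \eqn{se = se_{fixed} \max(1,
#' \sqrt{Q/(J-1)})}, with a two-sided normal p-value; Cochran's Q and its
#' chi-square p accompany the estimate.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 2 instruments.
#' @return list with \code{estimate} (\linkS4class{MREstimate}, method
#'   \code{ivw}) and \code{heterogeneity}
#'   (\linkS4class{HeterogeneityResult}).
#' @export
mrIVW <- function(h) {
  r <- records(h)
  J <- nrow(r)
  if (J < 2) stop("IVW requires at least 2 instruments, got ", J)
  fit <- .ivwCore(r$beta_x, r$beta_y, r$se_y)
  se <- fit$seFixed * max(1, sqrt(fit$q / (J - 1)))
  p <- 2 * stats::pnorm(-abs(fit$theta / se))
  list(estimate = MREstimate("ivw", fit$theta, se, p, J),
       heterogeneity = HeterogeneityResult(fit$q, J - 1))
}

#' Cochran's Q heterogeneity statistic for Wald ratios
#'
#' \eqn{Q = \sum_j w_j (\theta_j - \hat\theta)^2} on \eqn{J - 1} degrees
#' of freedom with an upper-tail chi-square p-value.
#'
#' @param ratios data.frame from \code{\link{waldRatios}}.
#' @param thetaHat pooled estimate around which to measure dispersion.
#' @return A \linkS4class{HeterogeneityResult}.
#' @export
cochranQ <- function(ratios, thetaHat) {
  J <- nrow(ratios)
  if (J < 2) stop("Cochran's Q requires at least 2 instruments")
  HeterogeneityResult(sum(ratios$w * (ratios$theta - thetaHat)^2), J - 1)
}

.wlsLine <- function(x, y, w, df) {
  # weighted least squares for an intercept + slope line via normal equations
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= .Machine$double.eps * sw * sxx)
    stop("collinear design: exposure betas identical after orientation")
  b1 <- (sw * sxy - sx * sy) / det
  b0 <- (sy - b1 * sx) / sw
  rss <- sum(w * (y - b0 - b1 * x)^2)
  sigma <- if (df > 0) sqrt(rss / df) else 0
  infl <- max(1, sigma)
  list(slope = b1, intercept = b0,
       seSlope = infl * sqrt(sw / det),
       seIntercept = infl * sqrt(sxx / det),
       sigma = sigma, rss = rss)
}

#' MR-Egger regression
#'
#' Weighted linear regression (weights \eqn{1/se_{Yj}^2}) of outcome
#' betas on exposure betas with an unconstrained intercept, after
#' orienting every instrument to a non-negative exposure beta. The slope
#' is the pleiotropy-robust causal estimate (valid when >50\% of
#' instruments are invalid, under InSIDE); the intercept estimates
#' average directional pleiotropy and serves as a pleiotropy test.
#' Standard errors are inflated by \code{max(1, residual SD)}; p-values
#' are two-sided t on J - 2 degrees of freedom.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @return list with \code{slope} and \code{intercept}
#'   \linkS4class{MREstimate}s (methods \code{egger_slope},
#'   \code{egger_intercept}).
#' @export
mrEgger <- function(h) {
  r <- records(h)
  J <- nrow(r)
  if (J < 3) stop("MR-Egger requires at least 3 instruments, got ", J)
  flip <- sign(r$beta_x) < 0
  bx <- abs(r$beta_x)
  by <- ifelse(flip, -r$beta_y, r$beta_y)
  fit <- .wlsLine(bx, by, 1 / r$se_y^2, J - 2)
  pSlope <- 2 * stats::pt(-abs(fit$slope / fit$seSlope), J - 2)
  pInt <- 2 * stats::pt(-abs(fit$intercept / fit$seIntercept), J - 2)
  list(slope = MREstimate("egger_slope", fit$slope, fit$seSlope, pSlope, J),
       intercept = MREstimate("egger_intercept", fit$intercept,
                              fit$seIntercept, pInt, J))
}

.weightedMedian <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(theta[1L])
  if (0.5 >= p[length(p)]) return(theta[length(p)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate with parametric-bootstrap SE
#'
#' The weighted median of the Wald ratios is consistent when up to 50\%
#' of the instrument weight comes from invalid instruments. Ratios are
#' ordered, weights normalized, and the estimate interpolated at the 50\%
#' point of the cumulative weight midpoints. The standard error is the SD
#' of the estimate over parametric-bootstrap replicates redrawing
#' \eqn{\beta_{Xj}^* \sim N(\beta_{Xj}, se_{Xj}^2)} and
#' \eqn{\beta_{Yj}^* \sim N(\beta_{Yj}, se_{Yj}^2)}; the p-value is
#' two-sided normal.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed (required; results are bit-reproducible).
#' @return An \linkS4class{MREstimate} (method \code{weighted_median}).
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  r <- records(h)
  J <- nrow(r)
  if (J < 3) stop("weighted median requires at least 3 instruments, got ", J)
  w <- r$beta_x^2 / r$se_y^2
  est <- .weightedMedian(r$beta_y / r$beta_x, w)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  bxs <- matrix(stats::rnorm(nBoot * J, rep(r$beta_x, each = nBoot),
                             rep(r$se_x, each = nBoot)), nBoot, J)
  bys <- matrix(stats::rnorm(nBoot * J, rep(r$beta_y, each = nBoot),
                             rep(r$se_y, each = nBoot)), nBoot, J)
  boot <- vapply(seq_len(nBoot), function(b) {
    bx <- bxs[b, ]
    .weightedMedian(bys[b, ] / bx, bx^2 / r$se_y^2)
  }, numeric(1))
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  MREstimate("weighted_median", est, se, p, J)
}

#' Multivariable MR
#'
#' Weighted regression (weights \eqn{1/se_{Yj}^2}) of outcome betas on
#' the instrument effects of K exposures jointly, with no intercept,
#' giving each exposure's direct (conditional) causal effect. Used to
#' adjust for genetic correlation between overlapping instrument sets,
#' e.g. the lipid fractions. SEs are inflated by \code{max(1, residual
#' SD)}; p-values are two-sided t on J - K degrees of freedom.
#'
#' @param betaX J x K matrix of exposure betas (columns named by
#'   exposure).
#' @param betaY,seY outcome betas and standard errors (length J).
#' @return named list of \linkS4class{MREstimate}s (method \code{mvmr}),
#'   one per exposure column.
#' @export
mrMVMR <- function(betaX, betaY, seY) {
  betaX <- as.matrix(betaX)
  J <- nrow(betaX); K <- ncol(betaX)
  if (J <= K) stop("multivariable MR requires more instruments than exposures")
  qrX <- qr(betaX)
  if (qrX$rank < K) {
    dep <- colnames(betaX)[qrX$pivot[(qrX$rank + 1):K]]
    stop("rank-deficient exposure matrix; dependent column(s): ",
         paste(if (is.null(dep)) "(unnamed)" else dep, collapse = ", "))
  }
  w <- 1 / seY^2
  xtwx <- crossprod(betaX, betaX * w)
  beta <- solve(xtwx, crossprod(betaX, betaY * w))[, 1L]
  rss <- sum(w * (betaY - betaX %*% beta)^2)
  df <- J - K
  sigma <- sqrt(rss / df)
  ses <- max(1, sigma) * sqrt(diag(solve(xtwx)))
  nm <- colnames(betaX)
  if (is.null(nm)) nm <- paste0("exposure", seq_len(K))
  out <- lapply(seq_len(K), function(k) {
    p <- 2 * stats::pt(-abs(beta[k] / ses[k]), df)
    MREstimate("mvmr", unname(beta[k]), unname(ses[k]), p, J)
  })
  names(out) <- nm
  out
}

# save/restore the global RNG state so seeded estimators do not disturb
# the caller's stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
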