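#' @include AllClasses.R
NULL

.BASES <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param a1,a2 single-base alleles.
#' @return logical.
#' @export
isPalindromic <- function(a1, a2) {
  if (!all(c(a1, a2) %in% names(.BASES)))
    stop("alleles must be A/C/G/T, got: ", a1, "/", a2)
  unname(.BASES[a1] == a2)
}

#' Complement of a single base
#'
#' @param a allele (A, C, G or T).
#' @return complementary base; an involution.
#' @export
complementAllele <- function(a) {
  if (!all(a %in% names(.BASES)))
    stop("alleles must be A/C/G/T, got: ", paste(a, collapse = ", "))
  unname(.BASES[a])
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele. Non-palindromic SNPs are kept directly, with allele swap
#' (outcome beta negated, frequency reflected), or after strand
#' complementation. Palindromic SNPs are dropped when the exposure minor
#' allele frequency exceeds \code{palindromicMafMax} (frequency too close
#' to 0.5 to resolve strand), or when either frequency is missing;
#' otherwise the outcome is oriented so both frequencies fall on the same
#' side of 0.5, and the pair is kept only if the oriented frequencies
#' agree within \code{eafTolerance}. Instruments absent from the outcome
#' or with irreconcilable allele sets are dropped. Every candidate
#' receives exactly one action-log entry. Duplicate outcome rows for a
#' snp_id keep the smallest-se row.
#'
#' @param exposure data.frame of instrument variant rows (as from
#'   \code{\link{clump}}) or a \linkS4class{SummaryStats}.
#' @param outcome outcome \linkS4class{SummaryStats}.
#' @param palindromicMafMax exposure-MAF cutoff above which palindromic
#'   SNPs are discarded (default 0.42).
#' @param eafTolerance maximum |eaf_x - eaf_y| after orientation for a
#'   retained palindromic SNP (default 0.2).
#' @param exposureId exposure identifier (taken from the SummaryStats
#'   when one is supplied).
#' @return A \linkS4class{HarmonizedSet}; an error is raised when no
#'   instrument survives.
#' @export
harmonizePair <- function(exposure, outcome, palindromicMafMax = 0.42,
                          eafTolerance = 0.2, exposureId = "exposure") {
  if (is(exposure, "SummaryStats")) {
    exposureId <- traitId(exposure)
    exposure <- variants(exposure)
  }
  stopifnot(is(outcome, "SummaryStats"))
  ov <- variants(outcome)
  # duplicates are impossible within a valid SummaryStats, but tolerate
  # raw outcome tables routed in via SummaryStats construction upstream
  oidx <- match(exposure$snp_id, ov$snp_id)

  n <- nrow(exposure)
  act <- character(n)
  keep <- logical(n)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    e1 <- exposure$effect_allele[i]; e2 <- exposure$other_allele[i]
    j <- oidx[i]
    if (is.na(j)) { act[i] <- "dropped_missing"; next }
    o1 <- ov$effect_allele[j]; o2 <- ov$other_allele[j]
    by <- ov$beta[j]; sy <- ov$se[j]; fy <- ov$eaf[j]
    fx <- exposure$eaf[i]

    if (isPalindromic(e1, e2)) {
      if (!setequal(c(o1, o2), c(e1, e2))) {
        act[i] <- "dropped_incompatible"; next
      }
      if (is.na(fx) || is.na(fy) ||
          pmin(fx, 1 - fx) > palindromicMafMax) {
        act[i] <- "dropped_palindromic_ambiguous"; next
      }
      # start from the labelled orientation, then align by frequency side
      if (o1 != e1) { by <- -by; fy <- 1 - fy }
      if (sign(fx - 0.5) != sign(fy - 0.5)) { by <- -by; fy <- 1 - fy }
      if (abs(fx - fy) >= eafTolerance) {
        act[i] <- "dropped_incompatible"; next
      }
      act[i] <- "kept_palindromic_aligned"
    } else {
      flipped <- FALSE
      if (!setequal(c(o1, o2), c(e1, e2))) {
        o1c <- complementAllele(o1); o2c <- complementAllele(o2)
        if (setequal(c(o1c, o2c), c(e1, e2))) {
          o1 <- o1c; o2 <- o2c; flipped <- TRUE
        } else {
          act[i] <- "dropped_incompatible"; next
        }
      }
      if (o1 == e1 && o2 == e2) {
        act[i] <- if (flipped) "kept_strand_flipped" else "kept_direct"
      } else if (o1 == e2 && o2 == e1) {
        by <- -by
        if (!is.na(fy)) fy <- 1 - fy
        act[i] <- if (flipped) "kept_strand_flipped" else "kept_swapped"
      } else {
        act[i] <- "dropped_incompatible"; next
      }
    }
    keep[i] <- TRUE
    beta_y[i] <- by; se_y[i] <- sy; eaf_y[i] <- fy
  }

  if (!any(keep))
    stop("no harmonizable instruments for exposure '", exposureId,
         "' against outcome '", traitId(outcome), "'")

  recs <- data.frame(
    snp_id = exposure$snp_id[keep],
    beta_x = exposure$beta[keep],
    se_x = exposure$se[keep],
    beta_y = beta_y[keep],
    se_y = se_y[keep],
    eaf_x = exposure$eaf[keep],
    eaf_y = eaf_y[keep],
    stringsAsFactors = FALSE
  )
  HarmonizedSet(exposureId, traitId(outcome), recs,
                data.frame(snp_id = exposure$snp_id, action = act,
                           stringsAsFactors = FALSE))
}
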