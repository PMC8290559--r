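#' @include AllClasses.R sumstats.R instruments.R harmonize.R estimators.R presso.R utils.R
NULL

#' Screen configuration
#'
#' Collects every threshold of the screening pipeline, with defaults
#' matching the standard exposome-wide MR design: genome-wide instrument
#' significance 5e-8, MAF > 0.01, clumping at r2 < 0.001, palindromic
#' MAF cutoff 0.42, categorical exposures need >= 250 cases and >= 3
#' independent instruments, FDR-significant at q < 0.05 and suggestive
#' at raw p < 0.05.
#'
#' @param pMax instrument p-value threshold (strict <).
#' @param mafMin minor-allele-frequency threshold (strict >).
#' @param r2Max LD clumping threshold.
#' @param palindromicMafMax exposure-MAF cutoff for palindromic SNPs.
#' @param eafTolerance frequency-concordance tolerance for retained
#'   palindromic SNPs.
#' @param minCases minimum case count for binary exposures.
#' @param minSnps minimum independent instruments.
#' @param fdrAlpha FDR significance level.
#' @param suggestiveAlpha raw-p suggestive level.
#' @param alphaPower type-I error rate used in power calculations.
#' @param orHyp hypothesized odds ratio for power calculations.
#' @param pressoNsim MR-PRESSO simulation replicates.
#' @param wmNboot weighted-median bootstrap replicates.
#' @param seed master seed (required; spawns per-exposure substreams).
#' @param powerThresholdValidation power above which a null validation
#'   result excludes an exposure (default 0.8).
#' @return list of class \code{"ScreenConfig"}.
#' @export
screenConfig <- function(pMax = 5e-8, mafMin = 0.01, r2Max = 0.001,
                         palindromicMafMax = 0.42, eafTolerance = 0.2,
                         minCases = 250, minSnps = 3, fdrAlpha = 0.05,
                         suggestiveAlpha = 0.05, alphaPower = 0.05,
                         orHyp = 0.8, pressoNsim = 1000, wmNboot = 1000,
                         seed, powerThresholdValidation = 0.8) {
  if (missing(seed)) stop("a master seed is required")
  stopifnot(pMax > 0, pMax < 1, mafMin >= 0, mafMin < 0.5,
            r2Max > 0, r2Max <= 1,
            palindromicMafMax > 0, palindromicMafMax <= 0.5,
            fdrAlpha > 0, fdrAlpha < 1, suggestiveAlpha > 0,
            suggestiveAlpha < 1, minCases >= 0, minSnps >= 1,
            pressoNsim >= 100, wmNboot >= 2,
            powerThresholdValidation > 0, powerThresholdValidation <= 1)
  structure(list(pMax = pMax, mafMin = mafMin, r2Max = r2Max,
                 palindromicMafMax = palindromicMafMax,
                 eafTolerance = eafTolerance, minCases = minCases,
                 minSnps = minSnps, fdrAlpha = fdrAlpha,
                 suggestiveAlpha = suggestiveAlpha,
                 alphaPower = alphaPower, orHyp = orHyp,
                 pressoNsim = pressoNsim, wmNboot = wmNboot,
                 seed = as.integer(seed),
                 powerThresholdValidation = powerThresholdValidation),
            class = "ScreenConfig")
}

#' Load a screen configuration from a YAML file
#'
#' The YAML file may carry any \code{\link{screenConfig}} field (snake_case
#' keys accepted) plus optional \code{exposures}, \code{outcomes},
#' \code{ld} and \code{dialect} entries naming input files and column
#' mappings.
#'
#' @param path YAML file path.
#' @return list with \code{config} (a ScreenConfig) and \code{files}
#'   (remaining entries).
#' @export
loadScreenConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- toCamel(names(raw))
  known <- names(formals(screenConfig))
  cfgArgs <- raw[intersect(names(raw), known)]
  list(config = do.call(screenConfig, cfgArgs),
       files = raw[setdiff(names(raw), known)])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and
#' returned in input order.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values in input order.
#' @export
fdrAdjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify an exposure into evidence tiers
#'
#' Significant when the FDR q-value is below \code{fdrAlpha}; otherwise
#' suggestive when the unadjusted IVW p is below \code{suggestiveAlpha};
#' otherwise null.
#'
#' @param pvalIVW unadjusted IVW p-value(s).
#' @param qFDR FDR-adjusted q-value(s).
#' @param cfg a \code{\link{screenConfig}}.
#' @return character vector of tiers.
#' @export
classifyTier <- function(pvalIVW, qFDR, cfg) {
  ifelse(qFDR < cfg$fdrAlpha, "significant",
         ifelse(pvalIVW < cfg$suggestiveAlpha, "suggestive", "null"))
}

#' Sign concordance across estimators
#'
#' TRUE iff every present point estimate (IVW -- or its PRESSO-corrected
#' replacement -- plus any of weighted median, Egger slope) has the same
#' non-zero sign; a zero estimate is discordant by convention.
#'
#' @param estimates named list of \linkS4class{MREstimate}s; must
#'   contain an element named \code{ivw}.
#' @return logical, or NA when fewer than two estimates are present.
#' @export
concordantEstimates <- function(estimates) {
  if (!"ivw" %in% names(estimates))
    stop("concordance requires an 'ivw' estimate")
  betas <- vapply(estimates, betaHat, numeric(1))
  if (length(betas) < 2) return(NA)
  s <- sign(betas)
  all(s != 0) && length(unique(s)) == 1L
}

.excludedRow <- function(id, outcomeTag, reason, meta) {
  data.frame(exposure_id = id, category = meta$category,
             domain = meta$domain, outcome = outcomeTag,
             eligible = FALSE, reason = reason,
             n_instruments = NA_integer_, n_harmonized = NA_integer_,
             r2 = NA_real_, f_stat = NA_real_, power = NA_real_,
             beta_ivw = NA_real_, se_ivw = NA_real_, pval_ivw = NA_real_,
             q_stat = NA_real_, q_pval = NA_real_,
             beta_egger = NA_real_, se_egger = NA_real_,
             pval_egger = NA_real_, egger_intercept = NA_real_,
             egger_intercept_p = NA_real_,
             beta_wm = NA_real_, se_wm = NA_real_, pval_wm = NA_real_,
             presso_global_p = NA_real_, n_outliers = NA_integer_,
             beta_presso = NA_real_,
             q_fdr = NA_real_, tier = NA_character_, concordant = NA,
             stringsAsFactors = FALSE)
}

#' Run the exposome-wide MR screen
#'
#' For every exposure x outcome pair: eligibility filtering (case count,
#' duplicate trait ids), instrument selection and LD clumping,
#' linear-to-log-odds transformation of binary-linear exposures,
#' harmonization, IVW with Cochran's Q, MR-Egger, weighted median and
#' MR-PRESSO (each on a per-exposure seeded substream), instrument
#' diagnostics, then Benjamini-Hochberg FDR over the eligible exposures
#' within each outcome separately, tier classification and sign
#' concordance. Excluded exposures are emitted with their exclusion
#' reason.
#'
#' @param exposures list of exposure \linkS4class{SummaryStats}.
#' @param outcomes named list of outcome \linkS4class{SummaryStats} on
#'   the log odds-ratio scale (e.g. \code{list(p90 = ..., p99 = ...)}).
#' @param ld an \linkS4class{LDMatrix} covering all candidate
#'   instruments, or NULL to treat candidates as independent (announced
#'   loudly once).
#' @param cfg a \code{\link{screenConfig}}.
#' @param metadata optional data.frame (\code{exposure_id},
#'   \code{category}, \code{domain}) of exposure labels.
#' @return list of class \code{"ScreenResult"}: \code{records}
#'   (data.frame, one row per exposure x outcome including exclusions),
#'   \code{details} (per-pair estimator objects), \code{config}.
#' @export
runScreen <- function(exposures, outcomes, ld = NULL, cfg,
                      metadata = NULL) {
  stopifnot(inherits(cfg, "ScreenConfig"), length(outcomes) >= 1)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("outcomes must be a named list")
  for (oc in outcomes) {
    if (traitType(oc) != "binary_logistic")
      stop("outcome '", traitId(oc),
           "' must be on the log odds-ratio scale (binary_logistic)")
  }
  if (is.null(ld))
    message("runScreen: no LD matrix supplied; ASSUMING pairwise r2 = 0 ",
            "between candidate instruments")

  getMeta <- function(id) {
    if (!is.null(metadata) && id %in% metadata$exposure_id) {
      m <- metadata[metadata$exposure_id == id, , drop = FALSE][1L, ]
      list(category = as.character(m$category), domain = as.character(m$domain))
    } else list(category = NA_character_, domain = NA_character_)
  }

  ids <- vapply(exposures, traitId, character(1))
  rows <- list(); details <- list()

  for (e in seq_along(exposures)) {
    stats <- exposures[[e]]
    id <- ids[e]
    meta <- getMeta(id)
    emitAll <- function(reason) {
      for (ot in names(outcomes))
        rows[[length(rows) + 1L]] <<- .excludedRow(id, ot, reason, meta)
    }

    if (e > 1L && id %in% ids[seq_len(e - 1L)]) { emitAll("duplicated"); next }
    if (traitType(stats) != "quantitative" && !is.na(stats@nCases) &&
        stats@nCases < cfg$minCases) { emitAll("too_few_cases"); next }

    cand <- selectInstruments(stats, cfg$pMax, cfg$mafMin)
    ind <- if (is.null(ld)) cand else clump(cand, ld, cfg$r2Max)
    elig <- exposureEligible(stats, nrow(ind), cfg$minCases, cfg$minSnps)
    if (!elig$eligible) { emitAll(elig$reason); next }

    # per-SD instrument scale for R2/F; estimation scale via transformation
    mu <- caseFraction(stats)
    indSD <- ind
    if (traitType(stats) == "binary_linear")
      indSD$beta <- ind$beta / sqrt(mu * (1 - mu))
    estStats <- if (traitType(stats) == "binary_linear")
      linearToLogodds(stats) else stats
    estInstr <- variants(estStats)[
      match(ind$snp_id, variants(estStats)$snp_id), , drop = FALSE]

    r2 <- varianceExplained(indSD)
    fst <- fStatistic(r2, stats@nTotal, nrow(ind))

    for (ot in names(outcomes)) {
      outc <- outcomes[[ot]]
      muY <- if (!is.na(outc@nCases)) outc@nCases / outc@nTotal else 0.5
      pw <- powerBinary(outc@nTotal, muY, r2, cfg$orHyp, cfg$alphaPower)

      h <- tryCatch(
        harmonizePair(estInstr, outc, cfg$palindromicMafMax,
                      cfg$eafTolerance, exposureId = id),
        error = function(err) NULL)
      if (is.null(h) || nSnps(h) < 2) {
        rr <- .excludedRow(id, ot, if (is.null(h))
          "no_harmonizable_instruments" else "too_few_instruments", meta)
        rr$r2 <- r2; rr$f_stat <- fst$f; rr$power <- pw
        rr$n_instruments <- nrow(ind)
        rows[[length(rows) + 1L]] <- rr
        next
      }
      J <- nSnps(h)

      ivw <- mrIVW(h)
      egg <- if (J >= 3) tryCatch(mrEgger(h), error = function(err) NULL)
             else NULL
      wm <- if (J >= 3)
        mrWeightedMedian(h, cfg$wmNboot,
                         seed = substreamSeed(cfg$seed, id, ot, "wm"))
        else NULL
      pr <- if (J >= 4)
        pressoTest(h, cfg$pressoNsim,
                   seed = substreamSeed(cfg$seed, id, ot, "presso"))
        else NULL

      conc <- NA
      concSet <- list(ivw = if (!is.null(pr) && !is.null(pr@corrected))
        pr@corrected else ivw$estimate)
      if (!is.null(wm)) concSet$weighted_median <- wm
      if (!is.null(egg)) concSet$egger_slope <- egg$slope
      if (length(concSet) >= 2) conc <- concordantEstimates(concSet)

      rows[[length(rows) + 1L]] <- data.frame(
        exposure_id = id, category = meta$category, domain = meta$domain,
        outcome = ot, eligible = TRUE, reason = "ok",
        n_instruments = nrow(ind), n_harmonized = J,
        r2 = r2, f_stat = fst$f, power = pw,
        beta_ivw = betaHat(ivw$estimate), se_ivw = stdErr(ivw$estimate),
        pval_ivw = pValue(ivw$estimate),
        q_stat = ivw$heterogeneity@qStat,
        q_pval = pValue(ivw$heterogeneity),
        beta_egger = if (is.null(egg)) NA_real_ else betaHat(egg$slope),
        se_egger = if (is.null(egg)) NA_real_ else stdErr(egg$slope),
        pval_egger = if (is.null(egg)) NA_real_ else pValue(egg$slope),
        egger_intercept = if (is.null(egg)) NA_real_
          else betaHat(egg$intercept),
        egger_intercept_p = if (is.null(egg)) NA_real_
          else pValue(egg$intercept),
        beta_wm = if (is.null(wm)) NA_real_ else betaHat(wm),
        se_wm = if (is.null(wm)) NA_real_ else stdErr(wm),
        pval_wm = if (is.null(wm)) NA_real_ else pValue(wm),
        presso_global_p = if (is.null(pr)) NA_real_ else pr@globalP,
        n_outliers = if (is.null(pr)) NA_integer_
          else length(outliers(pr)),
        beta_presso = if (is.null(pr) || is.null(pr@corrected)) NA_real_
          else betaHat(pr@corrected),
        q_fdr = NA_real_, tier = NA_character_, concordant = conc,
        stringsAsFactors = FALSE)
      details[[paste(id, ot, sep = "::")]] <-
        list(harmonized = h, ivw = ivw, egger = egg, wm = wm, presso = pr)
    }
  }

  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  # FDR within each outcome separately, over eligible exposures only
  for (ot in names(outcomes)) {
    sel <- rec$outcome == ot & rec$eligible
    if (any(sel)) {
      rec$q_fdr[sel] <- fdrAdjust(rec$pval_ivw[sel])
      rec$tier[sel] <- classifyTier(rec$pval_ivw[sel], rec$q_fdr[sel], cfg)
    }
  }
  structure(list(records = rec, details = details, config = cfg),
            class = "ScreenResult")
}

#' Merge screen and validation results into component calls
#'
#' Implements the component-of-the-exposome decision rule: an exposure
#' validated as significant in independent data is a component; an
#' exposure whose validation is null despite high power (at or above
#' \code{cfg$powerThresholdValidation}) is excluded; otherwise an
#' exposure robust in the screen (significant or suggestive for both
#' outcomes with concordant estimators) is a component flagged
#' unvalidated, and the remainder inherit their screen status.
#'
#' @param screen records data.frame from \code{\link{runScreen}} (or a
#'   ScreenResult).
#' @param validation records data.frame from an independent-exposure
#'   screen, or NULL when no validation data exist; must carry
#'   \code{power} when exclusion-by-power is to apply.
#' @param cfg a \code{\link{screenConfig}}.
#' @param primary,secondary outcome tags (defaults \code{"p90"},
#'   \code{"p99"}).
#' @return data.frame with one row per screened exposure:
#'   \code{exposure_id}, screen tiers, \code{concordant},
#'   \code{validation_tier}, \code{validation_power}, \code{component},
#'   \code{flag}.
#' @export
mergeValidation <- function(screen, validation = NULL, cfg,
                            primary = "p90", secondary = "p99") {
  if (inherits(screen, "ScreenResult")) screen <- screen$records
  if (inherits(validation, "ScreenResult")) validation <- validation$records
  ids <- unique(screen$exposure_id)
  if (!is.null(validation)) {
    stray <- setdiff(unique(validation$exposure_id), ids)
    if (length(stray))
      warning("validation exposures absent from screen: ",
              paste(stray, collapse = ", "))
  }
  pick <- function(df, id, ot) {
    r <- df[df$exposure_id == id & df$outcome == ot, , drop = FALSE]
    if (nrow(r)) r[1L, ] else NULL
  }
  out <- lapply(ids, function(id) {
    rp <- pick(screen, id, primary)
    rs <- pick(screen, id, secondary)
    tp <- if (is.null(rp)) NA_character_ else rp$tier
    ts <- if (is.null(rs)) NA_character_ else rs$tier
    conc <- if (is.null(rp)) NA else rp$concordant
    robustBoth <- !is.na(tp) && !is.na(ts) &&
      tp %in% c("significant", "suggestive") &&
      ts %in% c("significant", "suggestive") && isTRUE(conc)

    vrow <- NULL
    if (!is.null(validation)) {
      vr <- validation[validation$exposure_id == id, , drop = FALSE]
      if (nrow(vr)) vrow <- vr[1L, ]
    }
    vTier <- if (is.null(vrow)) NA_character_ else vrow$tier
    vPower <- if (is.null(vrow) || is.null(vrow$power)) NA_real_
      else vrow$power

    if (!is.na(vTier) && vTier == "significant") {
      component <- TRUE; flag <- "validated"
    } else if (!is.na(vTier) && vTier == "null" && !is.na(vPower) &&
               vPower >= cfg$powerThresholdValidation) {
      component <- FALSE; flag <- "excluded_validation"
    } else if (robustBoth) {
      component <- TRUE; flag <- "unvalidated"
    } else {
      component <- !is.na(tp) && tp == "significant" && isTRUE(conc)
      flag <- "unvalidated"
    }
    data.frame(exposure_id = id, tier_primary = tp, tier_secondary = ts,
               concordant = conc, validation_tier = vTier,
               validation_power = vPower, component = component,
               flag = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
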