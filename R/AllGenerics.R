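#' @include AllClasses.R
NULL

#' Accessors for exposomeMR classes
#'
#' @param object an exposomeMR S4 object.
#' @name accessors
#' @return \code{traitId}, \code{traitType}: character scalars.
#'   \code{caseFraction}: numeric case fraction or NA. \code{variants},
#'   \code{records}, \code{actions}, \code{perSnp}: data.frames.
#'   \code{nVariants}, \code{nSnps}: integer counts. \code{betaHat},
#'   \code{stdErr}, \code{pValue}: numeric scalars. \code{outliers},
#'   \code{snpIds}: character vectors.
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(object) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("caseFraction", function(object) standardGeneric("caseFraction"))
#' @rdname accessors
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("actions", function(object) standardGeneric("actions"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("betaHat", function(object) standardGeneric("betaHat"))
#' @rdname accessors
#' @export
setGeneric("stdErr", function(object) standardGeneric("stdErr"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("outliers", function(object) standardGeneric("outliers"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("perSnp", function(object) standardGeneric("perSnp"))

#' Write a result collection as tab-separated text
#'
#' @param records object to write.
#' @param path output file path.
#' @param allowEmpty allow writing an empty collection (header only).
#' @export
setGeneric("writeTable",
  function(records, path, allowEmpty = FALSE) standardGeneric("writeTable"))

#' @rdname accessors
setMethod("traitId", "SummaryStats", function(object) object@traitId)
#' @rdname accessors
setMethod("traitType", "SummaryStats", function(object) object@traitType)
#' @rdname accessors
setMethod("caseFraction", "SummaryStats", function(object) object@caseFraction)
#' @rdname accessors
setMethod("variants", "SummaryStats", function(object) object@variants)
#' @rdname accessors
setMethod("nVariants", "SummaryStats", function(object) nrow(object@variants))

#' @rdname accessors
setMethod("records", "HarmonizedSet", function(object) object@records)
#' @rdname accessors
setMethod("actions", "HarmonizedSet", function(object) object@actions)
#' @rdname accessors
setMethod("nSnps", "HarmonizedSet", function(object) nrow(object@records))

#' @rdname accessors
setMethod("betaHat", "MREstimate", function(object) object@betaHat)
#' @rdname accessors
setMethod("stdErr", "MREstimate", function(object) object@se)
#' @rdname accessors
setMethod("pValue", "MREstimate", function(object) object@pval)
#' @rdname accessors
setMethod("nSnps", "MREstimate", function(object) object@nSnps)

#' @rdname accessors
setMethod("pValue", "HeterogeneityResult", function(object) object@pval)

#' @rdname accessors
setMethod("outliers", "PressoResult", function(object) object@outliers)
#' @rdname accessors
setMethod("pValue", "PressoResult", function(object) object@globalP)
#' @rdname accessors
setMethod("perSnp", "PressoResult", function(object) object@perSnp)

#' @rdname accessors
setMethod("snpIds", "LDMatrix", function(object) object@snpIds)

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats:", object@traitId, sprintf("(%s)\n", object@traitType))
  cat(" ", nrow(object@variants), "variants; n =", object@nTotal)
  if (!is.na(object@nCases)) cat("; cases =", object@nCases)
  cat("\n")
  if (!is.na(object@caseFraction))
    cat("  case fraction mu =", format(object@caseFraction, digits = 4), "\n")
  if (length(object@dropLog) && sum(object@dropLog))
    cat("  rows dropped at read:",
        paste(names(object@dropLog), object@dropLog, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", object@exposureId, "->", object@outcomeId, "\n")
  cat(" ", nrow(object@records), "instruments kept of",
      nrow(object@actions), "candidates\n")
  tab <- table(object@actions$action)
  cat("  actions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]: beta = %.4g (SE %.4g), OR = %.3f [%.3f, %.3f], p = %.3g, J = %d\n",
              object@method, object@betaHat, object@se, object@orPoint,
              object@ciLow, object@ciHigh, object@pval, object@nSnps))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
              object@qStat, object@df, object@pval))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.4g, global p = %.4g (%d sims)\n",
              object@rssObs, object@globalP, object@nSim))
  if (length(object@outliers))
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix:", length(object@snpIds), "variants\n")
})
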