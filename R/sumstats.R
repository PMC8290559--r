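#' @include AllClasses.R AllGenerics.R
NULL

#' Column-mapping dialect for summary-statistics files
#'
#' Maps the canonical column names used internally (\code{snp},
#' \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#' \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n},
#' \code{n_cases}) onto the headers of a particular file. A compound
#' variant column such as \code{"1:1000:A:G"} can be decomposed by giving
#' \code{variantSplit}: the components are then taken as chrom, pos,
#' effect allele, other allele (the snp_id keeps the compound string).
#'
#' @param snp,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n,n_cases
#'   header names in the file; set a field to \code{NULL} when absent.
#' @param variantSplit single character on which to split a compound
#'   variant column into chrom:pos:effect:other, or \code{NULL}.
#' @return A list of class \code{"sumstatsDialect"}.
#' @export
sumstatsDialect <- function(snp = "snp", chrom = "chrom", pos = "pos",
                            effect_allele = "effect_allele",
                            other_allele = "other_allele",
                            eaf = "eaf", beta = "beta", se = "se",
                            pval = "pval", n = "n", n_cases = NULL,
                            variantSplit = NULL) {
  structure(list(snp = snp, chrom = chrom, pos = pos,
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                 n_cases = n_cases, variantSplit = variantSplit),
            class = "sumstatsDialect")
}

PVAL_FLOOR <- 1e-300

#' Read GWAS summary statistics from tab-separated text
#'
#' Reads a header-bearing TSV, maps columns through the dialect, and
#' enforces the per-variant invariants: single-base A/C/G/T alleles with
#' effect != other (indels and multi-allelic records excluded), se > 0,
#' eaf in (0,1) when present (missing eaf is allowed but such variants
#' cannot later resolve palindromic strand ambiguity), p in (0,1] with
#' p = 0 clipped to 1e-300, finite beta. Violating rows are dropped and
#' counted in the returned object's drop log; duplicated snp_ids keep the
#' first occurrence.
#'
#' @param path file path.
#' @param dialect a \code{\link{sumstatsDialect}}.
#' @param traitId trait identifier; defaults to the file base name.
#' @param traitType trait type (see \linkS4class{SummaryStats}).
#' @param caseFraction case fraction for \code{binary_linear} traits.
#' @param nCases case count, or NA; taken from the mapped column when
#'   present.
#' @return A \linkS4class{SummaryStats}.
#' @export
readSumstats <- function(path, dialect = sumstatsDialect(),
                         traitId = NULL, traitType = "quantitative",
                         caseFraction = NA_real_, nCases = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  if (is.null(traitId))
    traitId <- sub("\\.[^.]*$", "", basename(path))

  need <- c("snp", "beta", "se", "pval", "n")
  if (is.null(dialect$variantSplit))
    need <- c(need, "effect_allele", "other_allele")
  for (f in need) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("required column '", f, "' (mapped to '",
           if (is.null(col)) "<unmapped>" else col,
           "') not found in ", path)
  }

  pick <- function(f, default = NA) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }

  v <- data.frame(
    snp_id = as.character(pick("snp")),
    chrom = as.character(pick("chrom", NA_character_)),
    pos = suppressWarnings(as.integer(pick("pos", NA_integer_))),
    effect_allele = toupper(as.character(pick("effect_allele", NA_character_))),
    other_allele = toupper(as.character(pick("other_allele", NA_character_))),
    eaf = suppressWarnings(as.numeric(pick("eaf"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pval = suppressWarnings(as.numeric(pick("pval"))),
    n = suppressWarnings(as.numeric(pick("n"))),
    stringsAsFactors = FALSE
  )

  if (!is.null(dialect$variantSplit)) {
    parts <- strsplit(v$snp_id, dialect$variantSplit, fixed = TRUE)
    ok4 <- lengths(parts) >= 4L
    get <- function(i) vapply(parts, function(p)
      if (length(p) >= 4L) p[i] else NA_character_, character(1))
    v$chrom <- ifelse(ok4, get(1L), v$chrom)
    v$pos <- suppressWarnings(as.integer(get(2L)))
    v$effect_allele <- toupper(get(3L))
    v$other_allele <- toupper(get(4L))
  }

  drop <- c(missing_fields = 0L, bad_allele = 0L, nonpositive_se = 0L,
            bad_eaf = 0L, bad_pval = 0L, duplicate_snp = 0L)
  keep <- rep(TRUE, nrow(v))

  bad <- is.na(v$snp_id) | is.na(v$beta) | is.na(v$se) | is.na(v$pval) |
    is.na(v$n) | !is.finite(v$beta)
  drop["missing_fields"] <- sum(bad & keep); keep <- keep & !bad

  bases <- c("A", "C", "G", "T")
  bad <- !(v$effect_allele %in% bases) | !(v$other_allele %in% bases) |
    v$effect_allele == v$other_allele
  bad[is.na(bad)] <- TRUE
  drop["bad_allele"] <- sum(bad & keep); keep <- keep & !bad

  bad <- v$se <= 0
  bad[is.na(bad)] <- FALSE
  drop["nonpositive_se"] <- sum(bad & keep); keep <- keep & !bad

  # missing eaf is tolerated; out-of-range eaf is not
  bad <- !is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)
  drop["bad_eaf"] <- sum(bad & keep); keep <- keep & !bad

  v$pval[!is.na(v$pval) & v$pval == 0] <- PVAL_FLOOR
  bad <- v$pval < 0 | v$pval > 1
  bad[is.na(bad)] <- FALSE
  drop["bad_pval"] <- sum(bad & keep); keep <- keep & !bad

  # among duplicated snp_ids keep the most precise (smallest-se) valid row
  seRank <- ifelse(keep & !is.na(v$se), v$se, Inf)
  best <- !duplicated(v$snp_id[order(seRank)])[order(order(seRank))]
  drop["duplicate_snp"] <- sum(!best & keep); keep <- keep & best

  v <- v[keep, , drop = FALSE]
  if (sum(drop))
    message("readSumstats: dropped ", sum(drop), " row(s) [",
            paste(names(drop)[drop > 0], drop[drop > 0], sep = "=",
                  collapse = ", "), "] from ", basename(path))

  ncs <- pick("n_cases")
  if (is.na(nCases) && any(!is.na(ncs)))
    nCases <- suppressWarnings(max(as.numeric(ncs), na.rm = TRUE))

  SummaryStats(traitId = traitId, variants = v, traitType = traitType,
               caseFraction = caseFraction, nCases = nCases, dropLog = drop)
}

#' Convert linear-scale effects on a binary trait to log odds ratios
#'
#' Binary traits analyzed with a linear (mixed) model report betas on the
#' raw 0/1 scale. The approximate conversion to the log odds-ratio scale
#' is \eqn{\log OR = \beta / (\mu (1 - \mu))} with \eqn{\mu} the case
#' fraction; standard errors are divided by the same factor, so z-scores
#' and p-values are unchanged.
#'
#' @param stats a \linkS4class{SummaryStats} with
#'   \code{traitType == "binary_linear"}.
#' @return A \linkS4class{SummaryStats} on the log odds-ratio scale
#'   (\code{traitType == "binary_logistic"}).
#' @export
linearToLogodds <- function(stats) {
  stopifnot(is(stats, "SummaryStats"))
  if (traitType(stats) != "binary_linear")
    stop("linearToLogodds requires traitType binary_linear, got ",
         traitType(stats))
  mu <- caseFraction(stats)
  if (is.na(mu) || mu <= 0 || mu >= 1)
    stop("case fraction must lie in (0, 1)")
  f <- mu * (1 - mu)
  v <- variants(stats)
  v$beta <- v$beta / f
  v$se <- v$se / f
  SummaryStats(traitId = traitId(stats), variants = v,
               traitType = "binary_logistic", caseFraction = mu,
               nTotal = stats@nTotal, nCases = stats@nCases,
               dropLog = stats@dropLog)
}

.writeTSV <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' @describeIn writeTable Write any data.frame of results; floats are
#'   rendered with 17 significant digits so a re-read reproduces them
#'   bit-equal.
setMethod("writeTable", "data.frame", function(records, path, allowEmpty = FALSE) {
  if (nrow(records) == 0L && !allowEmpty)
    stop("refusing to write an empty collection (set allowEmpty = TRUE)")
  .writeTSV(records, path)
  invisible(NULL)
})

#' @describeIn writeTable Write the variant table of a SummaryStats in the
#'   canonical column order.
setMethod("writeTable", "SummaryStats", function(records, path, allowEmpty = FALSE) {
  v <- variants(records)
  if (nrow(v) == 0L && !allowEmpty)
    stop("refusing to write an empty collection (set allowEmpty = TRUE)")
  names(v)[names(v) == "snp_id"] <- "snp"
  .writeTSV(v, path)
  invisible(NULL)
})
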