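# Fixture builders shared across test files. Everything is generated in
# code; no data files.

makeHarmonized <- function(bx, by, sy, sx = rep(0.003, length(bx)),
                           ids = sprintf("s%03d", seq_along(bx)),
                           eaf = rep(0.3, length(bx))) {
  new("HarmonizedSet", exposureId = "X", outcomeId = "Y",
      records = data.frame(snp_id = ids, beta_x = bx, se_x = sx,
                           beta_y = by, se_y = sy, eaf_x = eaf,
                           eaf_y = eaf, stringsAsFactors = FALSE),
      actions = data.frame(snp_id = ids, action = "kept_direct",
                           stringsAsFactors = FALSE))
}

makeVariants <- function(n, seed = 1, effect = "A", other = "G") {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%04d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = rep_len(effect, n), other_allele = rep_len(other, n),
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.05), se = runif(n, 0.003, 0.02),
    pval = runif(n, 1e-12, 1), n = 10000,
    stringsAsFactors = FALSE)
}

randomSumstats <- function(n, seed = 1, traitId = "trait") {
  SummaryStats(traitId, makeVariants(n, seed))
}

# three-SNP exactly proportional toy: theta = 0.5, Q = 0
proportionalToy <- function() {
  makeHarmonized(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15),
                 sy = rep(0.01, 3))
}

# exact affine toy: slope 0.5, intercept 0.02, zero residuals
affineToy <- function() {
  makeHarmonized(bx = c(0.1, 0.2, 0.3), by = c(0.07, 0.12, 0.17),
                 sy = rep(0.01, 3))
}

# independent brute-force BH step-up, used as the FDR oracle
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(cands))
  }
  q
}

# closed-form weighted regression through the origin (IVW oracle)
wlsOriginOracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}
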