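#' Derive a reproducible substream seed
#'
#' Mixes a master seed with any number of integer or character labels
#' (e.g. exposure id, outcome tag, replicate index) into a deterministic
#' 31-bit seed, so any single unit of a large run can be reproduced in
#' isolation.
#'
#' @param seed master integer seed.
#' @param ... labels (integers or strings) identifying the substream.
#' @return integer in [1, 2^31 - 2].
#' @export
substreamSeed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  acc <- as.numeric(seed) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(paste(lab, collapse = "|"))
             else as.numeric(lab)
    for (cc in codes) acc <- (acc * 69069 + cc + 1) %% m
  }
  as.integer(acc %% (m - 2) + 1)
}
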