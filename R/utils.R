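## Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
## Used to derive per-(gene, miRNA) bootstrap substreams from one master seed
## so serial and parallel runs see identical resampling index streams.
.stringHash <- function(s) {
    codes <- utf8ToInt(s)
    h <- 0
    m <- 2147483647  # 2^31 - 1; 31 * h + 255 < 2^53, exact in doubles
    for (k in codes) h <- (h * 31 + k) %% m
    h
}

#' Derive a reproducible substream seed
#'
#' Combines a master seed with a character key (e.g. `"IL8|hsa-miR-17-5p"`)
#' into a seed below 2^31, stable across platforms and run order.
#'
#' @param masterSeed single integer-valued number
#' @param key single string
#' @return integer seed
#' @export
substreamSeed <- function(masterSeed, key) {
    stopifnot(length(masterSeed) == 1L, is.finite(masterSeed),
              length(key) == 1L, is.character(key))
    as.integer((abs(masterSeed) + .stringHash(key)) %% 2147483647)
}

## truncated-normal draw by resampling; bounds are inclusive
.rnormTrunc <- function(n, mean, sd, lower, upper) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < lower | x > upper)
    while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- which(x < lower | x > upper)
    }
    x
}

.assertProb <- function(p, what = "p") {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop(sprintf("'%s' must lie in [0, 1] with no missing values", what))
    invisible(p)
}
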