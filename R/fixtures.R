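#' Published result tables as machine-readable fixtures
#'
#' The study's printed tables, transcribed cell-for-cell to tab-separated
#' files shipped under `inst/extdata/` so counting and classification logic
#' can be exercised against the published numbers without any download:
#'
#' * `nfkbTable1()`: cohort description counts (`category`, `level`, `n`);
#'   217 cases, 169 colon / 48 rectal, 29 MSI.
#' * `nfkbTable2()`: paired pathway differential expression, 92 genes
#'   (`gene`, `tumour_mean`, `normal_mean`, `fold_change`, `raw_p`,
#'   `fdr_p`). Means and fold changes are as printed (2 decimals).
#' * `nfkbTable3()`: the 76 significant gene/miRNA associations (gene and
#'   miRNA group means and fold changes, printed raw and gene-level FDR
#'   p-values, seed-match and discordant-slope indicators). Censored raw
#'   p-values are kept verbatim as the string `"<0.0001"`.
#'
#' @return a `data.frame` per table
#' @name fixtures
NULL

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "nfkbMirNet",
                        mustWork = TRUE)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
}

#' @rdname fixtures
#' @export
nfkbTable1 <- function() .extdata("table1_cohort.tsv")

#' @rdname fixtures
#' @export
nfkbTable2 <- function() .extdata("table2_pathway_de.tsv")

#' @rdname fixtures
#' @export
nfkbTable3 <- function() {
    tab <- .extdata("table3_associations.tsv")
    tab$seed_match <- tab$seed_match == 1L
    tab$discordant_beta <- tab$discordant_beta == 1L
    tab
}
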