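#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom stats median quantile
NULL

.UNIVERSES <- c("protein_coding", "pathway", "mirna")
.SCALES <- c("raw_counts", "raw_intensity", "rpmpcg", "normalized_intensity")

#' Tagged expression matrix
#'
#' A features-by-samples matrix carried as a
#' [SummarizedExperiment::SummarizedExperiment] with two extra slots recording
#' which feature universe the rows come from (`protein_coding`, `pathway` or
#' `mirna`) and on which scale the values live (`raw_counts`, `raw_intensity`,
#' `rpmpcg` or `normalized_intensity`). Scale transitions happen only through
#' the normalization functions ([computeRPMPCG()], [normalizeMirna()]), so a
#' downstream stage can assert it was handed the scale it expects.
#'
#' @slot universe single string, one of `"protein_coding"`, `"pathway"`,
#'   `"mirna"`.
#' @slot scale single string, one of `"raw_counts"`, `"raw_intensity"`,
#'   `"rpmpcg"`, `"normalized_intensity"`.
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    slots = c(universe = "character", scale = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character(0)
    if (length(object@universe) != 1L || !object@universe %in% .UNIVERSES)
        msg <- c(msg, sprintf("'universe' must be one of: %s",
                              paste(.UNIVERSES, collapse = ", ")))
    if (length(object@scale) != 1L || !object@scale %in% .SCALES)
        msg <- c(msg, sprintf("'scale' must be one of: %s",
                              paste(.SCALES, collapse = ", ")))
    v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "feature and sample names are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicated feature ids: %s",
            paste(unique(rownames(object)[duplicated(rownames(object))]),
                  collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, sprintf("duplicated sample ids: %s",
            paste(unique(colnames(object)[duplicated(colnames(object))]),
                  collapse = ", ")))
    if (anyNA(v))
        msg <- c(msg, "missing values are not allowed")
    else if (any(v < 0))
        msg <- c(msg, "negative values are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   row and column names. Counts must be non-negative; no missing cells.
#' @param universe feature universe tag (see [ExpressionMatrix-class]).
#' @param scale value-scale tag.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, universe = "protein_coding", scale = "raw_counts")
#' @export
ExpressionMatrix <- function(values,
                             universe = c("protein_coding", "pathway",
                                          "mirna"),
                             scale = c("raw_counts", "raw_intensity",
                                       "rpmpcg", "normalized_intensity")) {
    universe <- match.arg(universe)
    scale <- match.arg(scale)
    if (!is.matrix(values))
        values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("ExpressionMatrix", se, universe = universe, scale = scale)
}

## internal: retag the scale after a sanctioned transition
.retag <- function(x, universe = x@universe, scale = x@scale) {
    x@universe <- universe
    x@scale <- scale
    validObject(x)
    x
}

#' Synthetic paired cohort
#'
#' Output of [simulateCohort()]: gene counts, raw miRNA intensities, sample
#' metadata, and the generating truth (parameters plus realized per-subject
#' random effects, library exposures, per-sample array scale factors and
#' per-subject miRNA paired differences) so that recovery tests can compare
#' estimates against what was planted.
#'
#' @slot counts [ExpressionMatrix-class], protein-coding raw counts.
#' @slot mirna [ExpressionMatrix-class], raw (pre-normalization) intensities.
#' @slot meta `data.frame` of per-sample metadata (see [validateSampleMeta()]).
#' @slot truth named `list` of generating parameters and realized effects.
#' @export
setClass("SyntheticCohort",
    slots = c(counts = "ExpressionMatrix", mirna = "ExpressionMatrix",
              meta = "data.frame", truth = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character(0)
    meta <- object@meta
    tab <- table(meta$subject_id, meta$tissue)
    if (!all(tab == 1L))
        msg <- c(msg, "each subject needs exactly one tumour and one normal sample")
    v <- SummarizedExperiment::assay(object@counts, withDimnames = FALSE)
    if (any(v != floor(v)))
        msg <- c(msg, "counts must be integers")
    if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticCohort-class gene count matrix accessor
#' @param x a `SyntheticCohort`
#' @export
cohortCounts <- function(x) x@counts

#' @describeIn SyntheticCohort-class raw miRNA intensity accessor
#' @export
cohortMirna <- function(x) x@mirna

#' @describeIn SyntheticCohort-class sample metadata accessor
#' @export
cohortMeta <- function(x) x@meta

#' @describeIn SyntheticCohort-class generating-truth accessor
#' @export
cohortTruth <- function(x) x@truth
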