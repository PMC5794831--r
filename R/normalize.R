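#' Reads per million protein-coding genes (RPMPCG)
#'
#' A gene's expression level in a sample is its count divided by the sample's
#' total count over all protein-coding genes, times 10^6. The denominator is
#' always the full protein-coding universe of the input matrix, also when the
#' result is restricted to a pathway gene subset, so RPMPCG values are
#' comparable across gene subsets.
#'
#' @param counts [ExpressionMatrix-class] with universe `protein_coding` and
#'   scale `raw_counts`
#' @param geneSubset optional character vector of genes to keep in the output
#'   (must all be present in `counts`); the output universe is then tagged
#'   `pathway`
#' @return [ExpressionMatrix-class] on the `rpmpcg` scale
#' @examples
#' m <- matrix(c(5, 999995, 10, 999990), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "protein_coding", "raw_counts")
#' exprValues(computeRPMPCG(em))["g1", ]  # 5 and 10 RPMPCG
#' @export
computeRPMPCG <- function(counts, geneSubset = NULL) {
    stopifnot(is(counts, "ExpressionMatrix"))
    if (universe(counts) != "protein_coding" ||
        exprScale(counts) != "raw_counts")
        stop("'counts' must be protein-coding raw counts")
    v <- exprValues(counts)
    totals <- colSums(v)
    if (any(totals <= 0))
        stop("zero protein-coding total in sample(s): ",
             paste(colnames(v)[totals <= 0], collapse = ", "))
    rpm <- sweep(v, 2L, totals, "/") * 1e6
    uni <- "protein_coding"
    if (!is.null(geneSubset)) {
        missing <- setdiff(geneSubset, rownames(rpm))
        if (length(missing))
            stop("gene(s) not in the count matrix: ",
                 paste(missing, collapse = ", "))
        rpm <- rpm[geneSubset, , drop = FALSE]
        uni <- "pathway"
    }
    ExpressionMatrix(rpm, universe = uni, scale = "rpmpcg")
}

#' 75th-percentile scaling of miRNA array intensities
#'
#' Each sample is multiplied by a scaling factor equal to the median of the
#' 75th percentiles of all samples divided by that sample's own 75th
#' percentile, so that after scaling every sample's 75th percentile equals
#' the cross-sample median of the pre-scaling 75th percentiles.
#'
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); the convention is configurable via `type`.
#'
#' @param intensities [ExpressionMatrix-class], universe `mirna`, scale
#'   `raw_intensity`, at least two samples
#' @param prob percentile used for scaling (default 0.75)
#' @param type quantile type passed to [stats::quantile()]
#' @return list with elements `normalized` (an [ExpressionMatrix-class] on
#'   the `normalized_intensity` scale) and `report` (class
#'   `NormalizationReport`: per-sample percentiles, their median, and the
#'   per-sample scaling factors)
#' @export
normalizeMirna <- function(intensities, prob = 0.75, type = 7) {
    stopifnot(is(intensities, "ExpressionMatrix"))
    if (universe(intensities) != "mirna" ||
        exprScale(intensities) != "raw_intensity")
        stop("'intensities' must be raw miRNA intensities")
    v <- exprValues(intensities)
    if (ncol(v) < 2L)
        stop("at least two samples are required")
    q <- apply(v, 2L, stats::quantile, probs = prob, type = type,
               names = FALSE)
    if (any(q <= 0))
        stop("zero ", prob * 100, "th percentile in sample(s): ",
             paste(colnames(v)[q <= 0], collapse = ", "))
    m <- stats::median(q)
    factors <- m / q
    out <- sweep(v, 2L, factors, "*")
    report <- structure(
        list(prob = prob, quantile_type = type,
             per_sample_percentile = stats::setNames(q, colnames(v)),
             median_percentile = m,
             scaling_factor = stats::setNames(factors, colnames(v))),
        class = "NormalizationReport")
    list(normalized = ExpressionMatrix(out, universe = "mirna",
                                       scale = "normalized_intensity"),
         report = report)
}

#' @export
print.NormalizationReport <- function(x, ...) {
    cat(sprintf(
        "NormalizationReport: %d samples, %g%% percentile scaling (type %d)\n",
        length(x$scaling_factor), x$prob * 100, x$quantile_type))
    cat(sprintf("  median percentile %.4g; factors in [%.4g, %.4g]\n",
                x$median_percentile, min(x$scaling_factor),
                max(x$scaling_factor)))
    invisible(x)
}

#' Prevalence filter for miRNAs
#'
#' Keeps miRNAs expressed (value strictly above `floor`) in strictly more
#' than `threshold` of the normal-mucosa samples. A miRNA detected in exactly
#' 20% of normals is dropped at the default threshold.
#'
#' @param intensities [ExpressionMatrix-class], universe `mirna`
#' @param meta sample metadata identifying the normal samples
#' @param threshold prevalence proportion in (0, 1), default 0.20
#' @param floor detection floor; "expressed" means value > floor (default 0)
#' @return the filtered [ExpressionMatrix-class]; dropped miRNA ids are
#'   attached as attribute `"dropped"`
#' @export
filterMirnaPrevalence <- function(intensities, meta, threshold = 0.20,
                                  floor = 0) {
    stopifnot(is(intensities, "ExpressionMatrix"),
              universe(intensities) == "mirna")
    if (threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie in (0, 1)")
    validateSampleMeta(meta)
    v <- exprValues(intensities)
    normals <- intersect(meta$sample_id[meta$tissue == "normal"],
                         colnames(v))
    if (length(normals) == 0L)
        stop("no normal samples found")
    prev <- rowMeans(v[, normals, drop = FALSE] > floor)
    keep <- prev > threshold
    out <- intensities[keep, ]
    attr(out, "dropped") <- rownames(v)[!keep]
    out
}

#' Expression filter for genes
#'
#' Drops genes with zero counts in every sample or undetected (count 0) in
#' strictly more than half of the samples.
#'
#' @param counts [ExpressionMatrix-class] of raw counts
#' @param geneSet optional gene ids to restrict to (ids absent from the
#'   matrix count as dropped, with reason `absent`)
#' @return list with character vectors `kept` and `dropped`, the latter
#'   carrying a `reasons` attribute parallel to it
#' @export
filterGeneExpression <- function(counts, geneSet = NULL) {
    stopifnot(is(counts, "ExpressionMatrix"))
    v <- exprValues(counts)
    genes <- if (is.null(geneSet)) rownames(v) else geneSet
    absent <- setdiff(genes, rownames(v))
    present <- intersect(genes, rownames(v))
    sub <- v[present, , drop = FALSE]
    zeroFrac <- rowMeans(sub == 0)
    allZero <- rowSums(sub) == 0
    drop <- allZero | zeroFrac > 0.5
    reasons <- ifelse(allZero[drop], "not_expressed", "mostly_missing")
    dropped <- c(absent, present[drop])
    attr(dropped, "reasons") <- c(rep("absent", length(absent)), reasons)
    list(kept = present[!drop], dropped = dropped)
}
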