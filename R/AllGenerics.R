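#' Feature-universe tag of an ExpressionMatrix
#' @param x an [ExpressionMatrix-class]
#' @return single string
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname universe
#' @export
setMethod("universe", "ExpressionMatrix", function(x) x@universe)

#' Value-scale tag of an ExpressionMatrix
#' @param x an [ExpressionMatrix-class]
#' @return single string
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname exprScale
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' Expression values as a base matrix
#' @param x an [ExpressionMatrix-class]
#' @return numeric matrix with feature rownames and sample colnames
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d features x %d samples [%s, %s]\n",
                nrow(object), ncol(object), object@universe, object@scale))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf(
        "SyntheticCohort: %d subjects, %d genes, %d miRNAs\n",
        length(unique(object@meta$subject_id)),
        nrow(object@counts), nrow(object@mirna)))
    pf <- object@truth$plantedFc
    pc <- object@truth$plantedCouplings
    cat(sprintf("  planted fold changes: %d; planted couplings: %d\n",
                length(pf), if (is.null(pc)) 0L else nrow(pc)))
})
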