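#' Read a feature-by-sample expression table
#'
#' Expects a tab-separated file whose first column holds feature ids and whose
#' header row holds sample ids. Duplicated feature or sample ids, missing
#' cells and negative values are rejected with an informative error.
#'
#' @param path file path
#' @param universe,scale tags for the resulting [ExpressionMatrix-class]
#' @return an [ExpressionMatrix-class]
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, universe, scale) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("expected a feature-id column plus at least one sample column")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop(sprintf("duplicated feature id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    sids <- colnames(tab)[-1L]
    if (anyDuplicated(sids))
        stop(sprintf("duplicated sample id(s): %s",
                     paste(unique(sids[duplicated(sids)]), collapse = ", ")))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric cells in expression table")
    if (anyNA(m))
        stop("missing cells in expression table")
    dimnames(m) <- list(ids, sids)
    ExpressionMatrix(m, universe = universe, scale = scale)
}

#' Write an expression matrix as tab-separated text
#'
#' Feature-major, UTF-8, unquoted; first column `feature_id`, then one column
#' per sample. [readExpressionMatrix()] of the result round-trips.
#'
#' @param x an [ExpressionMatrix-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeExpressionMatrix <- function(x, path) {
    v <- exprValues(x)
    out <- data.frame(feature_id = rownames(v), v,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

.META_COLS <- c("sample_id", "subject_id", "tissue", "age", "sex",
                "msi_status")

#' Validate a sample metadata table
#'
#' One row per tissue sample: `sample_id`, `subject_id`,
#' `tissue` (`tumour`/`normal`), `age` (years), `sex` (`male`/`female`),
#' `msi_status` (`MSI`/`MSS`/`unknown`). Sample ids must be unique and each
#' subject may contribute at most one tumour and one normal sample. With
#' `strictness = "study"` ages must fall in the recruitment window
#' \[30, 79\]; the default `"lenient"` skips that check so synthetic cohorts
#' need not mimic recruitment bounds.
#'
#' @param meta data.frame
#' @param strictness `"lenient"` (default) or `"study"`
#' @return `meta`, invisibly, with character columns
#' @export
validateSampleMeta <- function(meta, strictness = c("lenient", "study")) {
    strictness <- match.arg(strictness)
    missing <- setdiff(.META_COLS, colnames(meta))
    if (length(missing))
        stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
    for (col in c("sample_id", "subject_id", "tissue", "sex", "msi_status"))
        meta[[col]] <- as.character(meta[[col]])
    if (anyDuplicated(meta$sample_id))
        stop("duplicated sample_id(s): ",
             paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                   collapse = ", "))
    if (!all(meta$tissue %in% c("tumour", "normal")))
        stop("'tissue' must be 'tumour' or 'normal'")
    if (!all(meta$sex %in% c("male", "female")))
        stop("'sex' must be 'male' or 'female'")
    if (!all(meta$msi_status %in% c("MSI", "MSS", "unknown")))
        stop("'msi_status' must be 'MSI', 'MSS' or 'unknown'")
    if (nrow(meta)) {
        dup <- stats::aggregate(seq_len(nrow(meta)),
                                by = list(subject = meta$subject_id,
                                          tissue = meta$tissue),
                                FUN = length)
        if (any(dup$x > 1L))
            stop("subject(s) with more than one sample of the same tissue: ",
                 paste(unique(dup$subject[dup$x > 1L]), collapse = ", "))
    }
    if (strictness == "study" && any(meta$age < 30 | meta$age > 79))
        stop("ages outside the study recruitment window [30, 79]")
    invisible(meta)
}

#' Read / write sample metadata
#'
#' Tab-separated, one row per sample; see [validateSampleMeta()] for the
#' required columns.
#'
#' @param path file path
#' @param strictness forwarded to [validateSampleMeta()]
#' @return `readSampleMeta`: a validated `data.frame`.
#' @export
readSampleMeta <- function(path, strictness = "lenient") {
    meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if ("age" %in% colnames(meta)) meta$age <- as.numeric(meta$age)
    validateSampleMeta(meta, strictness)
    meta
}

#' @rdname readSampleMeta
#' @param meta metadata `data.frame`
#' @export
writeSampleMeta <- function(meta, path) {
    utils::write.table(meta, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a multi-record FASTA file
#'
#' Sequences are upper-cased; both DNA (`T`) and RNA (`U`) alphabets are
#' accepted and preserved as read (any U/T conversion is done inside the
#' seed-matching step, not here). Record ids are the first whitespace-token
#' of each header. Empty sequences, duplicate ids and letters outside
#' `ACGTUN` are rejected.
#'
#' @param path FASTA file path
#' @return named character vector of sequences, in file order
#' @export
readFastaSequences <- function(path) {
    set <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicated FASTA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(set))
    if (any(nchar(seqs) == 0L))
        stop("empty sequence for id(s): ",
             paste(ids[nchar(seqs) == 0L], collapse = ", "))
    bad <- grepl("[^ACGTUN]", seqs)
    if (any(bad))
        stop("letters outside ACGTUN in record(s): ",
             paste(ids[bad], collapse = ", "))
    names(seqs) <- ids
    seqs
}

#' @rdname readFastaSequences
#' @param seqs named character vector of sequences
#' @export
writeFastaSequences <- function(seqs, path) {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("'seqs' must have unique names")
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Pair tumour and normal samples by subject
#'
#' Returns the subjects that contribute both a tumour and a normal sample;
#' subjects missing either tissue are excluded with a message. A subject with
#' two samples of the same tissue is a validation error (via
#' [validateSampleMeta()]).
#'
#' @param meta sample metadata `data.frame`
#' @return `data.frame` with columns `subject_id`, `tumour`, `normal`
#'   (sample ids), one row per complete pair
#' @export
pairSamples <- function(meta) {
    validateSampleMeta(meta)
    if (nrow(meta) == 0L)
        return(data.frame(subject_id = character(0), tumour = character(0),
                          normal = character(0), stringsAsFactors = FALSE))
    tum <- meta[meta$tissue == "tumour", c("subject_id", "sample_id")]
    nor <- meta[meta$tissue == "normal", c("subject_id", "sample_id")]
    pairs <- merge(tum, nor, by = "subject_id",
                   suffixes = c(".tumour", ".normal"))
    excluded <- setdiff(unique(meta$subject_id), pairs$subject_id)
    if (length(excluded))
        message(length(excluded), " subject(s) without both tissues excluded: ",
                paste(excluded, collapse = ", "))
    pairs <- pairs[order(pairs$subject_id), , drop = FALSE]
    data.frame(subject_id = pairs$subject_id,
               tumour = pairs$sample_id.tumour,
               normal = pairs$sample_id.normal,
               stringsAsFactors = FALSE, row.names = NULL)
}
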