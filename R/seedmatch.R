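#' Extract a miRNA seed region
#'
#' The canonical seed window starts at position 2 of the mature miRNA: the
#' 6-mer seed is positions 2-7, the 7-mer 2-8 and the 8-mer 2-9 (1-based).
#' Sequences are handled in the RNA alphabet; a `T` in the input is read as
#' `U`. A window containing an ambiguous base (`N`) is flagged by returning
#' `NA` with a warning and is excluded from matching.
#'
#' @param mirnaSeq mature miRNA sequence (single string, ACGU/ACGT plus N)
#' @param length seed length, one of 6, 7, 8
#' @param offset 1-based start of the seed window (default 2, the canonical
#'   convention)
#' @return seed as an RNA string, or `NA` if the window is ambiguous
#' @examples
#' extractSeed("UAGCUUAUCAGACUGAUGUUGA", 6)  # "AGCUUA"
#' extractSeed("UAGCUUAUCAGACUGAUGUUGA", 8)  # "AGCUUAUC"
#' @export
extractSeed <- function(mirnaSeq, length, offset = 2L) {
    stopifnot(base::length(mirnaSeq) == 1L, length %in% c(6L, 7L, 8L),
              offset >= 1L)
    s <- chartr("Tt", "Uu", toupper(mirnaSeq))
    if (nchar(s) < offset + length - 1L)
        stop(sprintf("sequence too short (%d nt) for a %d-nt seed at position %d",
                     nchar(s), length, offset))
    seed <- substr(s, offset, offset + length - 1L)
    if (grepl("N", seed, fixed = TRUE)) {
        warning("ambiguous base in seed window; excluded from matching")
        return(NA_character_)
    }
    if (grepl("[^ACGU]", seed))
        stop("seed window contains letters outside ACGUN")
    seed
}

#' DNA target site of a seed
#'
#' The sequence a seed pairs with in a 3'UTR: the reverse complement of the
#' seed, transcribed to the DNA alphabet (A-U/T, G-C pairing).
#'
#' @param seed RNA seed string (ACGU)
#' @return DNA string (ACGT)
#' @examples
#' seedTarget("AGCUUA")  # "TAAGCT"
#' @export
seedTarget <- function(seed) {
    stopifnot(length(seed) == 1L, !is.na(seed))
    if (grepl("[^ACGU]", seed))
        stop("'seed' must be an RNA string over ACGU")
    rc <- Biostrings::reverseComplement(Biostrings::RNAString(seed))
    chartr("U", "T", as.character(rc))
}

#' Scan a 3'UTR for seed-region matches
#'
#' For each seed length 6, 7 and 8, records every exact occurrence of the
#' miRNA's seed target ([seedTarget()] of [extractSeed()]) in the UTR.
#' Matching is exact: no wobble pairing, no mismatches. Positions are
#' 0-based offsets of the match start in the UTR. Because the shorter seed
#' targets are suffixes of the 8-mer target, an 8-mer match at position `p`
#' always implies a 7-mer match at `p + 1` and a 6-mer match at `p + 2`.
#'
#' @param utrSeq UTR sequence (single string; DNA or RNA alphabet)
#' @param mirnaSeq mature miRNA sequence
#' @param lengths seed lengths to scan (default `c(6, 7, 8)`)
#' @return list with `matched_lengths` (integer vector of lengths with at
#'   least one occurrence) and `positions` (named list, one integer vector
#'   of 0-based start offsets per scanned length)
#' @export
scanUtr <- function(utrSeq, mirnaSeq, lengths = c(6L, 7L, 8L)) {
    stopifnot(length(utrSeq) == 1L, nchar(utrSeq) > 0L)
    utr <- chartr("Uu", "Tt", toupper(utrSeq))
    subject <- Biostrings::DNAString(utr)
    positions <- list()
    for (L in lengths) {
        seed <- tryCatch(extractSeed(mirnaSeq, L),
                         warning = function(w) NA_character_,
                         error = function(e) NA_character_)
        if (is.na(seed)) {
            positions[[as.character(L)]] <- integer(0)
            next
        }
        hits <- Biostrings::matchPattern(seedTarget(seed), subject)
        positions[[as.character(L)]] <- Biostrings::start(hits) - 1L
    }
    matched <- as.integer(names(positions)[
        vapply(positions, length, 0L) > 0L])
    list(matched_lengths = matched, positions = positions)
}

## resolve UTR records for a gene: exact-name records plus "gene|transcript"
.utrRecordsFor <- function(gene, utrSet) {
    ids <- names(utrSet)
    hit <- ids == gene | startsWith(ids, paste0(gene, "|"))
    utrSet[hit]
}

#' Annotate associations with seed-match status
#'
#' For every (gene, miRNA) association, scans the gene's 3'UTR record(s) for
#' the miRNA's 6/7/8-nt seed targets and sets `seed_match` to `TRUE` if any
#' transcript in any supplied assembly set yields a match at any length
#' (any-transcript rule; matches are reported at gene level). Genes absent
#' from every UTR set, and associations whose miRNA sequence is missing, get
#' `seed_match = NA` ("unknown") and are reported via a message.
#'
#' UTR sets may contain several transcripts per gene, named either exactly
#' as the gene or as `"<gene>|<transcript>"`.
#'
#' @param assocs association `data.frame` (from [runAssociations()] or a
#'   fixture) with columns `gene` and `mirna`
#' @param utrSeqs named character vector of UTR sequences, or a list of such
#'   vectors (e.g. one per genome assembly)
#' @param mirnaSeqs named character vector of mature miRNA sequences
#' @return `assocs` with `seed_match` (logical, `NA` = unknown) and
#'   `matched_lengths` (comma-separated string) columns filled in
#' @export
annotateAssociations <- function(assocs, utrSeqs, mirnaSeqs) {
    stopifnot(all(c("gene", "mirna") %in% colnames(assocs)))
    if (!is.list(utrSeqs)) utrSeqs <- list(utrSeqs)
    match_ <- rep(NA, nrow(assocs))
    lens <- character(nrow(assocs))
    unknown <- character(0)
    for (i in seq_len(nrow(assocs))) {
        g <- assocs$gene[i]; m <- assocs$mirna[i]
        if (!m %in% names(mirnaSeqs)) {
            unknown <- c(unknown, paste0(g, "|", m, " (no miRNA sequence)"))
            next
        }
        recs <- unlist(lapply(utrSeqs, .utrRecordsFor, gene = g))
        if (length(recs) == 0L) {
            unknown <- c(unknown, paste0(g, "|", m, " (no UTR record)"))
            next
        }
        found <- integer(0)
        for (u in recs)
            found <- union(found, scanUtr(u, mirnaSeqs[[m]])$matched_lengths)
        match_[i] <- length(found) > 0L
        lens[i] <- paste(sort(found), collapse = ",")
    }
    if (length(unknown))
        message(length(unknown), " association(s) with unknown seed-match status: ",
                paste(unknown, collapse = "; "))
    assocs$seed_match <- match_
    assocs$matched_lengths <- lens
    assocs
}
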