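# shared fixture builders and independent oracles

makeMeta <- function(n, msi = NULL, age = NULL, sex = NULL) {
    subjects <- sprintf("S%03d", seq_len(n))
    if (is.null(msi)) msi <- rep("MSS", n)
    if (is.null(age)) age <- rep(60, n)
    if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
    data.frame(
        sample_id = c(rbind(paste0(subjects, "_T"), paste0(subjects, "_N"))),
        subject_id = rep(subjects, each = 2),
        tissue = rep(c("tumour", "normal"), n),
        age = rep(age, each = 2),
        sex = rep(sex, each = 2),
        msi_status = rep(msi, each = 2),
        stringsAsFactors = FALSE)
}

makeMatrix <- function(values, features, samples, universe, scale) {
    m <- matrix(values, length(features), length(samples),
                dimnames = list(features, samples))
    ExpressionMatrix(m, universe = universe, scale = scale)
}

# brute-force Benjamini-Hochberg: sort, step-up, cummin, unsort
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# naive O(n*m) sliding-window seed scan oracle (no pattern matching library)
bruteScan <- function(utr, mirnaSeq, lengths = c(6L, 7L, 8L)) {
    utr <- chartr("Uu", "Tt", toupper(utr))
    rna <- chartr("Tt", "Uu", toupper(mirnaSeq))
    comp <- c(A = "T", C = "G", G = "C", U = "A")
    positions <- list()
    for (L in lengths) {
        seed <- substr(rna, 2, L + 1)
        letters_ <- strsplit(seed, "")[[1]]
        targ <- paste(rev(unname(comp[letters_])), collapse = "")
        hits <- integer(0)
        if (nchar(utr) >= L)
            for (i in seq_len(nchar(utr) - L + 1))
                if (substr(utr, i, i + L - 1) == targ)
                    hits <- c(hits, i - 1L)
        positions[[as.character(L)]] <- hits
    }
    positions
}

# coupling-slope calibration shorthand over the exported helper
truthNoiseSd <- function(truth, gene, mirna)
    couplingNoiseSd(truth, gene, mirna)
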