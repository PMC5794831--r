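test_that("seed extraction uses the canonical position-2 window", {
    expect_identical(extractSeed("UAGCUUAUCAGACUGAUGUUGA", 6), "AGCUUA")
    expect_identical(extractSeed("UAGCUUAUCAGACUGAUGUUGA", 7), "AGCUUAU")
    expect_identical(extractSeed("UAGCUUAUCAGACUGAUGUUGA", 8), "AGCUUAUC")
    expect_identical(extractSeed("tagcttatca", 6), "AGCUUA")  # DNA input ok
    expect_error(extractSeed("ACGUA", 6), "short")
    expect_warning(seed <- extractSeed("UAGNCUAUC", 6), "ambiguous")
    expect_true(is.na(seed))
})

test_that("seed targets are DNA reverse complements", {
    expect_identical(seedTarget("AGCUUA"), "TAAGCT")
    expect_identical(seedTarget("AAAAAA"), "TTTTTT")
    # reverse-complementing twice returns the DNA transliteration of the seed
    rc2 <- seedTarget(chartr("Tt", "Uu", seedTarget("AGCUUA")))
    expect_identical(rc2, "AGCTTA")
    expect_error(seedTarget("AGCTTA"), "RNA")
})

test_that("a planted 7-mer target is found with its nested 6-mer", {
    mirna <- "UAGCUUAUCAGACUGAUGUUGA"
    targ7 <- seedTarget(extractSeed(mirna, 7))       # 7 nt
    utr <- paste0(strrep("C", 12), targ7, strrep("C", 10))
    hit <- scanUtr(utr, mirna)
    expect_true(all(c(6, 7) %in% hit$matched_lengths))
    expect_identical(hit$positions[["7"]], 12L)
    expect_identical(hit$positions[["6"]], 13L)      # suffix nesting
    expect_identical(hit$positions[["8"]], integer(0))
})

test_that("an all-A UTR cannot match a seed containing C, G or U", {
    expect_identical(
        scanUtr(strrep("A", 100), "UAGCUUAUCAGACUGAUGUUGA")$matched_lengths,
        integer(0))
})

test_that("8-mer matches imply nested 7- and 6-mer matches", {
    set.seed(51)
    for (k in 1:20) {
        mirna <- paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                       collapse = "")
        utr <- paste0(paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                            collapse = ""),
                      seedTarget(extractSeed(mirna, 8)),
                      paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                            collapse = ""))
        hit <- scanUtr(utr, mirna)
        expect_true(all(c(6, 7, 8) %in% hit$matched_lengths))
        for (p in hit$positions[["8"]]) {
            expect_true((p + 1L) %in% hit$positions[["7"]])
            expect_true((p + 2L) %in% hit$positions[["6"]])
        }
    }
})

test_that("pattern scan equals the naive sliding-window oracle", {
    set.seed(52)
    for (k in 1:60) {
        utr <- paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                     collapse = "")
        mirna <- paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                       collapse = "")
        hit <- scanUtr(utr, mirna)
        oracle <- bruteScan(utr, mirna)
        for (L in c("6", "7", "8"))
            expect_identical(hit$positions[[L]], oracle[[L]])
    }
})

test_that("the mirror property holds: reverse-complemented UTR scanned for
           the unreversed seed transliteration gives the same count", {
    set.seed(53)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (k in 1:10) {
        utr <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                     collapse = "")
        mirna <- paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                       collapse = "")
        rcUtr <- paste(rev(unname(comp[strsplit(utr, "")[[1]]])),
                       collapse = "")
        for (L in c(6L, 7L, 8L)) {
            seedDna <- chartr("U", "T", extractSeed(mirna, L))
            fwd <- length(scanUtr(utr, mirna, L)$positions[[as.character(L)]])
            mirror <- length(gregexpr(seedDna, rcUtr, fixed = TRUE)[[1]])
            if (!grepl(seedDna, rcUtr, fixed = TRUE)) mirror <- 0L
            expect_identical(fwd, mirror)
        }
    }
})

test_that("association annotation applies the any-transcript, any-assembly rule", {
    mirnas <- c(m1 = "UAGCUUAUCAGACUGAUGUUGA", m2 = "UUGGCAAUCGUAGCAACCGAUU")
    targ <- seedTarget(extractSeed(mirnas[["m1"]], 7))
    utr37 <- c("g1|tx1" = strrep("A", 30),
               "g1|tx2" = paste0(strrep("A", 5), targ, strrep("A", 5)))
    utr38 <- c(g2 = strrep("A", 40))
    assocs <- data.frame(gene = c("g1", "g2", "g3", "g1"),
                         mirna = c("m1", "m1", "m1", "m3"),
                         stringsAsFactors = FALSE)
    expect_message(
        out <- annotateAssociations(assocs, list(GRCh37 = utr37,
                                                 GRCh38 = utr38), mirnas),
        "unknown")
    expect_identical(out$seed_match, c(TRUE, FALSE, NA, NA))
    expect_identical(out$matched_lengths[1], "6,7")
})

test_that("planted sequence designs are recovered exactly, no extras", {
    set.seed(54)
    mirnas <- sprintf("mir%02d", 1:10)
    genes <- sprintf("gene%02d", 1:8)
    planted <- data.frame(
        mirna = c("mir01", "mir02", "mir03", "mir04", "mir05",
                  "mir06", "mir07", "mir08", "mir09", "mir10"),
        gene = c("gene01", "gene01", "gene02", "gene03", "gene04",
                 "gene05", "gene06", "gene07", "gene08", "gene08"),
        seed_length = c(6L, 7L, 8L, 6L, 7L, 8L, 6L, 7L, 8L, 6L))
    sq <- simulateSequences(mirnas, genes, planted, seed = 7)
    for (r in seq_len(nrow(planted))) {
        hit <- scanUtr(sq$utr[[planted$gene[r]]],
                       sq$mirna[[planted$mirna[r]]])
        expect_true(planted$seed_length[r] %in% hit$matched_lengths)
        expect_true(sq$truth$position[r] %in%
                    hit$positions[[as.character(planted$seed_length[r])]])
    }
    # full cross-scan: only planted pairs match
    for (g in genes) for (m in mirnas) {
        hits <- scanUtr(sq$utr[[g]], sq$mirna[[m]])$matched_lengths
        plantedHere <- planted$seed_length[planted$gene == g &
                                           planted$mirna == m]
        if (length(plantedHere) == 0L) expect_identical(hits, integer(0))
        else expect_true(all(plantedHere %in% hits))
    }
})

test_that("empty planted designs yield match-free sequence sets", {
    sq <- simulateSequences(sprintf("m%d", 1:5), sprintf("g%d", 1:5),
                            NULL, seed = 3)
    for (g in names(sq$utr)) for (m in names(sq$mirna))
        expect_identical(scanUtr(sq$utr[[g]], sq$mirna[[m]])$matched_lengths,
                         integer(0))
    expect_error(simulateSequences(c("a", "a"), "g1", NULL), "duplicate")
})
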