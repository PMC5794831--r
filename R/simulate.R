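#' Parameters of a synthetic paired cohort
#'
#' Defaults reproduce the study conditions: 217 subjects each contributing
#' one carcinoma and one normal-mucosa sample, a protein-coding universe of
#' 17,461 genes of which the first 92 are tagged as the pathway gene set,
#' 814 miRNAs, a 13.4% MSI fraction, and an age/sex distribution of
#' Normal(64.8, 10.1) truncated to \[30, 79\] with 54.4% male.
#'
#' Counts for gene g, subject i, tissue t are negative binomial with mean
#' `exposure_it * baseline_g * exp(u_i) * FC_g^[t = tumour]` and variance
#' `mu + mu^2 / theta` with `theta = 1 / nbDispersion`; `u_i` is a shared
#' per-subject random intercept on the log scale. miRNA intensities are a
#' per-miRNA baseline plus truncated-at-zero Gaussian noise; the tumour
#' sample additionally carries a per-subject differential term, and planted
#' couplings feed that realized miRNA paired difference linearly (with the
#' stated slope, in RPMPCG units per intensity unit) into the gene's tumour
#' mean. Coupling injection happens before the per-sample array scale
#' distortion (drawn uniformly in `arrayScaleRange`), so recovery requires
#' the 75th-percentile normalization to undo the distortion.
#'
#' @param nSubjects number of subjects (pairs)
#' @param nGenesTotal protein-coding universe size
#' @param nPathwayGenes leading genes tagged as the pathway set
#' @param nMirnas number of miRNAs
#' @param fracMsi proportion of subjects with MSI tumours
#' @param nbDispersion NB dispersion (variance `mu + dispersion * mu^2`)
#' @param subjectSd log-scale SD of the per-subject random intercept
#' @param plantedFc named numeric vector of true tumour/normal fold changes
#' @param plantedFcMsi like `plantedFc` but applied only to MSI subjects
#' @param plantedMirnaFc named numeric vector of true miRNA fold changes
#' @param plantedCouplings `data.frame` with columns `gene`, `mirna`,
#'   `slope`: linear couplings on the paired-difference scale
#' @param arrayScaleRange range of per-sample miRNA scale distortions
#' @param ageMean,ageSd,sexMaleProb cohort demographics
#' @param meanLibSize,libSizeSd library-size exposure (log-normal)
#' @param mirnaNoiseCV,mirnaDeltaCV miRNA noise / per-subject differential,
#'   as coefficients of variation relative to the miRNA baseline
#' @param geneNames,mirnaNames optional explicit feature names
#' @param rngSeed integer seed
#' @return validated list of class `CohortParams`
#' @export
cohortParams <- function(nSubjects = 217L, nGenesTotal = 17461L,
                         nPathwayGenes = 92L, nMirnas = 814L,
                         fracMsi = 0.134, nbDispersion = 0.25,
                         subjectSd = 0.3, plantedFc = numeric(0),
                         plantedFcMsi = numeric(0),
                         plantedMirnaFc = numeric(0),
                         plantedCouplings = NULL,
                         arrayScaleRange = c(0.7, 1.4),
                         ageMean = 64.8, ageSd = 10.1, sexMaleProb = 0.544,
                         meanLibSize = 2e6, libSizeSd = 0.25,
                         mirnaNoiseCV = 0.3, mirnaDeltaCV = 0.4,
                         geneNames = NULL, mirnaNames = NULL, rngSeed = 1L) {
    if (nSubjects != as.integer(nSubjects) || nSubjects < 1)
        stop("'nSubjects' must be a positive integer")
    stopifnot(nGenesTotal >= 1, nPathwayGenes >= 0,
              nPathwayGenes <= nGenesTotal, nMirnas >= 1,
              fracMsi >= 0, fracMsi <= 1, nbDispersion >= 0, subjectSd >= 0,
              length(arrayScaleRange) == 2L, all(arrayScaleRange > 0),
              mirnaNoiseCV >= 0, mirnaDeltaCV >= 0)
    if (is.null(geneNames))
        geneNames <- c(sprintf("PWG%03d", seq_len(nPathwayGenes)),
                       sprintf("BG%05d",
                               seq_len(nGenesTotal - nPathwayGenes)))
    if (length(geneNames) != nGenesTotal || anyDuplicated(geneNames))
        stop("'geneNames' must be ", nGenesTotal, " unique names")
    if (is.null(mirnaNames))
        mirnaNames <- sprintf("mir-%04d", seq_len(nMirnas))
    if (length(mirnaNames) != nMirnas || anyDuplicated(mirnaNames))
        stop("'mirnaNames' must be ", nMirnas, " unique names")
    if (is.null(plantedCouplings))
        plantedCouplings <- data.frame(gene = character(0),
                                       mirna = character(0),
                                       slope = numeric(0))
    badFc <- setdiff(c(names(plantedFc), names(plantedFcMsi),
                       plantedCouplings$gene), geneNames)
    if (length(badFc))
        stop("planted gene(s) absent from the universe: ",
             paste(badFc, collapse = ", "))
    badMir <- setdiff(c(names(plantedMirnaFc), plantedCouplings$mirna),
                      mirnaNames)
    if (length(badMir))
        stop("planted miRNA(s) absent from the universe: ",
             paste(badMir, collapse = ", "))
    if (any(plantedFc <= 0) || any(plantedFcMsi <= 0) ||
        any(plantedMirnaFc <= 0))
        stop("planted fold changes must be positive")
    structure(list(
        nSubjects = as.integer(nSubjects),
        nGenesTotal = as.integer(nGenesTotal),
        nPathwayGenes = as.integer(nPathwayGenes),
        nMirnas = as.integer(nMirnas), fracMsi = fracMsi,
        nbDispersion = nbDispersion, subjectSd = subjectSd,
        plantedFc = plantedFc, plantedFcMsi = plantedFcMsi,
        plantedMirnaFc = plantedMirnaFc,
        plantedCouplings = plantedCouplings,
        arrayScaleRange = arrayScaleRange, ageMean = ageMean, ageSd = ageSd,
        sexMaleProb = sexMaleProb, meanLibSize = meanLibSize,
        libSizeSd = libSizeSd, mirnaNoiseCV = mirnaNoiseCV,
        mirnaDeltaCV = mirnaDeltaCV, geneNames = geneNames,
        mirnaNames = mirnaNames, rngSeed = as.integer(rngSeed)),
        class = "CohortParams")
}

#' Simulate a paired tumour/normal cohort
#'
#' Draws a full synthetic cohort under the model described in
#' [cohortParams()]; identical parameters and seed give bit-identical
#' cohorts.
#'
#' @param params a `CohortParams` object from [cohortParams()]
#' @return a [SyntheticCohort-class]
#' @export
simulateCohort <- function(params) {
    stopifnot(inherits(params, "CohortParams"))
    p <- params
    set.seed(p$rngSeed)
    subjects <- sprintf("S%04d", seq_len(p$nSubjects))
    age <- round(.rnormTrunc(p$nSubjects, p$ageMean, p$ageSd, 30, 79))
    sex <- ifelse(stats::runif(p$nSubjects) < p$sexMaleProb,
                  "male", "female")
    msi <- ifelse(stats::runif(p$nSubjects) < p$fracMsi, "MSI", "MSS")
    u <- stats::rnorm(p$nSubjects, 0, p$subjectSd)
    tumourIds <- paste0(subjects, "_T")
    normalIds <- paste0(subjects, "_N")
    sampleIds <- c(rbind(tumourIds, normalIds))  # interleaved, subject order
    nSamp <- 2L * p$nSubjects
    exposure <- p$meanLibSize *
        exp(stats::rnorm(nSamp, 0, p$libSizeSd) - p$libSizeSd^2 / 2)
    names(exposure) <- sampleIds
    ## baseline expression weights (fraction of the protein-coding library).
    ## Pathway genes are drawn on a measured-RPMPCG-like scale (lognormal
    ## around ~30 RPMPCG, spanning roughly 1-1000) so no single pathway gene
    ## dominates the library and distorts the RPMPCG denominator; the
    ## heavy-tailed background makes up the rest of the library mass.
    nPath <- p$nPathwayGenes
    wPath <- if (nPath > 0)
        exp(stats::rnorm(nPath, log(30), 1.5)) / 1e6 else numeric(0)
    if (sum(wPath) > 0.5) wPath <- wPath * 0.5 / sum(wPath)
    wBg <- exp(stats::rnorm(p$nGenesTotal - nPath, 0, 1.8))
    wBg <- wBg / sum(wBg) * (1 - sum(wPath))
    w <- c(wPath, wBg)
    names(w) <- p$geneNames
    fc <- stats::setNames(rep(1, p$nGenesTotal), p$geneNames)
    fc[names(p$plantedFc)] <- p$plantedFc
    fcMsi <- stats::setNames(rep(1, p$nGenesTotal), p$geneNames)
    fcMsi[names(p$plantedFcMsi)] <- p$plantedFcMsi

    ## miRNA layer first, so realized paired differences can feed couplings
    mirnaBase <- exp(stats::rnorm(p$nMirnas, 2, 1.5))
    names(mirnaBase) <- p$mirnaNames
    mirnaFc <- stats::setNames(rep(1, p$nMirnas), p$mirnaNames)
    mirnaFc[names(p$plantedMirnaFc)] <- p$plantedMirnaFc
    noiseSd <- p$mirnaNoiseCV * mirnaBase
    deltaSd <- p$mirnaDeltaCV * mirnaBase
    normalInt <- pmax(mirnaBase +
        matrix(stats::rnorm(p$nMirnas * p$nSubjects, 0, noiseSd),
               p$nMirnas, p$nSubjects), 0)
    delta <- matrix(stats::rnorm(p$nMirnas * p$nSubjects, 0, deltaSd),
                    p$nMirnas, p$nSubjects)
    tumourInt <- pmax(mirnaBase * mirnaFc + delta +
        matrix(stats::rnorm(p$nMirnas * p$nSubjects, 0, noiseSd),
               p$nMirnas, p$nSubjects), 0)
    realizedDelta <- tumourInt - normalInt   # pre-distortion paired diff
    dimnames(normalInt) <- list(p$mirnaNames, normalIds)
    dimnames(tumourInt) <- list(p$mirnaNames, tumourIds)
    dimnames(realizedDelta) <- list(p$mirnaNames, subjects)

    ## gene count means: exposure x baseline x subject effect x fold change
    mu <- matrix(0, p$nGenesTotal, nSamp,
                 dimnames = list(p$geneNames, sampleIds))
    for (i in seq_len(p$nSubjects)) {
        base_i <- w * exp(u[i])
        fcEff <- fc
        if (msi[i] == "MSI") fcEff <- fc * fcMsi
        mu[, tumourIds[i]] <- exposure[tumourIds[i]] * base_i * fcEff
        mu[, normalIds[i]] <- exposure[normalIds[i]] * base_i
    }
    ## planted couplings: the gene's tumour mean moves with the miRNA's
    ## realized paired difference, expressed in RPMPCG units
    pc <- p$plantedCouplings
    if (nrow(pc)) for (k in seq_len(nrow(pc))) {
        g <- pc$gene[k]; m <- pc$mirna[k]; b <- pc$slope[k]
        shift <- b * realizedDelta[m, ] / 1e6 *
            exposure[tumourIds] * exp(u)
        mu[g, tumourIds] <- pmax(mu[g, tumourIds] + shift, 1e-8)
    }
    theta <- if (p$nbDispersion <= 0) Inf else 1 / p$nbDispersion
    counts <- if (is.finite(theta)) {
        matrix(stats::rnbinom(length(mu), mu = mu, size = theta),
               nrow(mu), ncol(mu), dimnames = dimnames(mu))
    } else {
        matrix(stats::rpois(length(mu), lambda = mu),
               nrow(mu), ncol(mu), dimnames = dimnames(mu))
    }
    ## per-sample array scale distortion applied after coupling injection
    scaleFac <- stats::runif(nSamp, p$arrayScaleRange[1L],
                             p$arrayScaleRange[2L])
    names(scaleFac) <- sampleIds
    raw <- cbind(tumourInt, normalInt)[, sampleIds, drop = FALSE]
    raw <- sweep(raw, 2L, scaleFac, "*")

    meta <- data.frame(
        sample_id = sampleIds,
        subject_id = rep(subjects, each = 2L),
        tissue = rep(c("tumour", "normal"), times = p$nSubjects),
        age = rep(age, each = 2L),
        sex = rep(sex, each = 2L),
        msi_status = rep(msi, each = 2L),
        stringsAsFactors = FALSE)
    truth <- list(params = p, subjectEffect = stats::setNames(u, subjects),
                  exposure = exposure, baselineWeight = w,
                  foldChange = fc, foldChangeMsi = fcMsi,
                  mirnaBaseline = mirnaBase, mirnaFoldChange = mirnaFc,
                  mirnaDelta = realizedDelta, arrayScale = scaleFac,
                  plantedFc = p$plantedFc,
                  plantedCouplings = p$plantedCouplings)
    new("SyntheticCohort",
        counts = ExpressionMatrix(counts, "protein_coding", "raw_counts"),
        mirna = ExpressionMatrix(raw, "mirna", "raw_intensity"),
        meta = meta, truth = truth)
}

.RNA <- c("A", "C", "G", "U")

#' Simulate miRNA and 3'UTR sequences with planted seed matches
#'
#' Generates mature miRNA sequences (RNA alphabet) and gene 3'UTR sequences
#' (DNA alphabet) such that exactly the planted (miRNA, gene, seed length)
#' pairs carry a seed-region match: for each planted pair the DNA reverse
#' complement of the miRNA's seed of the stated length is embedded at a
#' recorded position in the gene's UTR, and all other pairs are match-free
#' by construction plus rejection sampling.
#'
#' Match-free background: UTRs are drawn from the three-letter alphabet
#' A/C/G while every miRNA carries an `A` at position 5 (inside all three
#' seed windows), so every seed target contains a `T` and cannot occur in
#' the background; a verification scan re-draws any UTR that still collides
#' with a planted insert. This background is deliberately artificial - it
#' trades base composition realism for exact control of the planted design.
#'
#' @param mirnaNames,geneNames unique feature names
#' @param plantedMatches `data.frame` with columns `mirna`, `gene`,
#'   `seed_length` (values in 6/7/8); may be empty
#' @param utrLength,mirnaLength sequence lengths (defaults 500 and 22 nt)
#' @param seed integer seed
#' @return list with `mirna` (named RNA strings), `utr` (named DNA strings)
#'   and `truth` (`data.frame`: `mirna`, `gene`, `seed_length`, `position`
#'   with 0-based insert offsets)
#' @export
simulateSequences <- function(mirnaNames, geneNames,
                              plantedMatches = NULL, utrLength = 500L,
                              mirnaLength = 22L, seed = 1L) {
    if (anyDuplicated(mirnaNames) || anyDuplicated(geneNames))
        stop("duplicate sequence identifiers")
    if (is.null(plantedMatches))
        plantedMatches <- data.frame(mirna = character(0),
                                     gene = character(0),
                                     seed_length = integer(0))
    stopifnot(all(plantedMatches$seed_length %in% c(6L, 7L, 8L)),
              all(plantedMatches$mirna %in% mirnaNames),
              all(plantedMatches$gene %in% geneNames),
              utrLength >= 20L, mirnaLength >= 9L)
    set.seed(seed)
    nM <- length(mirnaNames)
    ## miRNAs: random RNA with a forced A at position 5 (so every seed
    ## target contains a T and cannot occur in the T-free background).
    ## A candidate is rejected when its 6-mer target nests inside another
    ## miRNA's 8-mer target (or vice versa): otherwise planting one miRNA's
    ## site would deterministically create a match for the other.
    drawMirna <- function() {
        s <- sample(.RNA, mirnaLength, replace = TRUE)
        s[5L] <- "A"
        paste(s, collapse = "")
    }
    mirnas <- character(nM)
    t6s <- t8s <- character(0)
    for (j in seq_len(nM)) {
        repeat {
            cand <- drawMirna()
            c6 <- seedTarget(extractSeed(cand, 6L))
            c8 <- seedTarget(extractSeed(cand, 8L))
            clash <- any(vapply(t8s, function(t) grepl(c6, t, fixed = TRUE),
                                TRUE)) ||
                     any(vapply(t6s, function(t) grepl(t, c8, fixed = TRUE),
                                TRUE))
            if (!clash) { t6s <- c(t6s, c6); t8s <- c(t8s, c8); break }
        }
        mirnas[j] <- cand
    }
    names(mirnas) <- mirnaNames
    ## UTR background over A/C/G only: no T, hence no seed target
    drawUtr <- function() paste(sample(c("A", "C", "G"), utrLength,
                                       replace = TRUE), collapse = "")
    utrs <- stats::setNames(character(length(geneNames)), geneNames)
    truth <- plantedMatches
    truth$position <- rep(NA_integer_, nrow(truth))
    for (g in geneNames) {
        rows <- which(plantedMatches$gene == g)
        for (attempt in 1:100) {
            u <- drawUtr()
            for (r in rows) {
                L <- plantedMatches$seed_length[r]
                mseq <- mirnas[[plantedMatches$mirna[r]]]
                targ <- seedTarget(extractSeed(mseq, L))
                pos <- sample.int(nchar(u) - L + 1L, 1L)
                substr(u, pos, pos + L - 1L) <- targ
                ## longer targets grow by prepending one complement letter;
                ## pin the preceding position to a letter that cannot extend
                ## the planted site to an unplanted longer match
                if (L < 8L && pos > 1L) {
                    ext <- substr(seedTarget(extractSeed(mseq, L + 1L)),
                                  1L, 1L)
                    guard <- setdiff(c("A", "C", "G"), ext)
                    substr(u, pos - 1L, pos - 1L) <-
                        guard[sample.int(length(guard), 1L)]
                }
                truth$position[r] <- pos - 1L
            }
            ## verify: only planted pairs may match this UTR
            ok <- TRUE
            for (m in mirnaNames) {
                hits <- scanUtr(u, mirnas[[m]])$matched_lengths
                wantL <- plantedMatches$seed_length[
                    rows[plantedMatches$mirna[rows] == m]]
                allowed <- if (length(wantL)) 6:max(wantL) else integer(0)
                if (length(setdiff(hits, allowed)) ||
                    (length(wantL) && !all(wantL %in% hits))) {
                    ok <- FALSE
                    break
                }
            }
            if (ok) break
            if (attempt == 100L)
                stop("could not draw a conflict-free UTR for gene ", g)
        }
        utrs[[g]] <- u
    }
    list(mirna = mirnas, utr = utrs, truth = truth)
}

#' Paired-difference noise scales implied by a cohort's truth
#'
#' Returns the standard deviations of a gene's RPMPCG paired difference
#' (absent any coupling) and of a miRNA's intensity paired difference, as
#' implied by the generating parameters: the gene SD combines Poisson and
#' overdispersion noise on both tissues (the tumour side scaled by the
#' gene's planted fold change), the miRNA SD combines the per-subject
#' differential term and measurement noise on both tissues. Planted coupling
#' slopes stated in SD units convert to generator (raw) units as
#' `sdUnits * sd_gene / sd_mirna`.
#'
#' @param truth the `truth` list of a [SyntheticCohort-class]
#' @param gene,mirna feature names
#' @return named numeric vector with elements `gene` and `mirna`
#' @export
couplingNoiseSd <- function(truth, gene, mirna) {
    p <- truth$params
    r <- truth$baselineWeight[[gene]] * 1e6    # expected normal RPMPCG
    fc <- truth$foldChange[[gene]]
    k <- 1e6 / p$meanLibSize
    geneSd <- sqrt(fc * r * k + p$nbDispersion * (fc * r)^2 +
                   r * k + p$nbDispersion * r^2)
    mirnaSd <- truth$mirnaBaseline[[mirna]] *
        sqrt(p$mirnaDeltaCV^2 + 2 * p$mirnaNoiseCV^2)
    c(gene = geneSd, mirna = mirnaSd)
}
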