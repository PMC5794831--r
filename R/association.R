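#' Subject-level paired differences
#'
#' For every feature and every complete tumour/normal pair, the expression in
#' the carcinoma sample minus the expression in the normal sample, computed
#' on the normalized scale (RPMPCG for genes, normalized intensity for
#' miRNAs). Subjects lacking either tissue are excluded.
#'
#' @param x normalized [ExpressionMatrix-class] (`rpmpcg` or
#'   `normalized_intensity` scale)
#' @param meta sample metadata
#' @return list with `diff` (features x subjects matrix of differences) and
#'   `subjects` (`data.frame`: `subject_id`, `age`, `sex`)
#' @export
pairedDifferences <- function(x, meta) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (!exprScale(x) %in% c("rpmpcg", "normalized_intensity"))
        stop("'x' must be on a normalized scale (rpmpcg or normalized_intensity)")
    pairs <- pairSamples(meta)
    pairs <- pairs[pairs$tumour %in% colnames(x) &
                   pairs$normal %in% colnames(x), , drop = FALSE]
    v <- exprValues(x)
    if (nrow(pairs) == 0L) {
        warning("no complete tumour/normal pairs in the matrix")
        return(list(diff = v[, integer(0), drop = FALSE],
                    subjects = data.frame(subject_id = character(0),
                                          age = numeric(0),
                                          sex = character(0))))
    }
    d <- v[, pairs$tumour, drop = FALSE] - v[, pairs$normal, drop = FALSE]
    colnames(d) <- pairs$subject_id
    i <- match(pairs$tumour, meta$sample_id)
    list(diff = d,
         subjects = data.frame(subject_id = pairs$subject_id,
                               age = meta$age[i],
                               sex = as.character(meta$sex[i]),
                               stringsAsFactors = FALSE))
}

## Full and reduced design matrices for the association model.
## Age is centered and sex enters as a male indicator; zero-variance
## covariate columns (e.g. a single-sex cohort) are dropped from both models
## so the extra-sum-of-squares comparison stays valid.
.assocDesign <- function(mirnaDiff, age, sex) {
    covs <- cbind(age = age - mean(age),
                  sex = as.numeric(sex == "male"))
    covs <- covs[, apply(covs, 2L, stats::sd) > 0, drop = FALSE]
    Xr <- cbind(`(Intercept)` = 1, covs)
    Xf <- cbind(`(Intercept)` = 1, mirna = mirnaDiff, covs)
    list(full = Xf, reduced = Xr)
}

#' Age/sex-adjusted association between paired differences
#'
#' Ordinary least squares of the gene's paired differences on the miRNA's
#' paired differences, adjusted for age and sex. The reported statistic is
#' the extra-sum-of-squares F comparing the full model
#' `gene_diff ~ mirna_diff + age + sex` with the reduced model
#' `gene_diff ~ age + sex`; the slope is the miRNA coefficient.
#'
#' @param geneDiff,mirnaDiff numeric vectors of per-subject paired
#'   differences, same subjects in the same order
#' @param age,sex subject covariates (sex `"male"`/`"female"`)
#' @return list: `slope`, `f_stat`, `df1`, `df2`, `rss_full`, `rss_red`,
#'   `perfect` (logical; an exactly collinear fit gives infinite F, flagged)
#' @export
fitAssociation <- function(geneDiff, mirnaDiff, age, sex) {
    n <- length(geneDiff)
    stopifnot(length(mirnaDiff) == n, length(age) == n, length(sex) == n)
    if (n < 10L)
        stop("at least 10 complete subjects are required")
    if (stats::sd(mirnaDiff) == 0)
        stop("constant miRNA differences: slope not identifiable")
    des <- .assocDesign(mirnaDiff, age, sex)
    qf <- stats::lm.fit(des$full, geneDiff)
    qr_ <- stats::lm.fit(des$reduced, geneDiff)
    rssF <- sum(qf$residuals^2)
    rssR <- sum(qr_$residuals^2)
    df2 <- n - ncol(des$full)
    perfect <- rssF < max(1e-12, 1e-10 * rssR)
    f <- if (perfect) Inf else ((rssR - rssF) / 1) / (rssF / df2)
    list(slope = unname(qf$coefficients["mirna"]), f_stat = f,
         df1 = 1L, df2 = df2, rss_full = rssF, rss_red = rssR,
         perfect = perfect)
}

#' Residual-bootstrap p-value for the association F statistic
#'
#' Builds the null distribution of the F statistic by resampling residuals
#' from the null model of no association between gene and miRNA differences
#' (the reduced model `gene_diff ~ age + sex`): each bootstrap response is
#' the null fitted values plus residuals resampled with replacement, both
#' models are refit, and the F statistic recorded. The p-value uses the
#' add-one correction `(1 + #[F_b >= F_obs]) / (nBoot + 1)`, so it is never
#' zero and its floor at 10,000 draws is 1/10,001.
#'
#' `scheme = "signflip"` multiplies each null residual by an independent
#' random sign instead of resampling with replacement.
#'
#' @inheritParams fitAssociation
#' @param nBoot number of bootstrap draws (study value 10,000; values below
#'   100 warn, below 1 error)
#' @param seed integer seed for the resampling stream (see
#'   [substreamSeed()] for deriving per-pair substreams)
#' @param scheme `"resample"` (default) or `"signflip"`
#' @return list: `boot_p`, plus the observed fit (`slope`, `f_stat`, ...)
#'   from [fitAssociation()] and `n_boot`
#' @export
bootstrapP <- function(geneDiff, mirnaDiff, age, sex, nBoot = 10000,
                       seed = NULL, scheme = c("resample", "signflip")) {
    scheme <- match.arg(scheme)
    if (nBoot < 1) stop("'nBoot' must be at least 1")
    if (nBoot < 100) warning("'nBoot' below 100 gives a very coarse p-value")
    obs <- fitAssociation(geneDiff, mirnaDiff, age, sex)
    des <- .assocDesign(mirnaDiff, age, sex)
    nullFit <- stats::lm.fit(des$reduced, geneDiff)
    f0 <- nullFit$fitted.values
    e0 <- nullFit$residuals
    n <- length(geneDiff)
    if (!is.null(seed)) set.seed(seed)
    E <- if (scheme == "resample") {
        matrix(e0[sample.int(n, n * nBoot, replace = TRUE)], n, nBoot)
    } else {
        matrix(e0, n, nBoot) *
            matrix(sample(c(-1, 1), n * nBoot, replace = TRUE), n, nBoot)
    }
    Y <- f0 + E
    ## RSS under each model: ||y||^2 - ||Q^T y||^2 with thin-Q from one QR
    Qf <- qr.Q(qr(des$full))
    Qr <- qr.Q(qr(des$reduced))
    tot <- colSums(Y^2)
    rssF <- tot - colSums(crossprod(Qf, Y)^2)
    rssR <- tot - colSums(crossprod(Qr, Y)^2)
    df2 <- obs$df2
    fb <- ((rssR - rssF) / 1) / (rssF / df2)
    bootP <- (1 + sum(fb >= obs$f_stat)) / (nBoot + 1)
    c(list(boot_p = bootP, n_boot = as.integer(nBoot)), obs)
}

#' Gene-level FDR for miRNA associations
#'
#' Benjamini-Hochberg adjustment applied separately within each gene's
#' family of tested miRNAs.
#'
#' @param results `data.frame` with columns `gene` and `boot_p`
#' @return `results` with an `fdr_p` column (added or replaced)
#' @export
geneLevelFdr <- function(results) {
    stopifnot(all(c("gene", "boot_p") %in% colnames(results)))
    results$fdr_p <- stats::ave(results$boot_p, results$gene, FUN = bhFDR)
    results
}

#' Direction class of a gene/miRNA pair
#'
#' `inverse` when the gene and miRNA fold changes lie on opposite sides of
#' one (one up, one down), `same` when on the same side. A fold change of
#' exactly one is classified `same` and flagged as a boundary case. The
#' regression slope is checked against the class: a same-direction pair is
#' expected to have a positive slope on the paired-difference scale and an
#' inverse pair a negative one; disagreement raises the `discordant_beta`
#' flag (the class itself stays FC-based).
#'
#' @param geneFc,mirnaFc positive fold changes (vectorized)
#' @param slope regression slope(s) from [fitAssociation()]
#' @return `data.frame`: `direction` (`"inverse"`/`"same"`),
#'   `discordant_beta` (logical), `boundary` (logical)
#' @export
classifyDirection <- function(geneFc, mirnaFc, slope) {
    if (any(geneFc <= 0) || any(mirnaFc <= 0))
        stop("fold changes must be positive")
    prod <- (geneFc - 1) * (mirnaFc - 1)
    direction <- ifelse(prod < 0, "inverse", "same")
    boundary <- prod == 0
    expected <- ifelse(direction == "inverse", -1, 1)
    discordant <- sign(slope) != 0 & sign(slope) != expected
    data.frame(direction = direction, discordant_beta = discordant,
               boundary = boundary, stringsAsFactors = FALSE)
}

#' Test all gene x miRNA pairs
#'
#' Crosses the selected genes (by default only the dysregulated ones) with
#' every miRNA in the filtered matrix, computes the age/sex-adjusted slope
#' and bootstrap p-value for each pair on the paired-difference scale,
#' adjusts within gene ([geneLevelFdr()]), and classifies direction using
#' the genes' fold changes from the differential-expression table and miRNA
#' fold changes computed from group means over the paired samples.
#'
#' One master `seed` drives everything: each pair's resampling stream is the
#' substream [substreamSeed]`(seed, "<gene>|<mirna>")`, so results do not
#' depend on the order in which pairs are tested.
#'
#' @param de `data.frame` from [runDE()]
#' @param geneMatrix [ExpressionMatrix-class] on the `rpmpcg` scale
#' @param mirnaMatrix [ExpressionMatrix-class] on the `normalized_intensity`
#'   scale (after prevalence filtering)
#' @param meta sample metadata
#' @param dysregulatedOnly restrict to genes called `up`/`down` (default)
#' @param nBoot,scheme forwarded to [bootstrapP()]
#' @param seed master seed
#' @param alpha significance gate used for the `significant` column
#' @return `data.frame`: `gene`, `mirna`, `gene_fc`, `mirna_fc`, `slope`,
#'   `f_stat`, `boot_p`, `fdr_p`, `direction`, `discordant_beta`,
#'   `significant`, `seed_match` (NA until [annotateAssociations()])
#' @export
runAssociations <- function(de, geneMatrix, mirnaMatrix, meta,
                            dysregulatedOnly = TRUE, nBoot = 10000,
                            seed = 1, alpha = 0.05,
                            scheme = c("resample", "signflip")) {
    scheme <- match.arg(scheme)
    stopifnot(is(geneMatrix, "ExpressionMatrix"),
              is(mirnaMatrix, "ExpressionMatrix"))
    genes <- if (dysregulatedOnly) de$gene[de$call != "neither"] else de$gene
    genes <- intersect(genes, rownames(geneMatrix))
    mirnas <- rownames(mirnaMatrix)
    empty <- data.frame(gene = character(0), mirna = character(0),
                        gene_fc = numeric(0), mirna_fc = numeric(0),
                        slope = numeric(0), f_stat = numeric(0),
                        boot_p = numeric(0), fdr_p = numeric(0),
                        direction = character(0),
                        discordant_beta = logical(0),
                        significant = logical(0), seed_match = logical(0),
                        stringsAsFactors = FALSE)
    if (length(genes) == 0L || length(mirnas) == 0L)
        return(empty)
    gd <- pairedDifferences(geneMatrix, meta)
    md <- pairedDifferences(mirnaMatrix, meta)
    common <- intersect(colnames(gd$diff), colnames(md$diff))
    gD <- gd$diff[, common, drop = FALSE]
    mD <- md$diff[, common, drop = FALSE]
    subj <- gd$subjects[match(common, gd$subjects$subject_id), ]
    ## miRNA fold changes from group means over the paired samples
    pairs <- pairSamples(meta)
    mv <- exprValues(mirnaMatrix)
    pairs <- pairs[pairs$tumour %in% colnames(mv) &
                   pairs$normal %in% colnames(mv), , drop = FALSE]
    mirnaFc <- rowMeans(mv[, pairs$tumour, drop = FALSE]) /
        rowMeans(mv[, pairs$normal, drop = FALSE])
    geneFc <- de$fold_change[match(genes, de$gene)]
    names(geneFc) <- genes
    rows <- vector("list", length(genes) * length(mirnas))
    k <- 0L
    for (g in genes) {
        for (m in mirnas) {
            k <- k + 1L
            res <- tryCatch(
                bootstrapP(gD[g, ], mD[m, ], subj$age, subj$sex,
                           nBoot = nBoot,
                           seed = substreamSeed(seed, paste(g, m, sep = "|")),
                           scheme = scheme),
                error = function(e) NULL)
            if (is.null(res)) next
            rows[[k]] <- data.frame(
                gene = g, mirna = m,
                gene_fc = unname(geneFc[g]), mirna_fc = unname(mirnaFc[m]),
                slope = res$slope, f_stat = res$f_stat,
                boot_p = res$boot_p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out) || nrow(out) == 0L)
        return(empty)
    out <- geneLevelFdr(out)
    dir <- classifyDirection(out$gene_fc, out$mirna_fc, out$slope)
    out$direction <- dir$direction
    out$discordant_beta <- dir$discordant_beta
    out$significant <- out$fdr_p < alpha
    out$seed_match <- NA
    rownames(out) <- NULL
    out
}
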