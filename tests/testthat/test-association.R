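test_that("paired differences are tumour minus normal per subject", {
    meta <- makeMeta(3)
    v <- matrix(0, 2, 6, dimnames = list(c("f1", "f2"), meta$sample_id))
    v["f1", ] <- c(10, 4, 8, 8, 1, 5)   # T,N interleaved per subject
    v["f2", ] <- 2
    em <- ExpressionMatrix(v, "pathway", "rpmpcg")
    pd <- pairedDifferences(em, meta)
    expect_equal(pd$diff["f1", ], c(S001 = 6, S002 = 0, S003 = -4))
    expect_equal(unname(pd$diff["f2", ]), rep(0, 3))
    expect_identical(pd$subjects$subject_id, c("S001", "S002", "S003"))
    expect_error(pairedDifferences(
        ExpressionMatrix(v, "pathway", "raw_counts") , meta), "normalized")
})

test_that("a perfectly collinear pair is flagged with infinite F", {
    set.seed(41)
    md <- rnorm(20)
    age <- rep(60, 20); sex <- rep(c("male", "female"), 10)
    fit <- fitAssociation(md, md, age, sex)
    expect_true(fit$perfect)
    expect_identical(fit$f_stat, Inf)
    expect_equal(fit$slope, 1)
    expect_error(fitAssociation(md, rep(1, 20), age, sex), "constant")
    expect_error(fitAssociation(md[1:5], md[1:5], age[1:5], sex[1:5]),
                 "10")
})

test_that("the association F statistic matches R's anova F test", {
    set.seed(42)
    n <- 40
    age <- rnorm(n, 60, 8); sex <- sample(c("male", "female"), n, TRUE)
    md <- rnorm(n); gd <- 0.5 * md + rnorm(n) + 0.02 * age
    fit <- fitAssociation(gd, md, age, sex)
    full <- lm(gd ~ md + I(age - mean(age)) + I(sex == "male"))
    red <- lm(gd ~ I(age - mean(age)) + I(sex == "male"))
    ftab <- anova(red, full)
    expect_equal(fit$f_stat, ftab$F[2])
    expect_equal(fit$slope, unname(coef(full)["md"]))
    expect_equal(fit$df2, full$df.residual)
})

test_that("under the null the F statistic follows F(1, n-4)", {
    set.seed(43)
    n <- 30
    age <- rnorm(n, 60, 10); sex <- sample(c("male", "female"), n, TRUE)
    f <- replicate(4000, fitAssociation(rnorm(n), rnorm(n), age,
                                        sex)$f_stat)
    ks <- ks.test(f, pf, 1, n - 4)
    expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap p has the 1/(B+1) floor and is seed-deterministic", {
    set.seed(44)
    n <- 40
    age <- rnorm(n, 60, 8); sex <- sample(c("male", "female"), n, TRUE)
    md <- rnorm(n)
    gd <- 3 * md + rnorm(n, 0, 0.1)     # overwhelming signal
    b <- bootstrapP(gd, md, age, sex, nBoot = 2000, seed = 9)
    expect_equal(b$boot_p, 1 / 2001)
    b2 <- bootstrapP(gd, md, age, sex, nBoot = 2000, seed = 9)
    expect_identical(b$boot_p, b2$boot_p)
    expect_error(bootstrapP(gd, md, age, sex, nBoot = 0), "at least 1")
    expect_warning(bootstrapP(gd, md, age, sex, nBoot = 50, seed = 1),
                   "coarse")
})

test_that("bootstrap p agrees with the parametric F tail on Gaussian nulls", {
    set.seed(45)
    n <- 100
    age <- rnorm(n, 60, 8); sex <- sample(c("male", "female"), n, TRUE)
    for (k in 1:6) {
        md <- rnorm(n); gd <- rnorm(n)
        fit <- fitAssociation(gd, md, age, sex)
        parametric <- pf(fit$f_stat, 1, fit$df2, lower.tail = FALSE)
        if (parametric < 0.01 || parametric > 0.5) next
        b <- bootstrapP(gd, md, age, sex, nBoot = 10000, seed = k)
        expect_lt(abs(b$boot_p - parametric), 0.01)
    }
})

test_that("bootstrap p is invariant under affine rescaling of miRNA differences", {
    set.seed(46)
    n <- 50
    age <- rnorm(n, 60, 8); sex <- sample(c("male", "female"), n, TRUE)
    md <- rnorm(n); gd <- 0.4 * md + rnorm(n)
    b1 <- bootstrapP(gd, md, age, sex, nBoot = 2000, seed = 5)
    b2 <- bootstrapP(gd, 100 * md + 7, age, sex, nBoot = 2000, seed = 5)
    expect_equal(b1$boot_p, b2$boot_p)
    expect_equal(b2$slope * 100, b1$slope)
})

test_that("sign-flip residual scheme is also calibrated and deterministic", {
    set.seed(47)
    n <- 40
    age <- rnorm(n, 60, 8); sex <- sample(c("male", "female"), n, TRUE)
    md <- rnorm(n); gd <- rnorm(n)
    fit <- fitAssociation(gd, md, age, sex)
    parametric <- pf(fit$f_stat, 1, fit$df2, lower.tail = FALSE)
    b <- bootstrapP(gd, md, age, sex, nBoot = 5000, seed = 2,
                    scheme = "signflip")
    expect_equal(b$boot_p, parametric, tolerance = 0.05)
    expect_identical(b$boot_p,
                     bootstrapP(gd, md, age, sex, nBoot = 5000, seed = 2,
                                scheme = "signflip")$boot_p)
})

test_that("gene-level FDR adjusts within each gene family independently", {
    res <- data.frame(gene = c(rep("A", 3), rep("B", 2)),
                      boot_p = c(0.01, 0.02, 0.03, 0.04, 0.5))
    out <- geneLevelFdr(res)
    expect_equal(out$fdr_p[1:3], bruteBH(c(0.01, 0.02, 0.03)))
    expect_equal(out$fdr_p[4:5], bruteBH(c(0.04, 0.5)))
    # one small p among 814 tested miRNAs: BH gives 814 * p / 1
    pvec <- c(1 / 10001, runif(813, 0.2, 1))
    out2 <- geneLevelFdr(data.frame(gene = "G", boot_p = pvec))
    expect_equal(out2$fdr_p[1], 814 / 10001)
    # all equal p within one gene stay put
    out3 <- geneLevelFdr(data.frame(gene = "G", boot_p = rep(0.03, 5)))
    expect_equal(out3$fdr_p, rep(0.03, 5))
})

test_that("direction classes follow the published fold-change logic", {
    # inverse: gene down, miRNA up (TNFRSF11A / miR-17-5p)
    d1 <- classifyDirection(0.45, 3.73, -2)
    expect_identical(d1$direction, "inverse")
    expect_false(d1$discordant_beta)
    # same: both down (BCL2 / miR-150-5p)
    d2 <- classifyDirection(0.39, 0.38, 1.5)
    expect_identical(d2$direction, "same")
    # both down but negative slope: same class, discordant flag
    # (TNFRSF11A / miR-590-5p footnote case)
    d3 <- classifyDirection(0.45, 0.59, -0.8)
    expect_identical(d3$direction, "same")
    expect_true(d3$discordant_beta)
    # FC exactly 1 is a flagged boundary, classified same
    d4 <- classifyDirection(1, 2, 0.3)
    expect_identical(d4$direction, "same")
    expect_true(d4$boundary)
})

test_that("runAssociations recovers planted couplings and controls the null", {
    couplings <- data.frame(gene = c("PWG002", "PWG004"),
                            mirna = c("mir-0001", "mir-0002"),
                            slope = c(1, -1))
    p0 <- cohortParams(nSubjects = 80, nGenesTotal = 200, nPathwayGenes = 4,
                       nMirnas = 40,
                       plantedFc = c(PWG001 = 0.45, PWG002 = 2.2,
                                     PWG003 = 0.3, PWG004 = 3),
                       rngSeed = 48)
    truth0 <- cohortTruth(simulateCohort(p0))
    sds <- vapply(seq_len(2), function(k)
        truthNoiseSd(truth0, couplings$gene[k], couplings$mirna[k]),
        c(gene = 0, mirna = 0))
    couplings$slope <- sign(couplings$slope) * 0.9 *
        sds["gene", ] / sds["mirna", ]
    p <- cohortParams(nSubjects = 80, nGenesTotal = 200, nPathwayGenes = 4,
                      nMirnas = 40,
                      plantedFc = c(PWG001 = 0.45, PWG002 = 2.2,
                                    PWG003 = 0.3, PWG004 = 3),
                      plantedCouplings = couplings, rngSeed = 48)
    co <- simulateCohort(p)
    de <- runDE(cohortCounts(co), cohortMeta(co), sprintf("PWG%03d", 1:4))
    rpm <- computeRPMPCG(cohortCounts(co), sprintf("PWG%03d", 1:4))
    mir <- normalizeMirna(cohortMirna(co))$normalized
    mirKept <- filterMirnaPrevalence(mir, cohortMeta(co), 0.2)
    res <- runAssociations(de, rpm, mirKept, cohortMeta(co),
                           nBoot = 2000, seed = 99)
    hit <- res[paste(res$gene, res$mirna) %in%
               paste(couplings$gene, couplings$mirna), ]
    expect_true(all(hit$significant))
    expect_equal(sign(hit$slope),
                 sign(couplings$slope[match(paste(hit$gene, hit$mirna),
                     paste(couplings$gene, couplings$mirna))]))
    # false positives bounded: non-planted significant pairs are few
    others <- res[!paste(res$gene, res$mirna) %in%
                  paste(couplings$gene, couplings$mirna), ]
    expect_lte(sum(others$significant), 3)
    # determinism: identical seed gives identical boot_p stream
    res2 <- runAssociations(de, rpm, mirKept, cohortMeta(co),
                            nBoot = 2000, seed = 99)
    expect_identical(res$boot_p, res2$boot_p)
})

test_that("restricting to dysregulated genes empties a null test set", {
    p <- cohortParams(nSubjects = 25, nGenesTotal = 100, nPathwayGenes = 3,
                      nMirnas = 4, rngSeed = 49)
    co <- simulateCohort(p)
    de <- runDE(cohortCounts(co), cohortMeta(co), sprintf("PWG%03d", 1:3))
    rpm <- computeRPMPCG(cohortCounts(co), sprintf("PWG%03d", 1:3))
    mir <- normalizeMirna(cohortMirna(co))$normalized
    res <- runAssociations(de, rpm, mir, cohortMeta(co), nBoot = 200,
                           seed = 1)
    if (all(de$call == "neither")) expect_identical(nrow(res), 0L)
    else expect_true(all(res$gene %in% de$gene[de$call != "neither"]))
})
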