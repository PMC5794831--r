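#' Run the full analysis pipeline
#'
#' Executes the stages in order: gene expression filter, RPMPCG
#' normalization, miRNA 75th-percentile normalization and prevalence filter,
#' paired differential expression, miRNA association on the dysregulated
#' genes, optional seed-region annotation, and a summary. Any stage error
#' aborts with the stage name prepended.
#'
#' @param counts [ExpressionMatrix-class], protein-coding raw counts
#' @param mirna [ExpressionMatrix-class], raw miRNA intensities
#' @param meta sample metadata
#' @param geneSet pathway gene ids to analyse
#' @param utrSeqs,mirnaSeqs optional sequence sets for
#'   [annotateAssociations()]
#' @param stratum,fcHi,fcLo,alpha,prevalence,nBoot,seed,deMethod tuning
#'   parameters; defaults are the study settings (fold-change gates
#'   1.50/0.67, alpha 0.05, 20% prevalence, 10,000 bootstrap draws)
#' @return list with `de`, `associations` (significant pairs only),
#'   `all_pairs`, `normalization` report, and `summary` (named counts)
#' @export
runPipeline <- function(counts, mirna, meta, geneSet, utrSeqs = NULL,
                        mirnaSeqs = NULL, stratum = "all", fcHi = 1.50,
                        fcLo = 0.67, alpha = 0.05, prevalence = 0.20,
                        nBoot = 10000, seed = 1, deMethod = "robust") {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "': ", conditionMessage(e),
                 call. = FALSE))
    }
    filt <- stage("gene_filter", filterGeneExpression(counts, geneSet))
    rpm <- stage("rpmpcg", computeRPMPCG(counts, filt$kept))
    norm <- stage("mirna_normalization", normalizeMirna(mirna))
    mirnaKept <- stage("mirna_prevalence",
                       filterMirnaPrevalence(norm$normalized, meta,
                                             prevalence))
    de <- stage("paired_de",
                runDE(counts, meta, filt$kept, stratum = stratum,
                      fcHi = fcHi, fcLo = fcLo, alpha = alpha,
                      method = deMethod))
    allPairs <- stage("association",
                      runAssociations(de, rpm, mirnaKept, meta,
                                      dysregulatedOnly = TRUE,
                                      nBoot = nBoot, seed = seed,
                                      alpha = alpha))
    if (!is.null(utrSeqs) && !is.null(mirnaSeqs))
        allPairs <- stage("seed_annotation",
                          annotateAssociations(allPairs, utrSeqs, mirnaSeqs))
    sig <- allPairs[allPairs$significant, , drop = FALSE]
    list(de = de, associations = sig, all_pairs = allPairs,
         normalization = norm$report,
         summary = .pipelineSummary(de, sig))
}

.pipelineSummary <- function(de, sig) {
    c(n_genes_tested = nrow(de),
      n_down = sum(de$call == "down"),
      n_up = sum(de$call == "up"),
      n_pairs = nrow(sig),
      n_assoc_genes = length(unique(sig$gene)),
      n_assoc_mirnas = length(unique(sig$mirna)),
      n_seed_matches = sum(sig$seed_match %in% TRUE),
      n_inverse_matches = sum(sig$seed_match %in% TRUE &
                              sig$direction == "inverse"))
}

#' Summarise gene/miRNA associations
#'
#' Tabulates an (annotated) association table the way the study reports it:
#' per miRNA, the associated genes split by seed-match status; per gene, the
#' number of associated miRNAs; and overall totals.
#'
#' @param assocs association `data.frame` with columns `gene`, `mirna`,
#'   `direction` and (optionally) `seed_match`
#' @return list with `per_mirna` (`mirna`, `n_genes`, `genes_with_match`,
#'   `genes_without_match`), `per_gene` (`gene`, `n_mirnas`) and `totals`
#'   (`pairs`, `genes`, `mirnas`, `seed_matches`, `inverse_matches`)
#' @export
summarizeAssociations <- function(assocs) {
    if (nrow(assocs) == 0L)
        return(list(per_mirna = data.frame(mirna = character(0),
                                           n_genes = integer(0),
                                           genes_with_match = character(0),
                                           genes_without_match = character(0)),
                    per_gene = data.frame(gene = character(0),
                                          n_mirnas = integer(0)),
                    totals = c(pairs = 0L, genes = 0L, mirnas = 0L,
                               seed_matches = 0L, inverse_matches = 0L)))
    if (!"seed_match" %in% colnames(assocs)) assocs$seed_match <- NA
    perMirna <- do.call(rbind, lapply(split(assocs, assocs$mirna),
        function(d) data.frame(
            mirna = d$mirna[1L], n_genes = nrow(d),
            genes_with_match = paste(sort(d$gene[d$seed_match %in% TRUE]),
                                     collapse = ","),
            genes_without_match = paste(sort(d$gene[!d$seed_match %in% TRUE]),
                                        collapse = ","),
            stringsAsFactors = FALSE)))
    rownames(perMirna) <- NULL
    perGene <- stats::aggregate(list(n_mirnas = assocs$mirna),
                                by = list(gene = assocs$gene),
                                FUN = length)
    totals <- c(pairs = nrow(assocs),
                genes = length(unique(assocs$gene)),
                mirnas = length(unique(assocs$mirna)),
                seed_matches = sum(assocs$seed_match %in% TRUE),
                inverse_matches = sum(assocs$seed_match %in% TRUE &
                                      assocs$direction == "inverse"))
    list(per_mirna = perMirna, per_gene = perGene, totals = totals)
}
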