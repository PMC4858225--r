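#' Run the full isoform-usage / 3'UTR-shift analysis
#'
#' End-to-end composition of the expression and usage modules, mirroring
#' the isoform-level workflow: (optional) quantile normalization of the
#' transcript expression table, gene-level summation, the 1-FPKM gene
#' reliability filter, restriction to genes with two or more expressed
#' isoforms, isoform fractions and dIF, primary-expression classes,
#' length-distribution summaries, dIF shift distributions, usage subsets
#' a-d with weighted-3'UTR shifts, expression-stratified shifts, and —
#' when DE calls are supplied — the PTC tally and per-DE-group length
#' summaries.
#'
#' @param expression Expression data.frame (`transcript_id`, `gene_id`,
#'   sample columns).
#' @param conditions Named sample-to-condition map (`WT`/`KO`).
#' @param annotations Annotation data.frame ([annotate_transcripts()]).
#' @param de_calls Optional DE-call data.frame (`transcript_id`,
#'   `status`), e.g. from an external table ([read_de_table()]) or, for
#'   synthetic runs with enough replicates, from
#'   [call_differential_expression()].
#' @param normalize Quantile-normalize before analysis (normFPKM units).
#' @param cutoff Expression cutoff (1 FPKM/normFPKM).
#' @param dif_threshold Changing-isoform threshold (fraction, 0.20).
#' @param epsilon MA-plot pseudo-expression.
#' @param variant Weighted-UTR variant ([weighted_utr_length()]).
#' @param bin_edges Expression-stratification bin edges.
#' @return List with components `normalized` (the analysis-unit table),
#'   `gene_expression`, `genes_kept`, `genes_multi`, `genes_analysis`,
#'   `usage`, `primary`, `primary_counts`, `length_by_primary`, `shift`,
#'   `subsets`, `shift_by_subset`, `stratified`, `ma`, and (with DE calls)
#'   `ptc` and `length_by_de`.
#' @export
run_usage_analysis <- function(expression, conditions, annotations,
                               de_calls = NULL, normalize = TRUE,
                               cutoff = 1, dif_threshold = 0.20,
                               epsilon = 0.01, variant = "weighted_mean",
                               bin_edges = c(1, 5, 50, Inf)) {
  validate_expression(expression)
  x <- if (normalize) quantile_normalize(expression) else expression
  g <- sum_gene_expression(x, conditions)
  genes_kept <- filter_expressed_genes(g, cutoff)
  genes_multi <- multi_isoform_genes(x, conditions, cutoff)
  genes_analysis <- intersect(genes_kept, genes_multi)
  usage <- isoform_usage(x, conditions, genes = genes_analysis)
  primary <- classify_primary_expression(x, conditions, cutoff)
  coding <- annotations$transcript_id[annotations$orf_class != "NO_ORF"]
  in_scope <- primary$transcript_id %in% usage$transcript_id &
    primary$transcript_id %in% coding
  primary_counts <- table(factor(
    primary$class[in_scope],
    levels = c("WT_only", "KO_only", "both", "neither")))
  grp <- primary[primary$class != "neither",
                 c("transcript_id", "class")]
  names(grp) <- c("transcript_id", "group")
  length_by_primary <- summarize_length_distributions(
    annotations, grp, genes_multi)
  shift <- usage_shift_distributions(usage, primary)
  subsets <- classify_usage_subsets(
    usage, annotations, x, conditions, threshold = dif_threshold,
    cutoff = cutoff, variant = variant)
  shift_by_subset <- if (!is.null(subsets) && nrow(subsets)) {
    weighted_utr_shift_by_subset(subsets)
  } else {
    NULL
  }
  stratified <- if (!is.null(subsets) && nrow(subsets)) {
    expression_stratified_shift(subsets, bin_edges)
  } else {
    NULL
  }
  ma <- ma_summary(x, conditions, annotations, epsilon = epsilon)
  out <- list(
    normalized = x, gene_expression = g, genes_kept = genes_kept,
    genes_multi = genes_multi, genes_analysis = genes_analysis,
    usage = usage, primary = primary, primary_counts = primary_counts,
    length_by_primary = length_by_primary, shift = shift,
    subsets = subsets, shift_by_subset = shift_by_subset,
    stratified = stratified, ma = ma
  )
  if (!is.null(de_calls)) {
    out$ptc <- ptc_tally(annotations, de_calls)
    de_grp <- de_calls[, c("transcript_id", "status")]
    names(de_grp) <- c("transcript_id", "group")
    out$length_by_de <- summarize_length_distributions(
      annotations, de_grp, genes_multi)
  }
  out
}

#' Write the analysis result tables and a run report
#'
#' One TSV per table plus a structured text run report with gene/transcript
#' counts and the headline statistics.
#'
#' @param res Result list from [run_usage_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_usage_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      utils::write.table(x, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(res$usage, "usage_records.tsv")
  wt(res$primary, "primary_expression.tsv")
  wt(res$length_by_primary$summary, "length_summary_by_primary.tsv")
  wt(res$length_by_primary$tests, "length_tests_by_primary.tsv")
  wt(res$shift, "usage_shift_by_class.tsv")
  wt(res$subsets, "gene_subset_calls.tsv")
  wt(res$shift_by_subset$summary, "weighted_utr_shift_by_subset.tsv")
  wt(res$shift_by_subset$tests, "weighted_utr_shift_tests.tsv")
  wt(res$stratified, "expression_stratified_shift.tsv")
  if (!is.null(res$ptc)) {
    wt(res$ptc$summary, "ptc_tally.tsv")
    wt(res$length_by_de$summary, "length_summary_by_de.tsv")
    wt(res$length_by_de$tests, "length_tests_by_de.tsv")
  }
  rep_lines <- c(
    "utrshiftr run report",
    sprintf("genes_total\t%d", length(unique(res$gene_expression$gene_id))),
    sprintf("genes_kept\t%d", length(res$genes_kept)),
    sprintf("genes_multi_isoform\t%d", length(res$genes_multi)),
    sprintf("genes_analysis\t%d", length(res$genes_analysis)),
    sprintf("usage_records\t%d", nrow(res$usage)),
    sprintf("primary_%s\t%d", names(res$primary_counts),
            as.integer(res$primary_counts))
  )
  if (!is.null(res$subsets)) {
    tab <- table(res$subsets$subset)
    rep_lines <- c(rep_lines,
                   sprintf("subset_%s\t%d", names(tab), as.integer(tab)))
  }
  writeLines(rep_lines, file.path(dir, "run_report.txt"))
  invisible(dir)
}
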