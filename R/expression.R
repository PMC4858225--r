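#' Read / write an isoform expression table
#'
#' Expression tables are TSVs with a header row
#' `transcript_id gene_id <sample columns>`; values are nonnegative FPKM
#' (or normFPKM after [quantile_normalize()]). A sidecar two-column TSV
#' (`sample`, `condition`) maps sample columns to the `WT`/`KO` conditions.
#'
#' @param path File path.
#' @return `read_expression` returns the data.frame;
#'   `read_condition_map` returns a named character vector mapping sample
#'   name to condition.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_expression(x)
  x
}

#' @rdname read_expression
#' @param x Expression data.frame.
#' @export
write_expression <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_condition_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(x$condition, x$sample)
}

#' @rdname read_expression
#' @param conditions Named character vector mapping sample to condition.
#' @export
write_condition_map <- function(conditions, path) {
  utils::write.table(
    data.frame(sample = names(conditions), condition = unname(conditions)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(x) {
  if (!all(c("transcript_id", "gene_id") %in% names(x))) {
    stop("expression table must have transcript_id and gene_id columns")
  }
  vals <- as.matrix(x[, sample_columns(x), drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("negative expression values")
  invisible(x)
}

sample_columns <- function(x) {
  setdiff(names(x), c("transcript_id", "gene_id"))
}

check_conditions <- function(x, conditions) {
  samples <- sample_columns(x)
  missing <- setdiff(samples, names(conditions))
  if (length(missing)) {
    stop("samples without a condition label: ",
         paste(missing, collapse = ", "))
  }
  cond <- conditions[samples]
  if (!all(c("WT", "KO") %in% cond)) {
    stop("both WT and KO conditions need at least one sample")
  }
  cond
}

#' Quantile-normalize an isoform expression table
#'
#' Maps every sample column onto the common reference distribution formed by
#' the per-rank across-sample means, so that after normalization the sorted
#' values of all columns are identical; tied values within a column receive
#' the mean of the reference values for their tied ranks. Units of the
#' result are referred to as normFPKM. The normalization is applied at
#' transcript level, before any gene-level summation.
#'
#' @param x Expression data.frame (`transcript_id`, `gene_id`, samples).
#' @return The table with normalized sample columns and attribute
#'   `unit = "normFPKM"`.
#' @export
quantile_normalize <- function(x) {
  samples <- sample_columns(x)
  if (length(samples) < 2L) {
    stop("quantile normalization needs at least 2 samples")
  }
  m <- as.matrix(x[, samples, drop = FALSE])
  x[, samples] <- quantile_normalize_matrix(m)
  attr(x, "unit") <- "normFPKM"
  x
}

# Reference distribution = per-rank across-sample means; tied entries get
# the mean reference value over their tied ranks.
quantile_normalize_matrix <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  ref_cs <- c(0, cumsum(ref))
  apply(m, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (ref_cs[hi + 1L] - ref_cs[lo]) / (hi - lo + 1L)
  })
}

#' Per-condition mean expression of each transcript
#'
#' Condition-level expression is the arithmetic mean of that condition's
#' replicate columns.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @return data.frame `transcript_id`, `gene_id`, `WT`, `KO`.
#' @export
condition_means <- function(x, conditions) {
  cond <- check_conditions(x, conditions)
  samples <- sample_columns(x)
  m <- as.matrix(x[, samples, drop = FALSE])
  data.frame(
    transcript_id = x$transcript_id, gene_id = x$gene_id,
    WT = rowMeans(m[, cond == "WT", drop = FALSE]),
    KO = rowMeans(m[, cond == "KO", drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' Sum transcript expression to gene level
#'
#' All transcripts belonging to the same gene are summed, per sample, to
#' obtain gene expression; per-condition means are the arithmetic means of
#' the condition's replicate sums.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @return data.frame with `gene_id`, one column per sample, and
#'   condition-mean columns `WT` and `KO`.
#' @export
sum_gene_expression <- function(x, conditions) {
  cond <- check_conditions(x, conditions)
  samples <- sample_columns(x)
  m <- as.matrix(x[, samples, drop = FALSE])
  g <- rowsum(m, group = x$gene_id)
  out <- data.frame(gene_id = rownames(g), g, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$WT <- rowMeans(g[, cond == "WT", drop = FALSE])
  out$KO <- rowMeans(g[, cond == "KO", drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Isoform fraction of gene expression in one condition
#'
#' The fraction of gene expression originating from a transcript:
#' (transcript expression) / (gene expression), computed on condition-mean
#' values. Genes with zero expression in the condition are excluded and
#' reported via the `excluded_genes` attribute rather than divided.
#'
#' @param x Expression data.frame.
#' @param g Gene table from [sum_gene_expression()].
#' @param conditions Named sample-to-condition map.
#' @param condition `"WT"` or `"KO"`.
#' @return Named numeric vector of fractions, indexed by transcript_id,
#'   with attribute `excluded_genes`.
#' @export
isoform_fraction <- function(x, g, conditions, condition = c("WT", "KO")) {
  condition <- match.arg(condition)
  cm <- condition_means(x, conditions)
  gene_val <- stats::setNames(g[[condition]], g$gene_id)[cm$gene_id]
  excluded <- unique(cm$gene_id[gene_val == 0])
  keep <- gene_val > 0
  out <- stats::setNames(cm[[condition]][keep] / gene_val[keep],
                         cm$transcript_id[keep])
  attr(out, "excluded_genes") <- excluded
  out
}

#' Isoform usage records (condition fractions and dIF)
#'
#' One record per transcript of every gene with positive expression in both
#' conditions: the isoform fractions `if_wt` and `if_ko` and their
#' difference `dif = if_ko - if_wt`. Fractions sum to 1 per gene within
#' each condition.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @param genes Optional gene-id subset to restrict to.
#' @return data.frame `transcript_id`, `gene_id`, `if_wt`, `if_ko`, `dif`,
#'   with attribute `excluded_genes` (zero-expression genes).
#' @export
isoform_usage <- function(x, conditions, genes = NULL) {
  if (!is.null(genes)) x <- x[x$gene_id %in% genes, , drop = FALSE]
  g <- sum_gene_expression(x, conditions)
  f_wt <- isoform_fraction(x, g, conditions, "WT")
  f_ko <- isoform_fraction(x, g, conditions, "KO")
  shared <- intersect(names(f_wt), names(f_ko))
  cm <- condition_means(x, conditions)
  idx <- match(shared, cm$transcript_id)
  out <- data.frame(
    transcript_id = shared, gene_id = cm$gene_id[idx],
    if_wt = unname(f_wt[shared]), if_ko = unname(f_ko[shared]),
    stringsAsFactors = FALSE
  )
  out$dif <- out$if_ko - out$if_wt
  attr(out, "excluded_genes") <- union(attr(f_wt, "excluded_genes"),
                                       attr(f_ko, "excluded_genes"))
  out
}

#' Genes passing the 1-FPKM reliability filter
#'
#' Genes with condition-mean expression below `cutoff` in either WT or KO
#' are filtered out (strict: values exactly at the cutoff survive), so
#' downstream isoform fractions are computed only where they are reliable.
#'
#' @param g Gene table from [sum_gene_expression()].
#' @param cutoff Expression cutoff (FPKM/normFPKM).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(g, cutoff = 1) {
  g$gene_id[g$WT >= cutoff & g$KO >= cutoff]
}

#' Genes with two or more expressed isoforms
#'
#' An isoform counts as expressed when its condition-mean expression exceeds
#' `cutoff` in at least one condition.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @param cutoff Expression cutoff.
#' @return Character vector of multi-isoform gene ids.
#' @export
multi_isoform_genes <- function(x, conditions, cutoff = 1) {
  cm <- condition_means(x, conditions)
  expressed <- pmax(cm$WT, cm$KO) > cutoff
  counts <- table(cm$gene_id[expressed])
  names(counts)[counts >= 2L]
}

#' Classify "primarily expressed" transcripts
#'
#' A transcript is primarily expressed in one genotype when its
#' condition-mean expression is above `cutoff` in that genotype and below
#' `cutoff` in the other. Transcripts above the cutoff in both genotypes
#' are `both`; everything else (including values exactly at the cutoff) is
#' `neither`.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @param cutoff Expression cutoff (normFPKM).
#' @return data.frame `transcript_id`, `gene_id`, `class` with class in
#'   `WT_only`, `KO_only`, `both`, `neither`.
#' @export
classify_primary_expression <- function(x, conditions, cutoff = 1) {
  cm <- condition_means(x, conditions)
  cls <- rep("neither", nrow(cm))
  cls[cm$WT > cutoff & cm$KO < cutoff] <- "WT_only"
  cls[cm$KO > cutoff & cm$WT < cutoff] <- "KO_only"
  cls[cm$WT > cutoff & cm$KO > cutoff] <- "both"
  data.frame(transcript_id = cm$transcript_id, gene_id = cm$gene_id,
             class = cls, stringsAsFactors = FALSE)
}

#' MA summary of transcript expression by ORF class
#'
#' Per transcript, `A = log2(mean expression across condition means)` and
#' `M = log2((KO + epsilon) / (WT + epsilon))`, labelled with the
#' transcript's ORF class; per class, a running (windowed) mean of M along
#' A summarizes the fold-change trend, as drawn on MA plots.
#'
#' @param x Expression data.frame.
#' @param conditions Named sample-to-condition map.
#' @param annotations Annotation data.frame ([annotate_transcripts()]).
#' @param epsilon Pseudo-expression added to both conditions.
#' @param window Running-mean window (number of transcripts, made odd and
#'   capped at the class size).
#' @return List with `points` (per-transcript data.frame `transcript_id`,
#'   `orf_class`, `A`, `M`) and `trend` (per-class data.frame `orf_class`,
#'   `A`, `M_smooth` sorted by A).
#' @export
ma_summary <- function(x, conditions, annotations, epsilon = 0.01,
                       window = 101L) {
  cm <- condition_means(x, conditions)
  cls <- stats::setNames(annotations$orf_class, annotations$transcript_id)
  pts <- data.frame(
    transcript_id = cm$transcript_id,
    orf_class = unname(cls[cm$transcript_id]),
    A = log2((cm$WT + cm$KO) / 2 + epsilon),
    M = log2((cm$KO + epsilon) / (cm$WT + epsilon)),
    stringsAsFactors = FALSE
  )
  trend <- do.call(rbind, lapply(split(pts, pts$orf_class), function(p) {
    p <- p[order(p$A), , drop = FALSE]
    k <- min(as.integer(window), nrow(p))
    if (k %% 2L == 0L) k <- max(1L, k - 1L)
    data.frame(orf_class = p$orf_class, A = p$A,
               M_smooth = running_mean(p$M, k), stringsAsFactors = FALSE)
  }))
  rownames(trend) <- NULL
  list(points = pts, trend = trend)
}

# Centered running mean with shrinking windows at the edges.
running_mean <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Plumbing differential-expression test for synthetic runs
#'
#' A simple per-transcript two-sided rank-sum test on log-transformed
#' replicate values with Benjamini-Hochberg FDR control. This is plumbing
#' for synthetic exercises only: real differential-expression calls
#' (e.g. from a count-based model) should be supplied as an external TSV
#' (`transcript_id log2fc pvalue fdr status`) and consumed directly. Note
#' that with 2 replicates per condition the rank-sum test has no power
#' (minimum two-sided p = 1/3).
#'
#' @param x Expression data.frame with >= 2 replicates per condition.
#' @param conditions Named sample-to-condition map.
#' @param alpha FDR threshold for calling up/down status.
#' @param epsilon Pseudo-expression for the log transform and fold change.
#' @return data.frame `transcript_id`, `log2_fold_change`, `p_value`,
#'   `fdr`, `status` (`up`/`down`/`non`).
#' @export
call_differential_expression <- function(x, conditions, alpha = 0.05,
                                         epsilon = 0.01) {
  cond <- check_conditions(x, conditions)
  if (sum(cond == "WT") < 2L || sum(cond == "KO") < 2L) {
    stop("fewer than 2 replicates per condition: supply an external ",
         "differential-expression table instead")
  }
  samples <- sample_columns(x)
  m <- log2(as.matrix(x[, samples, drop = FALSE]) + epsilon)
  wt <- m[, cond == "WT", drop = FALSE]
  ko <- m[, cond == "KO", drop = FALSE]
  p <- vapply(seq_len(nrow(m)), function(i) {
    rank_test(ko[i, ], wt[i, ])
  }, numeric(1))
  lfc <- log2((rowMeans(2^ko - epsilon) + epsilon) /
                (rowMeans(2^wt - epsilon) + epsilon))
  fdr <- stats::p.adjust(p, method = "BH")
  status <- rep("non", nrow(m))
  status[fdr < alpha & lfc > 0] <- "up"
  status[fdr < alpha & lfc < 0] <- "down"
  data.frame(transcript_id = x$transcript_id, log2_fold_change = lfc,
             p_value = p, fdr = fdr, status = status,
             stringsAsFactors = FALSE)
}

#' Read / write differential-expression call tables
#'
#' TSV dialect: `transcript_id log2fc pvalue fdr status`.
#'
#' @param path File path.
#' @return data.frame with columns `transcript_id`, `log2_fold_change`,
#'   `p_value`, `fdr`, `status`.
#' @export
read_de_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(x) <- c("transcript_id", "log2_fold_change", "p_value", "fdr",
                "status")[seq_along(names(x))]
  x
}

#' @rdname read_de_table
#' @param de DE-call data.frame.
#' @export
write_de_table <- function(de, path) {
  out <- de
  names(out) <- c("transcript_id", "log2fc", "pvalue", "fdr",
                  "status")[seq_along(names(out))]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
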