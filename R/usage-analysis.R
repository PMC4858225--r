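#' Two-sided Mann-Whitney / Wilcoxon rank test
#'
#' Thin wrapper fixing the conventions used throughout the package: exact
#' null distribution when both groups have at most `exact_max` observations
#' and there are no ties; normal approximation with tie and continuity
#' correction otherwise. `paired = TRUE` gives the Wilcoxon signed-rank
#' test of a zero median difference.
#'
#' @param x,y Numeric samples.
#' @param paired Paired (signed-rank) test instead of two-sample rank-sum.
#' @param exact_max Largest group size for which the exact null is used.
#' @return Two-sided p-value.
#' @export
rank_test <- function(x, y, paired = FALSE, exact_max = 50L) {
  if (paired) {
    if (all(x == y)) return(1)          # no nonzero differences
  } else if (length(unique(c(x, y))) == 1L) {
    return(1)                           # fully degenerate comparison
  }
  has_ties <- anyDuplicated(if (paired) {
    d <- x - y
    abs(d[d != 0])
  } else {
    c(x, y)
  }) > 0L
  exact <- !has_ties && length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact,
                       correct = !exact)$p.value
  )
}

#' Tally PTC classes within differential-expression groups
#'
#' Cross-tabulates ORF class against DE status (`up`/`down`/`non`) and
#' reports, per status row, the count and percentage of PTC-positive
#' transcripts (percentage = 100 * count / row total). Transcripts missing
#' either label are excluded and counted.
#'
#' @param annotations Annotation data.frame ([annotate_transcripts()]).
#' @param de_calls DE-call data.frame with `transcript_id` and `status`.
#' @return List with `counts` (status x orf_class contingency table),
#'   `summary` (per-status data.frame `status`, `n`, `n_ptc`, `pct_ptc`),
#'   `overall` (one-row data.frame with the pooled tally) and `n_excluded`.
#' @export
ptc_tally <- function(annotations, de_calls) {
  status <- stats::setNames(de_calls$status, de_calls$transcript_id)
  st <- unname(status[annotations$transcript_id])
  ok <- !is.na(st) & !is.na(annotations$orf_class)
  n_excluded <- sum(!ok)
  cls <- annotations$orf_class[ok]
  st <- st[ok]
  counts <- table(status = st, orf_class = cls)
  per_status <- do.call(rbind, lapply(split(cls, st), function(cc) {
    data.frame(n = length(cc), n_ptc = sum(cc == "PTC_POSITIVE"))
  }))
  summary <- data.frame(status = rownames(per_status), per_status,
                        row.names = NULL, stringsAsFactors = FALSE)
  summary$pct_ptc <- 100 * summary$n_ptc / summary$n
  overall <- data.frame(
    status = "all", n = length(cls), n_ptc = sum(cls == "PTC_POSITIVE"),
    stringsAsFactors = FALSE
  )
  overall$pct_ptc <- 100 * overall$n_ptc / overall$n
  list(counts = counts, summary = summary, overall = overall,
       n_excluded = n_excluded)
}

#' Length-distribution summaries across transcript groups
#'
#' For transcripts of multi-isoform genes with an annotated ORF, summarizes
#' the distributions of full-length transcript, ORF, 5'UTR and 3'UTR
#' lengths per group (e.g. up/down/non-regulated, or the primary-expression
#' classes), with 25th/50th/75th percentiles (linear interpolation between
#' order statistics) and all pairwise two-sided rank-sum tests, reported
#' raw and BH-adjusted.
#'
#' @param annotations Annotation data.frame.
#' @param groups data.frame with `transcript_id` and `group`.
#' @param multi_genes Character vector of multi-isoform gene ids; only
#'   transcripts of these genes enter the summaries.
#' @return List with `summary` (`group`, `feature`, `n`, `p25`, `p50`,
#'   `p75`) and `tests` (`feature`, `group_a`, `group_b`, `p_value`,
#'   `p_adj`). Comparisons where a group has fewer than 2 values are
#'   skipped with a warning.
#' @export
summarize_length_distributions <- function(annotations, groups,
                                           multi_genes) {
  grp <- stats::setNames(groups$group, groups$transcript_id)
  ann <- annotations[annotations$gene_id %in% multi_genes &
                       annotations$orf_class != "NO_ORF", , drop = FALSE]
  ann$group <- unname(grp[ann$transcript_id])
  ann <- ann[!is.na(ann$group), , drop = FALSE]
  feats <- list(
    full_length = ann$utr5_len + ann$orf_len + ann$utr3_len,
    orf = ann$orf_len, utr5 = ann$utr5_len, utr3 = ann$utr3_len
  )
  summary <- do.call(rbind, lapply(names(feats), function(f) {
    vals <- split(feats[[f]], ann$group)
    do.call(rbind, lapply(names(vals), function(g) {
      q <- stats::quantile(vals[[g]], c(.25, .5, .75), type = 7, names = FALSE)
      data.frame(group = g, feature = f, n = length(vals[[g]]),
                 p25 = q[1], p50 = q[2], p75 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(names(feats), function(f) {
    vals <- split(feats[[f]], ann$group)
    gs <- names(vals)
    if (length(gs) < 2L) return(NULL)
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(p) {
      if (length(vals[[p[1]]]) < 2L || length(vals[[p[2]]]) < 2L) {
        warning("skipping comparison ", p[1], " vs ", p[2], " for ", f,
                ": group with fewer than 2 transcripts")
        return(NULL)
      }
      data.frame(feature = f, group_a = p[1], group_b = p[2],
                 p_value = rank_test(vals[[p[1]]], vals[[p[2]]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(tests) && nrow(tests)) {
    tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  }
  rownames(summary) <- NULL
  list(summary = summary, tests = tests)
}

#' Isoform-fraction shift distributions per primary-expression class
#'
#' For each primary-expression class, summarizes the distribution of dIF
#' (KO fraction minus WT fraction) and tests the WT and KO fraction
#' distributions against each other with a two-sided paired rank
#' (signed-rank) test. Usage records should already be restricted to
#' filtered, multi-isoform genes. Empty classes are skipped with a warning.
#'
#' @param usage Usage records ([isoform_usage()]).
#' @param primary data.frame with `transcript_id` and `class`
#'   ([classify_primary_expression()]).
#' @return data.frame `class`, `n`, `mean_dif`, `p25`, `p50`, `p75`,
#'   `p_value`.
#' @export
usage_shift_distributions <- function(usage, primary) {
  cls <- stats::setNames(primary$class, primary$transcript_id)
  usage$class <- unname(cls[usage$transcript_id])
  usage <- usage[!is.na(usage$class), , drop = FALSE]
  wanted <- c("WT_only", "KO_only", "both", "neither")
  out <- lapply(intersect(wanted, unique(usage$class)), function(g) {
    u <- usage[usage$class == g, , drop = FALSE]
    if (nrow(u) == 0L) {
      warning("empty primary-expression class skipped: ", g)
      return(NULL)
    }
    q <- stats::quantile(u$dif, c(.25, .5, .75), type = 7, names = FALSE)
    p <- if (nrow(u) >= 2L && any(u$dif != 0)) {
      rank_test(u$if_ko, u$if_wt, paired = TRUE)
    } else {
      1
    }
    data.frame(class = g, n = nrow(u), mean_dif = mean(u$dif),
               p25 = q[1], p50 = q[2], p75 = q[3], p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average weighted 3'UTR length of a gene
#'
#' Each isoform's 3'UTR length is weighted by its isoform fraction
#' (e_i / e_G). The `weighted_mean` variant returns
#' `sum(l_i * e_i / e_G)` — the weights already sum to 1, so the result is
#' a proper weighted mean bounded by `[min(l), max(l)]`. The
#' `printed_formula` variant additionally divides by the number of isoforms
#' n; it is provided because the originating methods equation literally
#' carries that divisor, but `weighted_mean` is the default.
#'
#' @param l 3'UTR lengths of the gene's isoforms (nt).
#' @param e Matching isoform expression values; `sum(e)` must be positive.
#' @param variant `"weighted_mean"` or `"printed_formula"`.
#' @return Length in nt.
#' @export
weighted_utr_length <- function(l, e,
                                variant = c("weighted_mean",
                                            "printed_formula")) {
  variant <- match.arg(variant)
  stopifnot(length(l) == length(e), length(l) >= 1L)
  e_g <- sum(e)
  if (e_g <= 0) stop("gene expression must be positive")
  w <- sum(l * e / e_g)
  if (variant == "printed_formula") w / length(l) else w
}

#' Classify genes into isoform-usage subsets and compute weighted-UTR shifts
#'
#' A changing isoform is one whose isoform fraction moves by at least
#' `threshold` (absolute percentage points, default 0.20) between
#' conditions. Genes are partitioned into: (a) no changing isoforms,
#' (b) only increasing, (c) only decreasing, (d) both. For each gene the
#' average weighted 3'UTR length is computed per condition
#' ([weighted_utr_length()], weights = condition-mean expression) and the
#' shift `delta = KO - WT` reported, along with the mean gene expression
#' used for expression stratification.
#'
#' Genes enter the analysis only if they pass the expression filters
#' carried by `usage`, and — when `require_all_expressed` (the default) —
#' only if every isoform exceeds `cutoff` in both condition means, so the
#' per-condition weights are reliable. Isoforms without an annotated ORF
#' have no 3'UTR; they are excluded from the weighting, with their
#' expression removed from the gene total, but their dIF still counts
#' towards the subset call.
#'
#' @param usage Usage records ([isoform_usage()]), restricted to filtered
#'   multi-isoform genes.
#' @param annotations Annotation data.frame.
#' @param x Expression data.frame (for per-condition weights).
#' @param conditions Named sample-to-condition map.
#' @param threshold Minimum |dIF| for a changing isoform.
#' @param cutoff Per-isoform expression cutoff for
#'   `require_all_expressed`.
#' @param require_all_expressed Restrict to genes whose isoforms all exceed
#'   `cutoff` in both conditions.
#' @param variant Weighted-UTR variant, see [weighted_utr_length()].
#' @return data.frame `gene_id`, `subset`, `weighted_utr_wt`,
#'   `weighted_utr_ko`, `delta_weighted_utr`, `mean_gene_expression`.
#' @export
classify_usage_subsets <- function(usage, annotations, x, conditions,
                                   threshold = 0.20, cutoff = 1,
                                   require_all_expressed = TRUE,
                                   variant = "weighted_mean") {
  cm <- condition_means(x, conditions)
  cm <- cm[cm$transcript_id %in% usage$transcript_id, , drop = FALSE]
  utr3 <- stats::setNames(annotations$utr3_len, annotations$transcript_id)
  orf_cls <- stats::setNames(annotations$orf_class,
                             annotations$transcript_id)
  by_gene <- split(usage, usage$gene_id)
  cm_by_gene <- split(cm, cm$gene_id)
  rows <- lapply(names(by_gene), function(gid) {
    u <- by_gene[[gid]]
    e <- cm_by_gene[[gid]]
    if (is.null(e)) return(NULL)
    if (require_all_expressed &&
        !all(e$WT > cutoff & e$KO > cutoff)) {
      return(NULL)
    }
    up <- any(u$dif >= threshold)
    down <- any(u$dif <= -threshold)
    subset <- if (up && down) "d" else if (up) "b" else if (down) "c"
              else "a"
    coding <- !is.na(orf_cls[e$transcript_id]) &
      orf_cls[e$transcript_id] != "NO_ORF"
    if (!any(coding)) return(NULL)
    l <- unname(utr3[e$transcript_id[coding]])
    w_wt <- weighted_utr_length(l, e$WT[coding], variant)
    w_ko <- weighted_utr_length(l, e$KO[coding], variant)
    data.frame(
      gene_id = gid, subset = subset, weighted_utr_wt = w_wt,
      weighted_utr_ko = w_ko, delta_weighted_utr = w_ko - w_wt,
      mean_gene_expression = (sum(e$WT) + sum(e$KO)) / 2,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighted-3'UTR-shift distributions per isoform-usage subset
#'
#' Summarizes the per-gene shift in average weighted 3'UTR length within
#' each usage subset, and tests subsets b, c and d against the no-change
#' subset a with two-sided Mann-Whitney rank tests.
#'
#' @param calls Gene subset calls ([classify_usage_subsets()]).
#' @return List with `summary` (`subset`, `n`, `p25`, `p50` (median),
#'   `p75` of the shift) and `tests` (`subset`, `p_value` vs subset a;
#'   `NULL` when subset a is empty, with a warning).
#' @export
weighted_utr_shift_by_subset <- function(calls) {
  by_subset <- split(calls$delta_weighted_utr, calls$subset)
  summary <- do.call(rbind, lapply(names(by_subset), function(s) {
    v <- by_subset[[s]]
    q <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(subset = s, n = length(v), p25 = q[1], p50 = q[2],
               p75 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  a <- by_subset[["a"]]
  tests <- NULL
  if (is.null(a) || length(a) == 0L) {
    warning("subset a empty: rank tests against it skipped")
  } else {
    others <- intersect(c("b", "c", "d"), names(by_subset))
    tests <- do.call(rbind, lapply(others, function(s) {
      data.frame(subset = s, n = length(by_subset[[s]]),
                 p_value = rank_test(by_subset[[s]], a),
                 stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(summary = summary, tests = tests)
}

#' Expression-stratified weighted-3'UTR shifts
#'
#' Bins genes by mean gene expression (default bin edges 1, 5, 50, Inf —
#' low, midrange, high) and reports the median weighted-UTR shift and gene
#' count per bin and usage subset. Empty bins are reported with n = 0.
#'
#' @param calls Gene subset calls ([classify_usage_subsets()]).
#' @param edges Increasing vector of bin edges; bins are
#'   `[edges[i], edges[i+1])`.
#' @return data.frame `bin`, `subset`, `n`, `median_delta`.
#' @export
expression_stratified_shift <- function(calls, edges = c(1, 5, 50, Inf)) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  labels <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  bin <- cut(calls$mean_gene_expression, breaks = edges, right = FALSE,
             labels = labels)
  subsets <- sort(unique(calls$subset))
  grid <- expand.grid(bin = labels, subset = subsets,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- calls$delta_weighted_utr[!is.na(bin) & bin == grid$bin[i] &
                                    calls$subset == grid$subset[i]]
    data.frame(bin = grid$bin[i], subset = grid$subset[i], n = length(v),
               median_delta = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
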