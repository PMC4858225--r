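# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration or direct arithmetic, never through the package
# functions they check.

# Brute-force 50-nt-rule oracle: enumerate every exon-exon junction offset
# of the spliced transcript and ask whether the stop codon ends more than
# `threshold` nt upstream of any junction.
oracle_ptc <- function(model, stop_end, threshold = 50L) {
  lens <- abs(model$ends - model$starts) + 1L
  n <- length(lens)
  if (n < 2L) return(FALSE)
  junctions <- cumsum(lens)[-n]
  any(junctions - stop_end > threshold)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all rank
# assignments (tie-free data only).
mw_enumerate_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  all_ranks <- seq_len(m + n)
  us <- apply(sets, 2, function(ii) sum(all_ranks[ii]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Tie-averaged quantile normalization, written directly from its
# definition: reference = per-rank across-sample means of the sorted
# columns; each value maps to the mean reference value of its tied ranks.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "min")
    n_tied <- table(col)[as.character(col)]
    vapply(seq_along(col), function(i) {
      mean(ref[r[i]:(r[i] + n_tied[i] - 1L)])
    }, numeric(1))
  })
}

# Small handmade expression fixture: one sample per condition, values are
# condition means by construction.
make_expression <- function(transcript_id, gene_id, wt, ko) {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             WT_1 = wt, KO_1 = ko, stringsAsFactors = FALSE)
}

fixture_conditions <- c(WT_1 = "WT", KO_1 = "KO")

# Annotation rows built directly from generator truth (exact by the
# annotation round-trip property; used where only lengths/classes matter).
annotation_from_truth <- function(truth) {
  data.frame(
    transcript_id = truth$transcript_id, gene_id = truth$gene_id,
    orf_class = ifelse(truth$ptc, "PTC_POSITIVE", "PTC_NEGATIVE"),
    cds_start_mrna = truth$utr5_len,
    stop_end_mrna = truth$utr5_len + truth$orf_len,
    utr5_len = truth$utr5_len, orf_len = truth$orf_len,
    utr3_len = truth$utr3_len,
    junction_distance = truth$junction_distance,
    stringsAsFactors = FALSE
  )
}
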