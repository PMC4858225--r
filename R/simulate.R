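#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: multi-isoform
#' genes whose isoforms share an ORF but differ in 3'UTR length (APA
#' variants), a configurable fraction of PTC-positive splice variants
#' (realized as an extra 3'UTR intron whose distance from the stop codon to
#' the last junction is drawn uniformly from `ptc_junction_range`), two
#' conditions (WT, KO) in replicates, and a planted KO-specific usage
#' increase of the longest-3'UTR isoform of effect genes. For effect genes
#' the long isoform receives the smallest usage share in WT, emulating NMD
#' suppression of long-3'UTR isoforms in wild-type germ cells.
#'
#' @param n_genes Number of genes.
#' @param isoform_range Inclusive range of isoforms per gene (uniform).
#' @param utr5_meanlog,utr5_sdlog Lognormal parameters of 5'UTR length
#'   (default median 150 nt).
#' @param orf_range ORF length range in nt (uniform over multiples of 3,
#'   start through stop codon).
#' @param utr3_meanlog,utr3_sdlog Lognormal parameters of the shortest
#'   3'UTR (default median 400 nt).
#' @param apa_extension_range Extra 3'UTR length range of APA variants.
#' @param ptc_isoform_fraction Probability that an isoform is a planted
#'   PTC-positive splice variant.
#' @param effect_gene_fraction Fraction of genes carrying the planted
#'   KO usage shift (drawn among multi-isoform genes).
#' @param planted_dif Isoform-fraction increase planted onto the
#'   longest-3'UTR isoform in KO.
#' @param replicates Replicates per condition (2 emulates a duplicate
#'   design; 3 a triplicate design).
#' @param noise_sd Lognormal (sdlog) replicate noise on expression.
#' @param scale_range Per-sample scale-factor range (exercises quantile
#'   normalization).
#' @param dirichlet_concentration Concentration of the Dirichlet baseline
#'   isoform fractions.
#' @param gene_expr_meanlog,gene_expr_sdlog Lognormal parameters of
#'   baseline gene expression (FPKM).
#' @param intron_range Intron length range (also used for the planted
#'   3'UTR skip).
#' @param exon_count_range Range of exon counts of the shared base
#'   structure (junctions fall in the 5'UTR/CDS region).
#' @param ptc_junction_range Range of the planted stop-to-last-junction
#'   distance of PTC isoforms (all > 50 so planted isoforms violate the
#'   50-nt rule by construction).
#' @param flank Plain genomic flank on either side of each gene locus.
#' @param sequences Generate genome and mRNA sequences (`FALSE` gives a
#'   structure-only scenario for geometry studies).
#' @param seed Integer seed; the whole scenario is a deterministic
#'   function of the configuration.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 1000L,
                            isoform_range = c(1L, 5L),
                            utr5_meanlog = log(150), utr5_sdlog = 0.4,
                            orf_range = c(300L, 3000L),
                            utr3_meanlog = log(400), utr3_sdlog = 0.6,
                            apa_extension_range = c(500L, 2000L),
                            ptc_isoform_fraction = 0.15,
                            effect_gene_fraction = 0.2,
                            planted_dif = 0.25,
                            replicates = 2L,
                            noise_sd = 0.2,
                            scale_range = c(0.7, 1.4),
                            dirichlet_concentration = 2,
                            gene_expr_meanlog = log(8),
                            gene_expr_sdlog = 1.2,
                            intron_range = c(60L, 200L),
                            exon_count_range = c(1L, 6L),
                            ptc_junction_range = c(51L, 500L),
                            flank = 25L,
                            sequences = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 0,
    cfg$ptc_isoform_fraction >= 0, cfg$ptc_isoform_fraction <= 1,
    cfg$effect_gene_fraction >= 0, cfg$effect_gene_fraction <= 1,
    cfg$planted_dif >= -1, cfg$planted_dif <= 1,
    cfg$replicates >= 1, cfg$noise_sd >= 0,
    cfg$orf_range[1] >= 6, cfg$ptc_junction_range[1] > 50
  )
  class(cfg) <- "scenario_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Coding sequence with exactly one in-frame stop, planted at the end.
random_cds <- function(orf_len) {
  n_codon <- orf_len %/% 3L
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  body <- sample(sense, n_codon - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# Map 0-based backbone offsets to 1-based genomic sense coordinates, given
# base-intron junction offsets J and intron lengths iv.
backbone_gpos <- function(o, junctions, intron_lens, flank) {
  shift <- vapply(o, function(x) sum(intron_lens[junctions <= x]),
                  numeric(1))
  flank + o + 1L + as.integer(shift)
}

# Split half-open backbone intervals at base junctions and convert to
# genomic sense-strand exon blocks.
backbone_exons <- function(intervals, junctions, intron_lens, flank) {
  blocks <- list()
  for (i in seq_len(nrow(intervals))) {
    from <- intervals$from[i]; to <- intervals$to[i]
    cuts <- junctions[junctions > from & junctions < to]
    bounds <- c(from, cuts, to)
    for (j in seq_len(length(bounds) - 1L)) {
      a <- bounds[j]; b <- bounds[j + 1L] - 1L
      blocks[[length(blocks) + 1L]] <-
        c(backbone_gpos(a, junctions, intron_lens, flank),
          backbone_gpos(b, junctions, intron_lens, flank))
    }
  }
  m <- do.call(rbind, blocks)
  data.frame(start = m[, 1], end = m[, 2])
}

flip_minus <- function(exons, chrom_len) {
  data.frame(start = chrom_len - exons$end + 1L,
             end = chrom_len - exons$start + 1L)
}

#' Simulate transcript structures, genome and ground truth
#'
#' Builds one locus per gene: all isoforms share the 5'UTR and CDS (and
#' their base introns, which fall in the 5'UTR/CDS region so that ordinary
#' isoforms keep their stop in the last exon), APA isoforms differ only in
#' the 3' extent of the final exon, and PTC isoforms carry one extra 3'UTR
#' intron placing the last junction 51-500 nt downstream of the stop.
#' Coding sequences contain exactly one in-frame stop, at the planted
#' position. Strands are assigned at random and minus-strand loci are
#' stored reverse-complemented.
#'
#' @param cfg A [scenario_config()].
#' @return List with `models` (assembled transcript models), `ref_models`
#'   and `ref_records` (reference transcripts with CDS/start codons),
#'   `genome` (named character vector, `NULL` for structure-only
#'   scenarios), `truth` (per-transcript data.frame) and `cfg`.
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  models <- list()
  ref_models <- list()
  ref_records <- list()
  genome <- if (cfg$sequences) character(cfg$n_genes) else NULL
  truth <- vector("list", cfg$n_genes)
  chroms <- sprintf("chr%05d", seq_len(cfg$n_genes))
  for (i in seq_len(cfg$n_genes)) {
    gene <- simulate_gene(cfg, i, chroms[i])
    models <- c(models, gene$models)
    ref_models[[gene$ref_model$transcript_id]] <- gene$ref_model
    ref_records[[gene$ref_record$transcript_id]] <- gene$ref_record
    if (cfg$sequences) genome[i] <- gene$chrom_seq
    truth[[i]] <- gene$truth
  }
  if (cfg$sequences) names(genome) <- chroms
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0),
      n_isoforms = integer(0), utr5_len = integer(0),
      orf_len = integer(0), utr3_len = integer(0), ptc = logical(0),
      junction_distance = integer(0), is_long = logical(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(truth) <- NULL
  list(models = models, ref_models = ref_models,
       ref_records = ref_records, genome = genome, truth = truth,
       cfg = cfg)
}

simulate_gene <- function(cfg, i, chrom) {
  gid <- sprintf("G%05d", i)
  strand <- sample(c("+", "-"), 1L)
  k <- sample(cfg$isoform_range[1]:cfg$isoform_range[2], 1L)
  utr5 <- max(10L, as.integer(round(stats::rlnorm(1, cfg$utr5_meanlog,
                                                  cfg$utr5_sdlog))))
  orf <- 3L * sample((cfg$orf_range[1] %/% 3L):(cfg$orf_range[2] %/% 3L),
                     1L)
  U <- utr5 + orf
  utr3_base <- max(60L, as.integer(round(stats::rlnorm(
    1, cfg$utr3_meanlog, cfg$utr3_sdlog))))
  utr3 <- rep(utr3_base, k)
  if (k >= 2L) {
    ext <- sort(as.integer(round(stats::runif(
      k - 1L, cfg$apa_extension_range[1], cfg$apa_extension_range[2]))))
    utr3[2:k] <- utr3_base + ext
  }
  ptc <- stats::runif(k) < cfg$ptc_isoform_fraction
  # PTC isoforms need room for the pre-junction 3'UTR stretch (>50 nt) and
  # a final exon; short 3'UTRs are extended before planting.
  min_tail <- 60L
  need <- cfg$ptc_junction_range[1] + min_tail + 1L
  utr3[ptc & utr3 < need] <- utr3[ptc & utr3 < need] + 600L
  # keep 3'UTR lengths unique so APA variants are distinct transcripts
  while (anyDuplicated(utr3)) {
    dup <- which(duplicated(utr3))
    utr3[dup] <- utr3[dup] + seq_along(dup)
  }
  a <- rep(NA_integer_, k)   # stop-to-last-junction distance of PTC forms
  skip <- rep(NA_integer_, k)
  for (j in which(ptc)) {
    a[j] <- sample(cfg$ptc_junction_range[1]:
                     min(cfg$ptc_junction_range[2], utr3[j] - min_tail),
                   1L)
    skip[j] <- sample(cfg$intron_range[1]:cfg$intron_range[2], 1L)
  }
  backbone_utr3 <- max(utr3 + ifelse(ptc, skip, 0L))
  n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
  junctions <- if (n_ex > 1L) {
    sort(sample(seq_len(U - 1L), n_ex - 1L))
  } else {
    integer(0)
  }
  intron_lens <- if (n_ex > 1L) {
    sample(cfg$intron_range[1]:cfg$intron_range[2], n_ex - 1L,
           replace = TRUE)
  } else {
    integer(0)
  }
  B <- U + backbone_utr3
  chrom_len <- 2L * cfg$flank + B + sum(intron_lens)

  build_exons <- function(intervals) {
    ex <- backbone_exons(intervals, junctions, intron_lens, cfg$flank)
    if (strand == "-") flip_minus(ex, chrom_len) else ex
  }
  iso_models <- vector("list", k)
  tids <- sprintf("%s.T%d", gid, seq_len(k))
  for (j in seq_len(k)) {
    intervals <- if (ptc[j]) {
      data.frame(from = c(0L, U + a[j] + skip[j]),
                 to = c(U + a[j], U + a[j] + skip[j] + (utr3[j] - a[j])))
    } else {
      data.frame(from = 0L, to = U + utr3[j])
    }
    ex <- build_exons(intervals)
    iso_models[[j]] <- transcript_model(tids[j], gid, chrom, strand,
                                        ex$start, ex$end)
  }
  names(iso_models) <- tids
  # reference transcript: base structure with the shortest 3'UTR, carrying
  # CDS (stop codon excluded, GTF convention) and start_codon features
  ref_tid <- paste0(gid, ".ref")
  ref_ex <- build_exons(data.frame(from = 0L, to = U + min(utr3)))
  ref_model <- transcript_model(ref_tid, gid, chrom, strand,
                                ref_ex$start, ref_ex$end)
  cds_blocks <- mrna_interval_to_blocks(ref_model, utr5, U - 3L)
  if (strand == "-") {
    cds_blocks <- cds_blocks[order(-cds_blocks$start), , drop = FALSE]
  }
  ref_record <- list(
    transcript_id = ref_tid, gene_id = gid, chrom = chrom, strand = strand,
    cds_starts = cds_blocks$start, cds_ends = cds_blocks$end,
    start_codon_genomic = mrna_to_genomic(ref_model, utr5)
  )
  chrom_seq <- NULL
  if (cfg$sequences) {
    backbone <- paste0(random_dna(utr5), random_cds(orf),
                       random_dna(backbone_utr3))
    bounds <- c(0L, junctions, B)
    segs <- substring(backbone, bounds[-length(bounds)] + 1L, bounds[-1])
    pieces <- character(2L * length(segs) - 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- segs
    if (length(intron_lens)) {
      pieces[seq(2L, length(pieces), by = 2L)] <-
        vapply(intron_lens, random_dna, character(1))
    }
    sense <- paste0(random_dna(cfg$flank), paste(pieces, collapse = ""),
                    random_dna(cfg$flank))
    chrom_seq <- if (strand == "-") revcomp(sense) else sense
  }
  last_base_junction <- if (length(junctions)) max(junctions) else NA_integer_
  truth <- data.frame(
    transcript_id = tids, gene_id = gid, chrom = chrom, strand = strand,
    n_isoforms = k, utr5_len = utr5, orf_len = orf, utr3_len = utr3,
    ptc = ptc,
    junction_distance = ifelse(ptc, a, last_base_junction - U),
    is_long = seq_len(k) == which.max(utr3) & k >= 2L,
    stringsAsFactors = FALSE
  )
  list(models = iso_models, ref_model = ref_model,
       ref_record = ref_record, chrom_seq = chrom_seq, truth = truth)
}

#' Simulate replicate expression tables with a planted usage shift
#'
#' Baseline gene expression is lognormal and baseline isoform fractions are
#' Dirichlet. For effect genes (drawn among multi-isoform genes) the
#' longest-3'UTR isoform receives the smallest WT usage share, and its KO
#' fraction is increased by `planted_dif` with the remaining isoforms
#' rescaled so gene expression is conserved in expectation. Replicate
#' values carry multiplicative lognormal noise and per-sample scale
#' factors.
#'
#' @param cfg A [scenario_config()].
#' @param truth Truth table from [simulate_annotation()].
#' @return List with `expression` (data.frame `transcript_id`, `gene_id`,
#'   sample columns), `conditions` (named map) and `truth` (input truth
#'   augmented with `effect_gene`, `if_wt_true`, `if_ko_true`, `dif_true`,
#'   `gene_expr`, `delta_weighted_utr_true`).
#' @export
simulate_expression <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  genes <- unique(truth$gene_id)
  n_iso <- stats::setNames(truth$n_isoforms[!duplicated(truth$gene_id)],
                           genes)
  multi <- genes[n_iso[genes] >= 2L]
  n_effect <- min(length(multi),
                  as.integer(round(cfg$effect_gene_fraction *
                                     length(genes))))
  effect_genes <- if (n_effect > 0L) sample(multi, n_effect) else character(0)
  gene_expr <- stats::setNames(
    stats::rlnorm(length(genes), cfg$gene_expr_meanlog,
                  cfg$gene_expr_sdlog), genes)
  truth$effect_gene <- truth$gene_id %in% effect_genes
  truth$if_wt_true <- NA_real_
  truth$if_ko_true <- NA_real_
  for (g in genes) {
    idx <- which(truth$gene_id == g)
    k <- length(idx)
    f <- stats::rgamma(k, shape = cfg$dirichlet_concentration)
    f <- f / sum(f)
    f_ko <- f
    if (g %in% effect_genes) {
      long <- which(truth$is_long[idx])[1]
      # NMD-active WT suppresses the long-3'UTR isoform
      ord <- order(f)
      f_sorted <- f[ord]
      f <- numeric(k)
      f[long] <- f_sorted[1]
      f[-long] <- f_sorted[-1]
      f_ko <- f
      f_ko[long] <- f[long] + cfg$planted_dif
      if (k > 1L && (1 - f[long]) > 0) {
        f_ko[-long] <- f[-long] * (1 - f_ko[long]) / (1 - f[long])
      }
    }
    truth$if_wt_true[idx] <- f
    truth$if_ko_true[idx] <- f_ko
  }
  truth$dif_true <- truth$if_ko_true - truth$if_wt_true
  truth$gene_expr <- unname(gene_expr[truth$gene_id])
  delta <- vapply(split(truth, truth$gene_id), function(tt) {
    sum(tt$utr3_len * tt$if_ko_true) - sum(tt$utr3_len * tt$if_wt_true)
  }, numeric(1))
  truth$delta_weighted_utr_true <- unname(delta[truth$gene_id])
  r <- cfg$replicates
  samples <- c(sprintf("WT_%d", seq_len(r)), sprintf("KO_%d", seq_len(r)))
  cond <- stats::setNames(rep(c("WT", "KO"), each = r), samples)
  scales <- stats::runif(length(samples), cfg$scale_range[1],
                         cfg$scale_range[2])
  m <- matrix(0, nrow = nrow(truth), ncol = length(samples),
              dimnames = list(NULL, samples))
  for (s in seq_along(samples)) {
    f <- if (cond[s] == "WT") truth$if_wt_true else truth$if_ko_true
    noise <- if (cfg$noise_sd > 0) {
      exp(stats::rnorm(nrow(truth), 0, cfg$noise_sd))
    } else {
      1
    }
    m[, s] <- truth$gene_expr * f * noise * scales[s]
  }
  expression <- data.frame(transcript_id = truth$transcript_id,
                           gene_id = truth$gene_id, m,
                           check.names = FALSE, stringsAsFactors = FALSE)
  list(expression = expression, conditions = cond, truth = truth)
}

#' Generate and write a complete synthetic scenario
#'
#' Runs [simulate_annotation()] and [simulate_expression()] and writes the
#' genome FASTA, reference and assembled GTFs, expression and condition
#' TSVs, the truth table and a config echo into `dir`. The whole scenario
#' is a deterministic function of the configuration (including its seed).
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed). `NULL` keeps
#'   everything in memory.
#' @return List with the in-memory objects (`models`, `ref_records`,
#'   `genome`, `expression`, `conditions`, `truth`, `cfg`) plus `paths`
#'   when files were written.
#' @export
simulate_scenario <- function(cfg, dir = NULL) {
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann$truth)
  out <- list(models = ann$models, ref_models = ann$ref_models,
              ref_records = ann$ref_records, genome = ann$genome,
              expression = expr$expression, conditions = expr$conditions,
              truth = expr$truth, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      assembled_gtf = file.path(dir, "assembled.gtf"),
      reference_gtf = file.path(dir, "reference.gtf"),
      genome_fasta = file.path(dir, "genome.fa"),
      expression_tsv = file.path(dir, "expression.tsv"),
      conditions_tsv = file.path(dir, "conditions.tsv"),
      truth_tsv = file.path(dir, "truth.tsv"),
      config_txt = file.path(dir, "config.txt")
    )
    write_gtf(ann$models, paths$assembled_gtf)
    write_gtf(ann$ref_models, paths$reference_gtf,
              cds_records = ann$ref_records)
    if (!is.null(ann$genome)) {
      write_genome_fasta(ann$genome, paths$genome_fasta)
    }
    write_expression(expr$expression, paths$expression_tsv)
    write_condition_map(expr$conditions, paths$conditions_tsv)
    write_truth(expr$truth, paths$truth_tsv)
    write_scenario_config(cfg, paths$config_txt)
    out$paths <- paths
  }
  out
}

#' Write / read a scenario truth table
#'
#' Plain TSV, losslessly round-trippable.
#'
#' @param truth Truth data.frame.
#' @param path File path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_scenario_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) paste(format(v, digits = 15),
                                        collapse = ","), character(1))
  writeLines(paste0(names(cfg), "\t", vals), path)
  invisible(path)
}

#' Direct noise-simulation estimate of null subset counts
#'
#' Estimates, by direct Monte-Carlo simulation of the replicate-noise
#' process on the truth fractions, how many genes the usage-subset
#' classifier should place in subsets b, c and d purely through
#' threshold-crossing noise. Serves as the independent reference for null
#' scenarios (no planted effect): the pipeline's observed counts should
#' fall inside the simulated distribution.
#'
#' The simulated noise process mirrors everything the measured values pass
#' through: multiplicative lognormal replicate noise, per-sample scale
#' factors and (by default) quantile normalization of the replicate
#' columns.
#'
#' @param cfg A [scenario_config()].
#' @param truth Augmented truth table ([simulate_expression()]).
#' @param n_rep Number of Monte-Carlo replicates.
#' @param threshold,cutoff Subset threshold and expression cutoff, as in
#'   [classify_usage_subsets()].
#' @param normalize Quantile-normalize each simulated replicate table, as
#'   the pipeline does.
#' @param seed Seed for the Monte-Carlo draws.
#' @return data.frame with one row per replicate and columns `b`, `c`,
#'   `d`, `bcd`.
#' @export
estimate_null_subset_counts <- function(cfg, truth, n_rep = 100L,
                                        threshold = 0.20, cutoff = 1,
                                        normalize = TRUE,
                                        seed = cfg$seed + 2L) {
  set.seed(seed)
  r <- cfg$replicates
  n <- nrow(truth)
  gene_f <- factor(truth$gene_id, levels = unique(truth$gene_id))
  out <- matrix(0L, nrow = n_rep, ncol = 3L,
                dimnames = list(NULL, c("b", "c", "d")))
  base <- cbind(matrix(truth$gene_expr * truth$if_wt_true, n, r),
                matrix(truth$gene_expr * truth$if_ko_true, n, r))
  for (rep_i in seq_len(n_rep)) {
    scales <- stats::runif(2L * r, cfg$scale_range[1], cfg$scale_range[2])
    noise <- exp(matrix(stats::rnorm(n * 2L * r, 0, cfg$noise_sd), n,
                        2L * r))
    m <- base * noise * rep(scales, each = n)
    if (normalize) m <- quantile_normalize_matrix(m)
    e_wt <- rowMeans(m[, seq_len(r), drop = FALSE])
    e_ko <- rowMeans(m[, r + seq_len(r), drop = FALSE])
    g_wt <- tapply(e_wt, gene_f, sum)
    g_ko <- tapply(e_ko, gene_f, sum)
    gene_ok <- g_wt >= cutoff & g_ko >= cutoff
    expressed <- pmax(e_wt, e_ko) > cutoff
    multi <- tapply(expressed, gene_f, sum) >= 2L
    all_expr <- tapply(e_wt > cutoff & e_ko > cutoff, gene_f, all)
    keep <- gene_ok & multi & all_expr
    dif <- e_ko / g_ko[gene_f] - e_wt / g_wt[gene_f]
    up <- tapply(dif >= threshold, gene_f, any)
    down <- tapply(dif <= -threshold, gene_f, any)
    out[rep_i, "b"] <- sum(keep & up & !down)
    out[rep_i, "c"] <- sum(keep & !up & down)
    out[rep_i, "d"] <- sum(keep & up & down)
  }
  out <- as.data.frame(out)
  out$bcd <- out$b + out$c + out$d
  out
}
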