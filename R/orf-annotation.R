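#' Find the most upstream compatible reference CDS start for a transcript
#'
#' A reference start codon is compatible with a query transcript when the
#' genomic coordinate of its first base is exonic in the query (it maps onto
#' the spliced mRNA) and at least 3 nt of spliced sequence remain downstream
#' of that position. Among compatible candidates the smallest mRNA offset —
#' the most upstream start — is returned, anchoring the reading frame to
#' annotated coding sequence rather than de novo ORF discovery.
#'
#' @param t A [transcript_model()].
#' @param refs Named list of reference CDS records ([read_gtf()],
#'   `reference_cds` mode).
#' @param scope `"same_gene"` restricts the search to reference records
#'   sharing the query's `gene_id`; `"genome_wide"` searches all records on
#'   the same chromosome and strand.
#' @return 0-based mRNA offset of the start codon, or `NA_integer_` when no
#'   compatible start exists.
#' @export
find_compatible_cds_start <- function(t, refs,
                                      scope = c("same_gene", "genome_wide")) {
  scope <- match.arg(scope)
  if (scope == "same_gene") {
    refs <- Filter(function(r) identical(r$gene_id, t$gene_id), refs)
  }
  tlen <- spliced_length(t)
  offs <- vapply(refs, function(r) {
    if (!identical(r$chrom, t$chrom) || !identical(r$strand, t$strand)) {
      return(NA_integer_)
    }
    off <- genomic_to_mrna(t, r$start_codon_genomic)
    if (is.na(off) || off + 3L > tlen) NA_integer_ else off
  }, integer(1))
  offs <- offs[!is.na(offs)]
  if (length(offs) == 0L) NA_integer_ else min(offs)
}

#' Scan for the first in-frame stop codon
#'
#' Reads codons from `start` and returns the 0-based offset one past the
#' last base of the first in-frame stop codon (TAA/TAG/TGA), or `NA` when no
#' in-frame stop occurs before the transcript end. Codons containing `N` are
#' treated as non-stop.
#'
#' @param mrna Nucleotide string (A/C/G/T/N).
#' @param start 0-based mRNA offset of the first codon base.
#' @return Integer offset one past the stop codon, or `NA_integer_`.
#' @export
scan_orf <- function(mrna, start) {
  start <- as.integer(start)
  stopifnot(start >= 0L, start + 3L <= nchar(mrna))
  if (grepl("[^ACGTN]", mrna)) {
    stop("mRNA sequence contains characters outside A/C/G/T/N")
  }
  n_codon <- (nchar(mrna) - start) %/% 3L
  first <- start + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(mrna, first, first + 2L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0L) NA_integer_ else start + 3L * hit[1]
}

#' Classify PTC status under the 50-nt rule
#'
#' A stop codon marks a transcript as PTC-positive when it lies more than
#' `distance_threshold` (default 50) nt upstream of the last exon-exon
#' junction. The distance is measured from the base immediately after the
#' stop codon (`stop_end_mrna`, 0-based) to the first base of the last exon,
#' and the rule is a strict inequality: a distance of exactly 50 nt is
#' PTC-negative. Mono-exonic transcripts (no junction) are PTC-negative.
#'
#' @param stop_end_mrna 0-based offset one past the stop codon.
#' @param last_junction 0-based offset of the last junction, or `NA`.
#' @param distance_threshold Strict distance threshold in nt.
#' @return List with `orf_class` (`"PTC_POSITIVE"`/`"PTC_NEGATIVE"`) and
#'   `junction_distance` (nt, `NA` when there is no junction).
#' @export
classify_ptc <- function(stop_end_mrna, last_junction,
                         distance_threshold = 50L) {
  if (is.na(last_junction)) {
    return(list(orf_class = "PTC_NEGATIVE", junction_distance = NA_integer_))
  }
  d <- as.integer(last_junction) - as.integer(stop_end_mrna)
  list(
    orf_class = if (d > distance_threshold) "PTC_POSITIVE" else "PTC_NEGATIVE",
    junction_distance = d
  )
}

#' Annotate a transcript with ORF coordinates, UTR lengths and PTC class
#'
#' Composes [find_compatible_cds_start()], [scan_orf()] and
#' [classify_ptc()]. Transcripts with no compatible start codon, or whose
#' reading frame runs off the 3' end without a stop, are `NO_ORF` and carry
#' `NA` lengths (they are excluded from UTR-length analyses downstream).
#' Otherwise `utr5_len + orf_len + utr3_len == spliced_length(t)` and
#' `orf_len` (start through stop codon inclusive) is divisible by 3.
#'
#' @param t A [transcript_model()].
#' @param refs Named list of reference CDS records.
#' @param genome Genome sequences (see [extract_mrna_sequence()]).
#' @param scope Compatible-CDS search scope, see
#'   [find_compatible_cds_start()].
#' @param distance_threshold PTC distance threshold, see [classify_ptc()].
#' @return One-row data.frame with columns `transcript_id`, `gene_id`,
#'   `orf_class`, `cds_start_mrna`, `stop_end_mrna`, `utr5_len`, `orf_len`,
#'   `utr3_len`, `junction_distance`.
#' @export
annotate_transcript <- function(t, refs, genome, scope = "same_gene",
                                distance_threshold = 50L) {
  no_orf <- data.frame(
    transcript_id = t$transcript_id, gene_id = t$gene_id,
    orf_class = "NO_ORF", cds_start_mrna = NA_integer_,
    stop_end_mrna = NA_integer_, utr5_len = NA_integer_,
    orf_len = NA_integer_, utr3_len = NA_integer_,
    junction_distance = NA_integer_, stringsAsFactors = FALSE
  )
  cds_start <- find_compatible_cds_start(t, refs, scope)
  if (is.na(cds_start)) return(no_orf)
  mrna <- extract_mrna_sequence(t, genome)
  stop_end <- scan_orf(mrna, cds_start)
  if (is.na(stop_end)) return(no_orf)
  junction <- last_junction_mrna_pos(t)
  cls <- classify_ptc(stop_end, junction, distance_threshold)
  data.frame(
    transcript_id = t$transcript_id, gene_id = t$gene_id,
    orf_class = cls$orf_class, cds_start_mrna = cds_start,
    stop_end_mrna = stop_end, utr5_len = cds_start,
    orf_len = stop_end - cds_start,
    utr3_len = spliced_length(t) - stop_end,
    junction_distance = cls$junction_distance, stringsAsFactors = FALSE
  )
}

#' Annotate a collection of transcripts
#'
#' Driver over [annotate_transcript()] with a per-gene reference index.
#'
#' @param models Named list of [transcript_model()]s.
#' @param refs Named list of reference CDS records.
#' @param genome Genome sequences.
#' @param scope,distance_threshold See [annotate_transcript()].
#' @return data.frame with one row per transcript (see
#'   [annotate_transcript()] for columns).
#' @export
annotate_transcripts <- function(models, refs, genome, scope = "same_gene",
                                 distance_threshold = 50L) {
  genome <- as_genome_sequence(genome)
  if (scope == "same_gene") {
    gene_of <- vapply(refs, `[[`, character(1), "gene_id")
    by_gene <- split(refs, gene_of)
    rows <- lapply(models, function(t) {
      annotate_transcript(t, by_gene[[t$gene_id]] %||% list(), genome,
                          scope = "same_gene",
                          distance_threshold = distance_threshold)
    })
  } else {
    rows <- lapply(models, annotate_transcript, refs = refs,
                   genome = genome, scope = scope,
                   distance_threshold = distance_threshold)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a transcript annotation table
#'
#' Plain TSV with one row per transcript; `NA` lengths mark `NO_ORF`
#' transcripts.
#'
#' @param annotations data.frame from [annotate_transcripts()].
#' @param path File path.
#' @return `write_annotation` returns the path invisibly; `read_annotation`
#'   returns the data.frame.
#' @export
write_annotation <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
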