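#' Construct a transcript model
#'
#' A transcript model is a stranded, exon-structured transcript: the unit of
#' ORF annotation and of all spliced-coordinate arithmetic. Exons are stored
#' in transcript (5'->3') orientation: genomic starts strictly increase along
#' the transcript on the plus strand and strictly decrease on the minus
#' strand. Inputs given in genomic order are re-sorted.
#'
#' @param transcript_id Transcript identifier (opaque text).
#' @param gene_id Parent gene identifier.
#' @param chrom Sequence (chromosome) name shared by all exons.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of 1-based, inclusive genomic exon
#'   coordinates (GTF convention), one entry per exon, in any order.
#' @return An object of class `transcript_model`.
#' @examples
#' t <- transcript_model("T1", "G1", "chr1", "+", c(1, 201), c(100, 300))
#' spliced_length(t)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             starts, ends) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("transcript ", transcript_id, ": needs >=1 exon with matching ",
         "start/end vectors")
  }
  if (!strand %in% c("+", "-")) {
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  }
  if (any(ends < starts)) {
    stop("transcript ", transcript_id, ": exon end < start")
  }
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  if (anyDuplicated(s) || any(s[-1] <= e[-length(e)])) {
    stop("transcript ", transcript_id, ": overlapping or duplicated exons")
  }
  if (strand == "-") {
    s <- rev(s); e <- rev(e)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, starts = s, ends = e),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s, %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$starts), spliced_length(x)))
  invisible(x)
}

#' Spliced (mature mRNA) length of a transcript
#'
#' @param t A [transcript_model()].
#' @return Total exonic length in nucleotides.
#' @export
spliced_length <- function(t) {
  sum(t$ends - t$starts + 1L)
}

#' Map a genomic coordinate onto the spliced mRNA
#'
#' Returns the 0-based offset of a genomic base in the spliced,
#' strand-oriented mRNA, or `NA` when the coordinate is intronic or outside
#' the transcript. Genomic coordinates are 1-based inclusive; all mRNA
#' offsets in this package are 0-based.
#'
#' @param t A [transcript_model()].
#' @param g A 1-based genomic coordinate (scalar).
#' @return Integer mRNA offset, or `NA_integer_`.
#' @export
genomic_to_mrna <- function(t, g) {
  g <- as.integer(g)
  lens <- t$ends - t$starts + 1L
  before <- cumsum(c(0L, lens[-length(lens)]))
  for (i in seq_along(lens)) {
    if (g >= t$starts[i] && g <= t$ends[i]) {
      within <- if (t$strand == "+") g - t$starts[i] else t$ends[i] - g
      return(before[i] + within)
    }
  }
  NA_integer_
}

#' Map an mRNA offset back to its genomic coordinate
#'
#' Inverse of [genomic_to_mrna()] for exonic positions.
#'
#' @param t A [transcript_model()].
#' @param off 0-based mRNA offset (scalar, in `[0, spliced_length - 1]`).
#' @return 1-based genomic coordinate.
#' @export
mrna_to_genomic <- function(t, off) {
  off <- as.integer(off)
  if (off < 0L || off >= spliced_length(t)) {
    stop("transcript ", t$transcript_id, ": mRNA offset ", off,
         " outside [0, ", spliced_length(t) - 1L, "]")
  }
  lens <- t$ends - t$starts + 1L
  before <- cumsum(c(0L, lens[-length(lens)]))
  i <- findInterval(off, before)
  within <- off - before[i]
  if (t$strand == "+") t$starts[i] + within else t$ends[i] - within
}

#' Genomic blocks covered by an mRNA interval
#'
#' Projects the half-open mRNA interval `[from, to)` (0-based offsets) onto
#' the genome, returning one row per exonic block in genomic order. Used to
#' emit CDS features when writing reference annotation.
#'
#' @param t A [transcript_model()].
#' @param from,to 0-based mRNA offsets, `from < to <= spliced_length(t)`.
#' @return A data.frame with columns `start`, `end` (1-based inclusive).
#' @export
mrna_interval_to_blocks <- function(t, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(from >= 0L, to > from, to <= spliced_length(t))
  lens <- t$ends - t$starts + 1L
  before <- cumsum(c(0L, lens[-length(lens)]))
  after <- before + lens
  keep <- which(after > from & before < to)
  blocks <- lapply(keep, function(i) {
    a <- max(from, before[i]) - before[i]  # within-exon offsets
    b <- min(to, after[i]) - 1L - before[i]
    if (t$strand == "+") {
      c(t$starts[i] + a, t$starts[i] + b)
    } else {
      c(t$ends[i] - b, t$ends[i] - a)
    }
  })
  out <- do.call(rbind, blocks)
  out <- data.frame(start = out[, 1], end = out[, 2])
  out[order(out$start), , drop = FALSE]
}

#' mRNA offset of the last exon-exon junction
#'
#' The junction position is the 0-based spliced offset of the first base of
#' the last exon, i.e. the spliced length of all exons but the last. This is
#' the positional reference of the 50-nt rule: a stop codon ending more than
#' 50 nt upstream of this offset marks a transcript as PTC-positive.
#' Mono-exonic transcripts have no junction and return `NA`.
#'
#' @param t A [transcript_model()].
#' @return Integer offset or `NA_integer_`.
#' @export
last_junction_mrna_pos <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(NA_integer_)
  lens <- t$ends - t$starts + 1L
  sum(lens[-n])
}

#' All exon-exon junction offsets of a transcript
#'
#' 0-based spliced offsets of the first base of exons 2..n, 5'->3'.
#' Mono-exonic transcripts return an empty vector.
#'
#' @param t A [transcript_model()].
#' @return Integer vector (possibly empty).
#' @export
junction_mrna_positions <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(integer(0))
  lens <- t$ends - t$starts + 1L
  cumsum(lens)[-n]
}

#' Extract the spliced mRNA sequence of a transcript
#'
#' Concatenates exon sequences in transcript orientation; minus-strand
#' transcripts are reverse-complemented. The result always has length
#' `spliced_length(t)`.
#'
#' @param t A [transcript_model()].
#' @param genome A genome as returned by [read_genome_fasta()] (named
#'   character vector of chromosome sequences) or a
#'   [Biostrings::DNAStringSet].
#' @return A nucleotide string (A/C/G/T/N).
#' @export
extract_mrna_sequence <- function(t, genome) {
  genome <- as_genome_sequence(genome)
  chrom_seq <- genome[[t$chrom]]
  if (is.null(chrom_seq) || is.na(chrom_seq)) {
    stop("transcript ", t$transcript_id, ": chromosome '", t$chrom,
         "' not present in genome")
  }
  if (max(t$ends) > nchar(chrom_seq) || min(t$starts) < 1L) {
    stop("transcript ", t$transcript_id,
         ": exon coordinates outside genome bounds for ", t$chrom)
  }
  # genomic order, then orient
  s <- t$starts; e <- t$ends
  if (t$strand == "-") { s <- rev(s); e <- rev(e) }
  seq_fwd <- paste(substring(chrom_seq, s, e), collapse = "")
  if (t$strand == "+") seq_fwd else revcomp(seq_fwd)
}

#' Reverse complement of a nucleotide string
#'
#' @param x A nucleotide string (A/C/G/T/N, upper case).
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Normalize a genome argument to a named character vector of sequences.
as_genome_sequence <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(as.list(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(as.list(genome))
  }
  if (is.list(genome)) return(genome)
  stop("unsupported genome representation: ", class(genome)[1])
}
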