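#' Read transcript models or reference CDS records from a GTF file
#'
#' Ensembl-style attribute syntax (`key "value";`) is expected; features
#' other than `exon`, `CDS` and `start_codon` are skipped and unknown
#' attributes are ignored, so assembler output (e.g. Cufflinks) reads
#' cleanly. Exons are grouped by `transcript_id`, sorted into transcript
#' orientation, and validated: a transcript whose exons mix strands or
#' chromosomes, or that contains duplicated/overlapping exons, is rejected
#' with an error naming the offending id.
#'
#' In `reference_cds` mode, CDS segments are collected per transcript and
#' the genomic coordinate of the first base of the start codon is taken from
#' a `start_codon` feature when present, otherwise derived as the 5'-most
#' CDS base in transcript orientation. CDS-bearing transcripts for which no
#' start codon can be resolved are flagged with a warning and excluded from
#' the compatible-CDS search.
#'
#' @param path Path to a GTF file.
#' @param mode `"transcripts"` (exon structures) or `"reference_cds"`.
#' @param quiet Suppress the parsed-transcript count message.
#' @return For `"transcripts"`, a named list of [transcript_model()]s.
#'   For `"reference_cds"`, a named list of reference CDS records: lists
#'   with `transcript_id`, `gene_id`, `chrom`, `strand`, `cds_starts`,
#'   `cds_ends` (genomic, 5'->3') and `start_codon_genomic`.
#' @export
read_gtf <- function(path, mode = c("transcripts", "reference_cds"),
                     quiet = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  keep <- mc$type %in% c("exon", "CDS", "start_codon")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$transcript_id) || anyNA(df$gene_id)) {
    stop("GTF features lacking transcript_id or gene_id attributes in ",
         path)
  }
  if (mode == "transcripts") {
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exon features found in ", path)
    models <- build_transcript_models(ex)
    if (!quiet) message("read_gtf: parsed ", length(models),
                        " transcript(s) from ", basename(path))
    return(models)
  }
  build_reference_cds(df, path, quiet = quiet)
}

# Field-count pre-validation so malformed lines are reported by number.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[nfield < 9L]
  if (length(bad)) {
    stop("malformed GTF line(s) (fewer than 9 tab-separated fields) at ",
         "line ", paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  }
  invisible(TRUE)
}

build_transcript_models <- function(ex) {
  split_ex <- split(ex, ex$transcript_id)
  bad <- character(0)
  models <- vector("list", length(split_ex))
  names(models) <- names(split_ex)
  for (tid in names(split_ex)) {
    e <- split_ex[[tid]]
    if (length(unique(e$strand)) != 1L || length(unique(e$chrom)) != 1L) {
      bad <- c(bad, tid)
      next
    }
    m <- tryCatch(
      transcript_model(tid, e$gene_id[1], e$chrom[1], e$strand[1],
                       e$start, e$end),
      error = function(cnd) conditionMessage(cnd)
    )
    if (is.character(m)) bad <- c(bad, tid) else models[[tid]] <- m
  }
  if (length(bad)) {
    stop("invalid transcript structure(s) rejected: ",
         paste(bad, collapse = ", "))
  }
  models
}

build_reference_cds <- function(df, path, quiet = FALSE) {
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features found in ", path)
  sc <- df[df$type == "start_codon", , drop = FALSE]
  sc_by_tid <- split(sc, sc$transcript_id)
  recs <- list()
  flagged <- character(0)
  for (tid in unique(cds$transcript_id)) {
    seg <- cds[cds$transcript_id == tid, , drop = FALSE]
    if (length(unique(seg$strand)) != 1L || length(unique(seg$chrom)) != 1L) {
      flagged <- c(flagged, tid)
      next
    }
    strand <- seg$strand[1]
    ord <- order(seg$start)
    seg <- seg[ord, , drop = FALSE]
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    sc_t <- sc_by_tid[[tid]]
    start_codon <- if (!is.null(sc_t) && nrow(sc_t)) {
      # first base of the start codon in transcript orientation
      if (strand == "+") min(sc_t$start) else max(sc_t$end)
    } else if (strand == "+") {
      seg$start[1]
    } else {
      seg$end[1]
    }
    # the start codon's first base must lie inside the first CDS segment
    in_first <- start_codon >= seg$start[1] && start_codon <= seg$end[1]
    if (is.na(start_codon) || !in_first) {
      flagged <- c(flagged, tid)
      next
    }
    recs[[tid]] <- list(
      transcript_id = tid, gene_id = seg$gene_id[1], chrom = seg$chrom[1],
      strand = strand, cds_starts = seg$start, cds_ends = seg$end,
      start_codon_genomic = start_codon
    )
  }
  if (length(flagged)) {
    warning("reference transcript(s) without a resolvable start codon ",
            "excluded from the compatible-CDS search: ",
            paste(flagged, collapse = ", "))
  }
  if (!quiet) message("read_gtf: parsed ", length(recs),
                      " reference CDS record(s) from ", basename(path))
  recs
}

#' Write transcript models (and optional reference CDS) to a GTF file
#'
#' Emits Ensembl-dialect exon features for each model, in genomic order per
#' transcript. When `cds_records` is supplied, CDS and start_codon features
#' are written for the matching transcript ids, making the file readable in
#' `reference_cds` mode.
#'
#' @param models Named list of [transcript_model()]s.
#' @param path Output path.
#' @param cds_records Optional named list of reference CDS records (see
#'   [read_gtf()]).
#' @param source Value for the GTF source column.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(models, path, cds_records = NULL,
                      source = "utrshiftr") {
  lines <- character(0)
  fmt <- paste0("%s\t", source,
                "\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";")
  for (t in models) {
    s <- t$starts; e <- t$ends
    ord <- order(s)
    lines <- c(lines, sprintf(fmt, t$chrom, "exon", s[ord], e[ord],
                              t$strand, t$gene_id, t$transcript_id))
    r <- cds_records[[t$transcript_id]]
    if (!is.null(r)) {
      ord2 <- order(r$cds_starts)
      lines <- c(lines,
                 sprintf(fmt, r$chrom, "CDS", r$cds_starts[ord2],
                         r$cds_ends[ord2], r$strand, r$gene_id,
                         r$transcript_id))
      sc1 <- r$start_codon_genomic
      sc <- if (r$strand == "+") c(sc1, sc1 + 2L) else c(sc1 - 2L, sc1)
      lines <- c(lines, sprintf(fmt, r$chrom, "start_codon", sc[1], sc[2],
                                r$strand, r$gene_id, r$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Multi-record files with wrapped lines are accepted. Record names are
#' truncated at the first whitespace. Sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
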