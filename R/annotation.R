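#' Transcript models: one reference transcript per gene
#'
#' A `transcript_models` object is a data frame with one row per gene holding
#' the reference transcript used throughout the pipeline: its sequence and the
#' CDS boundaries in 0-based, half-open transcript coordinates. `cds_start` is
#' the first nucleotide of the annotated start codon; `cds_end` is one past the
#' last nucleotide of the stop codon, so the 5'UTR is `[0, cds_start)`, the CDS
#' (including the stop codon) is `[cds_start, cds_end)` and the 3'UTR is
#' `[cds_end, length)`.
#'
#' @param gene_id,transcript_id character identifiers.
#' @param sequence transcript sequence over A/C/G/T/U/N; stored uppercase with
#'   U converted to T.
#' @param cds_start,cds_end CDS boundaries, 0-based half-open.
#' @return A one-row `transcript_models` data frame.
#' @examples
#' transcript_model("g1", "tx1", paste(rep("ACGT", 30), collapse = ""), 30, 90)
#' @export
transcript_model <- function(gene_id, transcript_id, sequence, cds_start,
                             cds_end) {
  sequence <- normalize_seq(sequence)
  m <- data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    sequence = sequence,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  validate_models(structure(m, class = c("transcript_models", "data.frame")))
}

#' Combine transcript model rows into a validated set
#'
#' @param df data frame with columns `gene_id`, `transcript_id`, `sequence`,
#'   `cds_start`, `cds_end` (0-based half-open).
#' @return A `transcript_models` data frame sorted by `gene_id`.
#' @export
as_transcript_models <- function(df) {
  df$sequence <- vapply(df$sequence, normalize_seq, character(1),
                        USE.NAMES = FALSE)
  df$length <- nchar(df$sequence)
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- df$transcript_id
  validate_models(structure(df, class = c("transcript_models", "data.frame")))
}

normalize_seq <- function(s) {
  s <- chartr("u", "t", as.character(s))
  s <- toupper(chartr("U", "T", s))
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside A/C/G/T/U/N")
  s
}

validate_models <- function(m) {
  stopifnot(is.data.frame(m))
  if (anyDuplicated(m$gene_id))
    stop("duplicate gene_id in transcript model set")
  bad <- !(m$cds_start >= 0 & m$cds_start < m$cds_end &
             m$cds_end <= m$length)
  if (any(bad))
    stop("invalid CDS bounds for transcript(s): ",
         paste(m$transcript_id[bad], collapse = ", "))
  if (any((m$cds_end - m$cds_start) %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(m$transcript_id[(m$cds_end - m$cds_start) %% 3L != 0L],
               collapse = ", "))
  if (any(m$cds_end - m$cds_start < 6L))
    stop("CDS shorter than two codons")
  if (any(nchar(m$sequence) != m$length))
    stop("sequence length disagrees with length field")
  m
}

#' Load transcript annotation from GTF + FASTA
#'
#' Reads CDS features from a transcript-space GTF (the `seqname` column holds
#' transcript identifiers) together with the transcript sequences, converts
#' the 1-based closed GTF coordinates to 0-based half-open transcript
#' coordinates, and selects one reference transcript per gene.
#'
#' Transcripts whose CDS length is not a multiple of 3, or is shorter than two
#' codons, are skipped with a warning. A transcript with CDS features but no
#' sequence in the FASTA is an error.
#'
#' @param gtf path to a GTF file with `CDS` features and
#'   `gene_id`/`transcript_id` attributes.
#' @param fasta path to a FASTA file of transcript sequences.
#' @param reference_rule how to pick the reference transcript of a gene:
#'   `"longest_cds"` (ties broken by lexicographically smallest
#'   `transcript_id`) or `"first_listed"` (first appearance in the GTF).
#' @return A [as_transcript_models()] data frame, one row per gene.
#' @export
load_annotation <- function(gtf, fasta,
                            reference_rule = c("longest_cds", "first_listed")) {
  reference_rule <- match.arg(reference_rule)
  gr <- rtracklayer::import(gtf, format = "gtf")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", gtf)

  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seq_chr <- as.character(seqs)

  tx_ids <- as.character(cds$transcript_id)
  first_seen <- match(unique(tx_ids), tx_ids)
  tab <- data.frame(
    transcript_id = unique(tx_ids),
    gene_id = as.character(cds$gene_id)[first_seen],
    order = order(first_seen),
    stringsAsFactors = FALSE
  )
  tab$order <- seq_len(nrow(tab))
  tab$cds_start <- vapply(tab$transcript_id, function(tx)
    min(GenomicRanges::start(cds[tx_ids == tx])) - 1L, integer(1))
  tab$cds_end <- vapply(tab$transcript_id, function(tx)
    max(GenomicRanges::end(cds[tx_ids == tx])), integer(1))

  missing <- setdiff(tab$transcript_id, names(seq_chr))
  if (length(missing))
    stop("no sequence in FASTA for transcript(s): ",
         paste(missing, collapse = ", "))

  len <- tab$cds_end - tab$cds_start
  bad <- len %% 3L != 0L | len < 6L
  if (any(bad)) {
    warning("skipping transcript(s) with invalid CDS length: ",
            paste(tab$transcript_id[bad], collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no usable transcripts after CDS validation")

  tab$cds_len <- tab$cds_end - tab$cds_start
  keep <- vapply(split(tab, tab$gene_id), function(g) {
    if (reference_rule == "longest_cds") {
      g <- g[order(-g$cds_len, g$transcript_id), , drop = FALSE]
    } else {
      g <- g[order(g$order), , drop = FALSE]
    }
    g$transcript_id[1L]
  }, character(1))
  tab <- tab[tab$transcript_id %in% keep, , drop = FALSE]
  tab$sequence <- unname(seq_chr[tab$transcript_id])

  as_transcript_models(tab[, c("gene_id", "transcript_id", "sequence",
                               "cds_start", "cds_end")])
}

#' Write transcript models to GTF + FASTA
#'
#' Inverse of [load_annotation()]: emits one `exon` feature spanning the
#' transcript and one `CDS` feature per model, with coordinates converted back
#' to 1-based closed GTF convention, plus the sequences as FASTA.
#'
#' @param models a `transcript_models` data frame.
#' @param gtf,fasta output paths.
#' @return Invisibly, the paths.
#' @export
write_annotation <- function(models, gtf, fasta) {
  n <- nrow(models)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(models$transcript_id, each = 2L),
    ranges = IRanges::IRanges(
      start = as.vector(rbind(rep(1L, n), models$cds_start + 1L)),
      end = as.vector(rbind(models$length, models$cds_end))
    ),
    strand = "+",
    type = rep(c("exon", "CDS"), n),
    phase = rep(c(NA_integer_, 0L), n),
    source = "ribodens",
    gene_id = rep(models$gene_id, each = 2L),
    transcript_id = rep(models$transcript_id, each = 2L)
  )
  rtracklayer::export(gr, gtf, format = "gtf")
  seqs <- Biostrings::DNAStringSet(structure(models$sequence,
                                             names = models$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(c(gtf = gtf, fasta = fasta))
}

#' Fetch one model row by transcript id
#' @param models a `transcript_models` data frame.
#' @param transcript_id identifier to look up.
#' @return One-row `transcript_models`.
#' @export
get_model <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  models[i, , drop = FALSE]
}
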