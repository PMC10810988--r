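#' Read and write FASTA contig tables
#'
#' `read_fasta()` parses a (multi-record) FASTA file into a contigs tibble,
#' uppercasing lowercase input. Characters outside `{A,C,G,T,N}` either
#' raise an error (`on_invalid = "error"`, the default strict mode) or are
#' mapped to `N` (`on_invalid = "to_n"`). `write_fasta()` writes a contigs
#' tibble (or named character vector) wrapped at 60 columns; a write/read
#' round trip preserves ids and sequences exactly.
#'
#' @param path File path.
#' @param on_invalid How to treat non-`ACGTN` characters.
#' @return `read_fasta()` returns a tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, on_invalid = c("error", "to_n")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) abort(sprintf("empty FASTA: %s", path))
  seqs <- toupper(as.character(set))
  if (on_invalid == "error") {
    assert_dna(seqs, allow_n = TRUE, what = sprintf("FASTA '%s'", path))
  } else {
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  ids <- sub("\\s.*$", "", names(set))
  tibble(id = ids, sequence = unname(seqs))
}

#' @rdname read_fasta
#' @param contigs Tibble with `id` and `sequence`, or a named character
#'   vector of sequences.
#' @export
write_fasta <- function(contigs, path) {
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs), sequence = unname(contigs))
  }
  stopifnot(all(c("id", "sequence") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) abort("contig ids must be unique")
  set <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

RETAINED_GFF_TYPES <- c("CDS", "ncRNA", "pseudogene", "intergenic")

#' Read and write GFF3 feature annotations
#'
#' `read_gff3()` imports a GFF3 file and keeps only the retained feature
#' types (CDS, ncRNA, pseudogene, intergenic); rare types (riboswitch,
#' tmRNA, ...) are dropped at parse time. `write_gff3()` exports an
#' annotations tibble with the standard version pragma. Coordinates are
#' 1-based inclusive on both sides of the round trip.
#'
#' @param path File path.
#' @return `read_gff3()` returns a tibble with `contig_id`, `start`, `end`,
#'   `strand`, `feature_type`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type)
  )
  dplyr::filter(df, .data$feature_type %in% RETAINED_GFF_TYPES)
}

#' @rdname read_gff3
#' @param annotations Annotations tibble (`contig_id`, `start`, `end`,
#'   `strand`, `feature_type`).
#' @export
write_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig_id,
    ranges = IRanges::IRanges(start = annotations$start, end = annotations$end),
    strand = annotations$strand,
    type = annotations$feature_type,
    source = "dnalm",
    phase = ifelse(annotations$feature_type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write labeled sequence records as TSV
#'
#' The plain-text exchange format for benchmark datasets: columns `id`,
#' `sequence`, `label`, and any extra columns present (`source_class`,
#' `split`, ...).
#'
#' @param path File path.
#' @return `read_labeled_tsv()` returns a tibble.
#' @export
read_labeled_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(sequence = "c", id = "c"))
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(df))) {
    abort(sprintf("labeled TSV must have columns %s", paste(need, collapse = ", ")))
  }
  df
}

#' @rdname read_labeled_tsv
#' @param records Labeled records tibble.
#' @export
write_labeled_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
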