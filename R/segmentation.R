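#' Split a contig into non-overlapping segments
#'
#' Contiguous segmentation tiles the sequence left to right into chunks of
#' `segment_length`. A final short remainder is kept when at least
#' `min_keep` nucleotides long (default 30 nt, the smallest segment used in
#' mixed-length training batches) and dropped otherwise.
#'
#' @param contig A one-row data frame with columns `id` and `sequence`, or a
#'   single named DNA string.
#' @param segment_length Target segment length in nucleotides (>= 1).
#' @param min_keep Minimum length of a trailing remainder to keep.
#' @return A tibble with columns `contig_id`, `start`, `end` (1-based,
#'   inclusive) and `sequence`.
#' @examples
#' segment_contiguous(c(chr = paste(rep("ACGT", 250), collapse = "")), 256)
#' @export
segment_contiguous <- function(contig, segment_length, min_keep = 30) {
  contig <- as_contig_row(contig)
  if (segment_length < 1) abort("`segment_length` must be >= 1")
  n <- nchar(contig$sequence)
  if (n == 0) return(empty_segments())
  starts <- seq.int(1L, n, by = segment_length)
  ends <- pmin(starts + segment_length - 1L, n)
  keep <- (ends - starts + 1L) >= pmin(min_keep, segment_length)
  starts <- starts[keep]; ends <- ends[keep]
  tibble(
    contig_id = contig$id,
    start = starts,
    end = ends,
    sequence = substring(contig$sequence, starts, ends)
  )
}

#' Randomly sample segments to a target coverage
#'
#' Segments with uniform start positions and lengths uniform in
#' `length_range` are drawn with replacement (segments may overlap) until
#' the total sampled base pairs reach `coverage` times the contig length.
#'
#' @inheritParams segment_contiguous
#' @param length_range Two-element vector `(min, max)` of segment lengths.
#' @param coverage Target total sampled bp as a fraction of contig length;
#'   `coverage = 1` draws roughly one copy's worth.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble as in [segment_contiguous()].
#' @export
segment_random <- function(contig, length_range, coverage = 1, seed = NULL) {
  contig <- as_contig_row(contig)
  if (length(length_range) != 2 || length_range[2] < length_range[1]) {
    abort("`length_range` must be (min, max) with max >= min")
  }
  n <- nchar(contig$sequence)
  if (length_range[1] < 1 || length_range[2] > n) {
    abort("`length_range` must lie within [1, contig length]")
  }
  if (coverage < 0) abort("`coverage` must be nonnegative")
  with_seed(seed, {
    target <- coverage * n
    starts <- integer(0); lens <- integer(0); total <- 0
    while (total < target) {
      len <- sample.int(length_range[2] - length_range[1] + 1L, 1L) +
        length_range[1] - 1L
      start <- sample.int(n - len + 1L, 1L)
      starts <- c(starts, start); lens <- c(lens, len)
      total <- total + len
    }
    if (length(starts) == 0) return(empty_segments())
    tibble(
      contig_id = contig$id,
      start = starts,
      end = starts + lens - 1L,
      sequence = substring(contig$sequence, starts, starts + lens - 1L)
    )
  })
}

empty_segments <- function() {
  tibble(contig_id = character(), start = integer(), end = integer(),
         sequence = character())
}

# Accept either a named character scalar or a one-row contigs data frame.
as_contig_row <- function(contig) {
  if (is.character(contig) && length(contig) == 1) {
    id <- names(contig)
    if (is.null(id)) id <- "contig"
    return(list(id = id, sequence = unname(contig)))
  }
  if (is.data.frame(contig) && nrow(contig) == 1 &&
      all(c("id", "sequence") %in% names(contig))) {
    return(list(id = contig$id, sequence = contig$sequence))
  }
  abort("`contig` must be a named DNA string or a one-row tibble with id, sequence")
}
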