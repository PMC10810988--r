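#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange bind_rows group_by ungroup
#'   summarise across left_join row_number n
#' @importFrom purrr map map_chr map_int map_dbl pmap map2
#' @importFrom stats runif rbinom setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the extended alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length, each element the sequence of
#'   the opposite strand read 5' to 3'.
#' @examples
#' revcomp("AAAACCCCGG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA string against an alphabet; returns TRUE/FALSE vectorised.
is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  bad <- !is_dna(x, allow_n = allow_n)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {%s} (first offender: element %d)",
      what, if (allow_n) "A,C,G,T,N" else "A,C,G,T", which(bad)[1]
    ))
  }
  invisible(x)
}

# Largest-remainder (Hamilton) apportionment of `n` items into parts with
# target fractions `p`. Returns integer vector summing to n.
apportion_largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  quota <- n * p
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Run code with a locally fixed RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Random DNA of length n with a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# sample() treats a length-1 numeric x as 1:x; this does not.
sample_one <- function(x) x[sample.int(length(x), 1L)]
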