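#' Local context-aware (LCA) tokenization
#'
#' DNA segments are represented as overlapping k-mers sampled every `shift`
#' nucleotides, so consecutive tokens overlap by `k - shift` characters.
#' Two parameters dominate the approach: the k-mer size `k` and the stride
#' `shift` (1 <= shift <= k). `shift = 1` gives maximal overlap; `shift = k`
#' gives disjoint tokens. The token vocabulary holds all `4^k` k-mers over
#' `{A,C,G,T}` plus five special tokens, so `|vocab| = 4^k + 5` (4101 for
#' k = 6; 9 for k = 1).
#'
#' @name lca-tokenization
NULL

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L
MASK_ID <- 4L
N_SPECIAL <- 5L

#' Build the LCA token vocabulary for a k-mer size
#'
#' Special tokens `[PAD] [UNK] [CLS] [SEP] [MASK]` occupy ids 0-4; the `4^k`
#' k-mers follow in lexicographic order from id 5. The construction is
#' deterministic.
#'
#' @param k K-mer size, between 1 and 12 (guard against combinatorial blowup).
#' @return A tibble with columns `token` (character) and `id` (integer,
#'   0-based), one row per vocabulary entry; `4^k + 5` rows in total.
#' @examples
#' nrow(lca_vocabulary(6)) # 4101
#' nrow(lca_vocabulary(1)) # 9
#' @export
lca_vocabulary <- function(k) {
  check_k(k)
  kmers <- all_kmers(k)
  tibble(
    token = c(SPECIAL_TOKENS, kmers),
    id = seq_len(N_SPECIAL + length(kmers)) - 1L
  )
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 || k > 12) {
    abort("`k` must be a single integer in [1, 12]")
  }
  invisible(as.integer(k))
}

all_kmers <- function(k) {
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  grid <- do.call(expand.grid, c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

#' Create an LCA tokenizer configuration
#'
#' @param k K-mer size (1-12).
#' @param shift Stride in nucleotides between consecutive k-mer starts;
#'   `1 <= shift <= k`.
#' @param max_positions Number of token slots per encoded segment, including
#'   the two special positions (`[CLS]`, `[SEP]`). Default 1024, matching the
#'   base model family; see [covered_nt()] for the nucleotide span this buys.
#' @return An object of class `lca_tokenizer` with the vocabulary, `k`,
#'   `shift` and `max_positions`.
#' @examples
#' tok <- lca_tokenizer(k = 6, shift = 1)
#' tok$vocab_size
#' @export
lca_tokenizer <- function(k = 6, shift = 1, max_positions = 1024) {
  k <- check_k(k)
  if (!is.numeric(shift) || length(shift) != 1 || shift < 1 || shift > k) {
    abort("`shift` must satisfy 1 <= shift <= k")
  }
  vocab <- lca_vocabulary(k)
  ids <- setNames(vocab$id, vocab$token)
  structure(
    list(
      k = k,
      shift = as.integer(shift),
      max_positions = as.integer(max_positions),
      special_tokens = SPECIAL_TOKENS,
      vocab = vocab,
      .ids = ids,
      vocab_size = nrow(vocab)
    ),
    class = "lca_tokenizer"
  )
}

#' @export
print.lca_tokenizer <- function(x, ...) {
  cat(sprintf(
    "<lca_tokenizer> k = %d, shift = %d, vocab = %d tokens, %d positions (%d nt context)\n",
    x$k, x$shift, x$vocab_size, x$max_positions,
    covered_nt(x$max_positions, x$k, x$shift)
  ))
  invisible(x)
}

#' Tokenize a DNA sequence into overlapping k-mers
#'
#' Tokens are `substr(sequence, i, i + k - 1)` for
#' `i = 1, 1 + shift, 1 + 2 shift, ...` while the window fits; trailing
#' nucleotides not reachable by a full k-mer are unused. With `shift = 2` and
#' even `k`, an odd-length sequence never uses its last character.
#'
#' @param sequence A single uppercase DNA string of length >= k.
#' @inheritParams lca_tokenizer
#' @return Character vector of token strings. Characters outside `{A,C,G,T}`
#'   are carried through here and map to `[UNK]` at encode time.
#' @examples
#' lca_tokenize("AAGTCCAGGATCAAGATT", k = 6, shift = 1)
#' lca_tokenize("AAGTCCAGGATCAAGATT", k = 6, shift = 2)
#' @export
lca_tokenize <- function(sequence, k = 6, shift = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  if (n < k) abort(sprintf("sequence length %d is below k = %d: nothing to tokenize", n, k))
  starts <- seq.int(1L, n - k + 1L, by = shift)
  substring(sequence, starts, starts + k - 1L)
}

# Number of k-mer tokens a sequence of length n yields.
n_lca_tokens <- function(n, k, shift) {
  if (n < k) 0L else as.integer((n - k) %/% shift + 1L)
}

# Integer ids for k-mer token strings; non-ACGT tokens -> [UNK].
# Arithmetic encoding (base 4) rather than a dictionary lookup, so encoding
# stays O(n k) for large batches.
kmer_ids <- function(tokens, k) {
  chars <- matrix(utf8ToInt(paste(tokens, collapse = "")), nrow = k)
  digit <- matrix(match(chars, utf8ToInt("ACGT")) - 1L, nrow = k) # NA for non-ACGT
  pow <- 4^((k - 1):0)
  idx <- colSums(digit * pow)
  ids <- as.integer(idx) + N_SPECIAL
  ids[is.na(idx)] <- UNK_ID
  ids
}

#' Encode a DNA segment to token ids
#'
#' Produces `[CLS] <k-mer ids> [SEP]`, optionally right-padded with `[PAD]`
#' to `max_positions`. Segments whose k-mer count exceeds
#' `max_positions - 2` are truncated at the 3' end with a warning (the 5'
#' end is kept). Tokens containing characters outside `{A,C,G,T}` encode as
#' `[UNK]`.
#'
#' @param sequence A single uppercase DNA string.
#' @param tokenizer An [lca_tokenizer()].
#' @param pad Right-pad the id vector with `[PAD]` to `max_positions`.
#' @return An object of class `tokenized_segment`: a list with `tokens`
#'   (character, k-mers only), `ids` (integer, with specials), and
#'   `n_covered_nt = k + (n_kmers - 1) * shift`.
#' @examples
#' encode_segment("ACGT", lca_tokenizer(k = 1))$ids
#' @export
encode_segment <- function(sequence, tokenizer, pad = FALSE) {
  stopifnot(inherits(tokenizer, "lca_tokenizer"))
  k <- tokenizer$k
  shift <- tokenizer$shift
  tokens <- lca_tokenize(sequence, k, shift)
  limit <- tokenizer$max_positions - 2L
  if (length(tokens) > limit) {
    warn(sprintf(
      "segment yields %d k-mers but only %d positions are available; truncating at the 3' end",
      length(tokens), limit
    ))
    tokens <- tokens[seq_len(limit)]
  }
  ids <- c(CLS_ID, kmer_ids(tokens, k), SEP_ID)
  if (pad && length(ids) < tokenizer$max_positions) {
    ids <- c(ids, rep(PAD_ID, tokenizer$max_positions - length(ids)))
  }
  structure(
    list(
      tokens = tokens,
      ids = ids,
      n_covered_nt = k + (length(tokens) - 1L) * shift,
      k = k,
      shift = shift
    ),
    class = "tokenized_segment"
  )
}

#' Decode LCA tokens back to the DNA sequence
#'
#' Reconstructs the first token fully, then appends the last `shift`
#' characters of each subsequent token. Overlapping regions of consecutive
#' tokens must agree; a disagreement raises an error naming the first
#' offending token.
#'
#' @param tokens Character vector of k-mer tokens (specials stripped).
#' @inheritParams lca_tokenizer
#' @return The reconstructed DNA string.
#' @examples
#' decode_tokens(lca_tokenize("AAGTCCAGGATCAAGATT", 6, 2), k = 6, shift = 2)
#' @export
decode_tokens <- function(tokens, k = 6, shift = 1) {
  if (length(tokens) == 0) abort("no tokens to decode")
  if (any(nchar(tokens) != k)) abort("all tokens must have length k")
  if (length(tokens) > 1) {
    prev_tail <- substring(tokens[-length(tokens)], shift + 1L, k)
    next_head <- substring(tokens[-1], 1L, k - shift)
    bad <- which(prev_tail != next_head)
    if (length(bad) > 0) {
      abort(sprintf(
        "overlap mismatch between tokens %d and %d: '%s' vs '%s'",
        bad[1], bad[1] + 1L, prev_tail[bad[1]], next_head[bad[1]]
      ))
    }
  }
  paste0(tokens[1], paste(substring(tokens[-1], k - shift + 1L, k), collapse = ""))
}

#' Nucleotide context covered by a token budget
#'
#' A model with `n_token_positions` slots spends `n_special` of them on
#' special tokens; the remaining slots hold k-mers that jointly cover
#' `k + (n_token_positions - n_special - 1) * shift` nucleotides. This is
#' the context-size arithmetic behind the 1027 nt (k=6, shift=1, 1024
#' positions), 1022 nt (k=1) and 4096 nt (k=6, shift=2, 2048 positions)
#' figures of the base model family.
#'
#' @param n_token_positions Total token slots including specials.
#' @param k K-mer size.
#' @param shift Stride in nucleotides.
#' @param n_special Number of special-token slots (default 2: `[CLS]`,
#'   `[SEP]`).
#' @return Covered nucleotides (integer).
#' @examples
#' covered_nt(1024, k = 6, shift = 1) # 1027
#' covered_nt(1024, k = 1, shift = 1) # 1022
#' covered_nt(2048, k = 6, shift = 2) # 4096
#' @export
covered_nt <- function(n_token_positions, k, shift, n_special = 2) {
  if (n_token_positions <= n_special) {
    abort("`n_token_positions` must exceed `n_special`")
  }
  as.integer(k + (n_token_positions - n_special - 1) * shift)
}

#' Corrupt nucleotides and mask the overlapping tokens
#'
#' Emulates single-character corruption: each given position is replaced by
#' an unknown character and every k-mer token whose window contains a
#' corrupted position is mapped to `[MASK]`. With k = 6 and shift = 1,
#' corrupting the 7th nucleotide of an 18-mer masks six consecutive tokens;
#' with shift = 2 the masked windows jointly hide the 8th character as well.
#'
#' @param sequence A single uppercase DNA string.
#' @param positions Integer vector of 1-based nucleotide positions to corrupt.
#' @param tokenizer An [lca_tokenizer()].
#' @return A `tokenized_segment` whose `ids` carry `[MASK]` at affected
#'   token positions, plus elements `masked_tokens` (1-based k-mer token
#'   indices) and `original_ids` (the uncorrupted encoding).
#' @export
corrupt_and_mask <- function(sequence, positions, tokenizer) {
  n <- nchar(sequence)
  if (any(positions < 1 | positions > n)) {
    abort("corruption positions must lie within the sequence")
  }
  seg <- encode_segment(sequence, tokenizer)
  masked <- overlapping_token_indices(positions, tokenizer$k, tokenizer$shift,
                                      length(seg$tokens))
  out <- seg
  out$original_ids <- seg$ids
  out$ids[masked + 1L] <- MASK_ID # +1: [CLS] occupies position 1
  out$masked_tokens <- masked
  out
}

# 1-based indices of k-mer tokens whose window [ (j-1)*shift+1, (j-1)*shift+k ]
# intersects any of the 1-based nt positions.
overlapping_token_indices <- function(positions, k, shift, n_tokens) {
  if (length(positions) == 0 || n_tokens == 0) return(integer(0))
  hits <- lapply(positions, function(p) {
    # token j covers p  <=>  (j-1)*shift + 1 <= p <= (j-1)*shift + k
    lo <- ceiling((p - k) / shift) + 1L
    hi <- floor((p - 1) / shift) + 1L
    seq.int(max(1L, lo), min(n_tokens, hi))
  })
  sort(unique(unlist(hits)))
}

#' Persist a tokenized dataset as TSV
#'
#' Writes one row per segment with space-separated token ids plus `k` and
#' `shift` metadata columns, a plain-text cache that round-trips through
#' [read_tokenized_tsv()].
#'
#' @param segments List of `tokenized_segment` objects.
#' @param path Output file path.
#' @export
write_tokenized_tsv <- function(segments, path) {
  stopifnot(all(map_chr(segments, ~class(.x)[1]) == "tokenized_segment"))
  df <- tibble(
    ids = map_chr(segments, ~paste(.x$ids, collapse = " ")),
    k = map_int(segments, "k"),
    shift = map_int(segments, "shift")
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_tokenized_tsv
#' @return `read_tokenized_tsv()` returns a list of integer id vectors with
#'   attributes `k` and `shift`.
#' @export
read_tokenized_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- map(strsplit(df$ids, " "), as.integer)
  attr(ids, "k") <- df$k[1]
  attr(ids, "shift") <- df$shift[1]
  ids
}
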