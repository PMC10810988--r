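#' Fit an order-o nucleotide Markov chain
#'
#' Transition counts are accumulated over all sliding windows of length
#' `order + 1`; the fitted model predicts the next nucleotide from the
#' previous `order` nucleotides, giving `4^(order + 1)` (context, next)
#' entries — 256 for the order-3 chain. With `add_revcomp` each sequence's
#' reverse complement is appended before counting (strand-symmetric
#' counts), the construction used when modelling the composition of
#' promoter sets. The initial-context distribution is the empirical
#' distribution of length-`order` prefixes.
#'
#' @param seqs Character vector of DNA sequences, each longer than `order`.
#'   Sequences with non-`ACGT` characters are skipped with a warning.
#' @param order Chain order, >= 0.
#' @param add_revcomp Append reverse complements before counting.
#' @param pseudocount Laplace smoothing added to every (context, next) count
#'   (default 0: direct estimation).
#' @return An object of class `markov_model`: counts matrix
#'   `[4^order contexts x 4]`, normalized transition matrix, initial
#'   distribution, `order`, `pseudocount`.
#' @examples
#' m <- fit_markov("ACGTACGTACGTACGT", order = 3)
#' tidy(m)
#' @export
fit_markov <- function(seqs, order, add_revcomp = FALSE, pseudocount = 0) {
  stopifnot(order >= 0, pseudocount >= 0)
  if (length(seqs) == 0) abort("empty corpus: no sequences to fit")
  ok <- is_dna(seqs, allow_n = FALSE) & nchar(seqs) > order
  if (!any(ok)) abort("no usable sequences (ACGT-only, length > order) in corpus")
  if (any(!ok)) {
    warn(sprintf("%d sequences skipped (non-ACGT characters or too short)", sum(!ok)))
  }
  seqs <- seqs[ok]
  if (add_revcomp) seqs <- c(seqs, revcomp(seqs))

  contexts <- all_contexts(order)
  counts <- matrix(pseudocount, nrow = length(contexts), ncol = 4,
                   dimnames = list(contexts, DNA_BASES))
  init <- setNames(rep(0, length(contexts)), contexts)
  for (s in seqs) {
    n <- nchar(s)
    ctx <- if (order == 0) rep(".", n) else substring(s, 1:(n - order), order:(n - 1))
    nxt <- substring(s, (order + 1):n, (order + 1):n)
    tab <- table(factor(ctx, levels = contexts), factor(nxt, levels = DNA_BASES))
    counts <- counts + as.numeric(tab) # strip the "table" class, keep layout
    pre <- if (order == 0) "." else substring(s, 1, order)
    init[pre] <- init[pre] + 1
  }
  structure(
    list(
      order = as.integer(order),
      counts = counts,
      transition = normalize_rows(counts),
      initial_distribution = init / sum(init),
      pseudocount = pseudocount,
      add_revcomp = add_revcomp
    ),
    class = "markov_model"
  )
}

all_contexts <- function(order) {
  # "." labels the empty context of the order-0 chain (a valid R name)
  if (order == 0) "." else all_kmers(order)
}

normalize_rows <- function(m) {
  rs <- rowSums(m)
  out <- m / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- NA_real_
  out
}

#' Number of (context, next-base) entries of an order-o chain
#'
#' @param order Chain order, >= 0.
#' @return `4^(order + 1)`: 256 for order 3, 4 for order 0.
#' @export
transition_entry_count <- function(order) {
  stopifnot(order >= 0)
  4^(order + 1)
}

#' A uniform order-0 nucleotide model
#'
#' The "pure random" preset: every base equiprobable. The compositional
#' alternative is `fit_markov(positives, order = 0)`.
#'
#' @return A `markov_model` of order 0 with uniform transitions.
#' @export
uniform_markov <- function() {
  counts <- matrix(1, nrow = 1, ncol = 4, dimnames = list(".", DNA_BASES))
  structure(
    list(order = 0L, counts = counts, transition = normalize_rows(counts),
         initial_distribution = setNames(1, "."), pseudocount = 0, add_revcomp = FALSE),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> order %d, %d (context, next) entries%s\n",
              x$order, transition_entry_count(x$order),
              if (x$add_revcomp) ", strand-symmetrized" else ""))
  invisible(x)
}

#' Sample sequences from a fitted Markov chain
#'
#' Each sequence starts with a context drawn from the model's
#' initial-context distribution, then extends one base at a time from the
#' fitted transition probabilities.
#'
#' @param model A `markov_model`.
#' @param length Sequence length, > `model$order`.
#' @param n Number of sequences.
#' @param seed Optional integer seed.
#' @return Character vector of `n` DNA strings.
#' @export
generate_markov <- function(model, length, n, seed = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (length <= model$order) abort("`length` must exceed the model order")
  if (n == 0) return(character(0))
  o <- model$order
  tr <- model$transition
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ctx_start <- sample(names(model$initial_distribution), 1,
                          prob = model$initial_distribution)
      chars <- if (o == 0) character(0) else strsplit(ctx_start, "")[[1]]
      while (length(chars) < length) {
        ctx <- if (o == 0) "." else paste(utils::tail(chars, o), collapse = "")
        p <- tr[ctx, ]
        if (anyNA(p)) {
          abort(sprintf("context '%s' has no observed transitions and pseudocount is 0", ctx))
        }
        chars <- c(chars, sample(DNA_BASES, 1, prob = p))
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a Markov model into a long transition table
#'
#' @param x A `markov_model`.
#' @param ... Unused.
#' @return Tibble with `context`, `next_base`, `count`, `probability`.
#' @export
tidy.markov_model <- function(x, ...) {
  tibble(
    context = rep(rownames(x$counts), times = 4),
    next_base = rep(DNA_BASES, each = nrow(x$counts)),
    count = as.vector(x$counts),
    probability = as.vector(x$transition)
  ) %>%
    arrange(.data$context, .data$next_base)
}

#' Serialize a Markov model to TSV
#'
#' One row per context with A/C/G/T transition probabilities; the inverse of
#' [read_markov_tsv()] up to the unrecoverable raw counts (probabilities are
#' restored exactly).
#'
#' @param model A `markov_model`.
#' @param path File path.
#' @export
write_markov_tsv <- function(model, path) {
  df <- tibble(context = rownames(model$transition)) %>%
    dplyr::bind_cols(as_tibble(model$transition))
  attr_line <- sprintf("# order=%d", model$order)
  writeLines(attr_line, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_markov_tsv
#' @export
read_markov_tsv <- function(path) {
  header <- readLines(path, n = 1)
  order <- as.integer(sub("# order=", "", header))
  df <- readr::read_tsv(path, skip = 1, show_col_types = FALSE,
                        col_types = readr::cols(context = "c"))
  df$context[is.na(df$context)] <- "."
  tr <- as.matrix(df[, DNA_BASES])
  rownames(tr) <- df$context
  structure(
    list(order = order, counts = tr, transition = tr,
         initial_distribution = setNames(rep(1 / nrow(tr), nrow(tr)), df$context),
         pseudocount = NA_real_, add_revcomp = NA),
    class = "markov_model"
  )
}
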