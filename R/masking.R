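#' Masking configuration for masked-language-model batches
#'
#' With overlapping k-mers, masking a single token is insufficient: an
#' unmasked neighbour sharing `k - shift` characters would leak the hidden
#' content. Masking therefore operates at the nucleotide level: masking
#' *events* hide `span_nt` consecutive nucleotides each, and every token
#' overlapping a hidden nucleotide is masked. Because one event masks about
#' `(k + span_nt - 1) / shift` tokens, the per-nucleotide event probability
#' is recalibrated from the target masked-token fraction (see
#' [select_mask_events()]).
#'
#' Noise is applied independently per masked token: replaced by `[MASK]`
#' with probability `p1`, by a uniformly random non-special k-mer with
#' `p2`, left unchanged with `p3` (defaults 0.8 / 0.1 / 0.1).
#'
#' @param target_mask_fraction Target fraction of k-mer tokens masked
#'   (default 0.15).
#' @param span_nt Contiguous nucleotides hidden per masking event (default 2,
#'   the span used with k = 6).
#' @param p1,p2,p3 Mask / randomize / keep probabilities; must sum to 1.
#' @param calibration `"exact"` (default) chooses the event probability so
#'   the interior per-token masked probability equals the target exactly;
#'   `"first_order"` uses the linear approximation
#'   `target / (k + span_nt - 1)`.
#' @param seed Optional integer seed used by [make_mlm_batch()].
#' @return An object of class `masking_config`.
#' @export
masking_config <- function(target_mask_fraction = 0.15, span_nt = 2,
                           p1 = 0.8, p2 = 0.1, p3 = 0.1,
                           calibration = c("exact", "first_order"),
                           seed = NULL) {
  if (abs(p1 + p2 + p3 - 1) > 1e-8 || any(c(p1, p2, p3) < 0)) {
    abort("p1 + p2 + p3 must equal 1 with all nonnegative")
  }
  if (target_mask_fraction <= 0 || target_mask_fraction >= 1) {
    abort("`target_mask_fraction` must be in (0, 1)")
  }
  if (span_nt < 1) abort("`span_nt` must be >= 1")
  structure(
    list(
      target_mask_fraction = target_mask_fraction,
      span_nt = as.integer(span_nt),
      p1 = p1, p2 = p2, p3 = p3,
      calibration = match.arg(calibration),
      seed = seed
    ),
    class = "masking_config"
  )
}

# Per-nucleotide event-start probability implied by a masking config.
mask_event_probability <- function(config, k, shift) {
  span <- config$span_nt
  f <- config$target_mask_fraction
  # an event intersects k + span - 1 candidate token start offsets in nt space
  width <- k + span - 1
  p_sel <- switch(config$calibration,
    exact = 1 - (1 - f)^(1 / width),
    first_order = f / width
  )
  if (p_sel >= 1) abort("masking config infeasible: event probability >= 1")
  p_sel
}

#' Select nucleotides to hide for one segment
#'
#' Samples masking-event start positions i.i.d. over the nucleotides covered
#' by the segment's tokens, each event hiding `span_nt` consecutive
#' nucleotides. The per-position probability is recalibrated so that after
#' overlap expansion the masked-token fraction matches
#' `target_mask_fraction`: an interior token is hit by an event iff one of
#' the `k + span_nt - 1` start positions intersecting its window fires, so
#' the exact calibration solves `1 - (1 - p_sel)^(k + span_nt - 1) = target`.
#'
#' @param n_tokens Number of k-mer tokens in the segment.
#' @param config A [masking_config()].
#' @param k,shift Tokenizer parameters.
#' @return Sorted integer vector of hidden 1-based nucleotide indices
#'   (possibly empty).
#' @export
select_mask_events <- function(n_tokens, config, k, shift) {
  stopifnot(n_tokens > 0)
  p_sel <- mask_event_probability(config, k, shift)
  n_nt <- k + (n_tokens - 1L) * shift
  span <- config$span_nt
  starts <- which(stats::runif(n_nt) < p_sel)
  if (length(starts) == 0) return(integer(0))
  hidden <- unique(unlist(lapply(starts, function(s) s:min(s + span - 1L, n_nt))))
  sort(hidden)
}

#' Expand hidden nucleotides to the overlapping token set
#'
#' Returns every token index whose k-mer window intersects a hidden
#' nucleotide. This guarantees the no-leak property: no unmasked token
#' contains a masked nucleotide. For k = 6, shift = 1, an interior hidden
#' nucleotide masks six consecutive tokens.
#'
#' @param masked_nt Integer vector of hidden 1-based nucleotide indices.
#' @param k,shift Tokenizer parameters.
#' @param n_tokens Number of k-mer tokens in the segment.
#' @return Sorted integer vector of 1-based k-mer token indices.
#' @examples
#' expand_mask_to_overlaps(7, k = 6, shift = 1, n_tokens = 13)
#' @export
expand_mask_to_overlaps <- function(masked_nt, k, shift, n_tokens) {
  overlapping_token_indices(masked_nt, k, shift, n_tokens)
}

#' Apply three-way noise to masked token ids
#'
#' Independently per masked token: `[MASK]` with probability `p1`, a
#' uniformly random non-special k-mer id with `p2`, unchanged with `p3`.
#'
#' @param ids Integer id vector for one encoded segment (with specials).
#' @param masked_positions 1-based positions within `ids` to perturb.
#' @param config A [masking_config()].
#' @param vocab_size Total vocabulary size (specials + k-mers).
#' @return The perturbed id vector.
#' @export
apply_noise <- function(ids, masked_positions, config, vocab_size) {
  if (length(masked_positions) == 0) return(ids)
  if (any(masked_positions < 1 | masked_positions > length(ids))) {
    abort("masked positions out of range")
  }
  u <- stats::runif(length(masked_positions))
  to_mask <- u < config$p1
  to_random <- !to_mask & u < config$p1 + config$p2
  ids[masked_positions[to_mask]] <- MASK_ID
  n_r <- sum(to_random)
  if (n_r > 0) {
    ids[masked_positions[to_random]] <-
      sample.int(vocab_size - N_SPECIAL, n_r, replace = TRUE) + N_SPECIAL - 1L
  }
  ids
}

#' Build a masked-language-model batch
#'
#' For each encoded segment: select masking events in nucleotide space,
#' expand to all overlapping tokens (no-leak), and apply three-way noise.
#' Special tokens are never masked. Labels carry the original ids exactly at
#' masked positions and `NA` elsewhere.
#'
#' @param segments List of `tokenized_segment` objects sharing one tokenizer
#'   configuration.
#' @param config A [masking_config()]; its `seed` (when set) makes the batch
#'   deterministic.
#' @param vocab_size Total vocabulary size; defaults to `4^k + 5`.
#' @return An object of class `masked_batch`: list with integer matrices
#'   `input_ids` and `labels` (`NA` = ignore) and logical matrix `mask`, all
#'   `[n_segments x max positions]` right-padded with `[PAD]`, plus
#'   `hidden_nt` (per-segment hidden nucleotide indices, for masking audits)
#'   and `k`, `shift`.
#' @export
make_mlm_batch <- function(segments, config, vocab_size = NULL) {
  stopifnot(length(segments) > 0, inherits(config, "masking_config"))
  ks <- map_int(segments, "k")
  shifts <- map_int(segments, "shift")
  if (length(unique(ks)) != 1 || length(unique(shifts)) != 1) {
    abort("all segments in a batch must share one tokenizer configuration")
  }
  k <- ks[1]; shift <- shifts[1]
  if (is.null(vocab_size)) vocab_size <- 4^k + N_SPECIAL
  width <- max(map_int(segments, ~length(.x$ids)))
  with_seed(config$seed, {
    input_ids <- matrix(PAD_ID, nrow = length(segments), ncol = width)
    labels <- matrix(NA_integer_, nrow = length(segments), ncol = width)
    mask <- matrix(FALSE, nrow = length(segments), ncol = width)
    hidden <- vector("list", length(segments))
    for (i in seq_along(segments)) {
      seg <- segments[[i]]
      n_tok <- length(seg$tokens)
      hidden_nt <- select_mask_events(n_tok, config, k, shift)
      masked_tok <- expand_mask_to_overlaps(hidden_nt, k, shift, n_tok)
      ids <- seg$ids
      pos <- masked_tok + 1L # offset for [CLS]
      noisy <- apply_noise(ids, pos, config, vocab_size)
      input_ids[i, seq_along(noisy)] <- noisy
      labels[i, pos] <- ids[pos]
      mask[i, pos] <- TRUE
      hidden[[i]] <- hidden_nt
    }
    structure(
      list(input_ids = input_ids, labels = labels, mask = mask,
           hidden_nt = hidden, k = k, shift = shift),
      class = "masked_batch"
    )
  })
}

#' Masked-token negative log likelihood
#'
#' The masked-language-model loss: the sum over masked positions of the
#' negative log probability assigned to the true token,
#' `L = -sum_i m_i * log y_i[l_i]`. The mean per masked token is reported
#' alongside (batch-size invariant; the form used for optimization).
#'
#' @param predicted_probs Numeric matrix `[positions x vocab]`, rows summing
#'   to 1.
#' @param labels Integer vector of true 0-based token ids (`NA` where
#'   unmasked).
#' @param mask Logical vector; defaults to `!is.na(labels)`.
#' @param eps Probability clamp guarding `log(0)`.
#' @return List with `sum`, `mean` and `n_masked`.
#' @export
mlm_loss <- function(predicted_probs, labels, mask = NULL, eps = 1e-12) {
  if (is.null(mask)) mask <- !is.na(labels)
  stopifnot(length(labels) == nrow(predicted_probs), length(mask) == length(labels))
  idx <- which(mask)
  if (length(idx) == 0) return(list(sum = 0, mean = NaN, n_masked = 0L))
  p <- predicted_probs[cbind(idx, labels[idx] + 1L)]
  nll <- -log(pmax(p, eps))
  list(sum = sum(nll), mean = mean(nll), n_masked = length(idx))
}
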