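#' Binary-classification metrics from a confusion table
#'
#' Computes MCC, F1, precision, recall, accuracy, sensitivity and
#' specificity from the four confusion counts. MCC is defined as 0 when any
#' factor of its denominator vanishes (the standard convention for
#' degenerate tables); sensitivity is identical to recall.
#'
#' @param TP,TN,FP,FN Nonnegative counts.
#' @return One-row tibble with columns `mcc`, `f1`, `precision`, `recall`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(TP = 50, TN = 50, FP = 0, FN = 0)
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) abort("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) abort("empty confusion table")
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  precision <- if (TP + FP == 0) NaN else TP / (TP + FP)
  recall <- if (TP + FN == 0) NaN else TP / (TP + FN)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(
    mcc = mcc,
    f1 = f1,
    precision = precision,
    recall = recall,
    accuracy = (TP + TN) / total,
    sensitivity = recall,
    specificity = if (TN + FP == 0) NaN else TN / (TN + FP)
  )
}

#' Confusion counts from labels and predictions
#'
#' @param truth,predicted Vectors of 0/1 labels.
#' @return Named list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(
    TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0)
  )
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counting one half. Equivalent to
#' the area under the curve of sensitivity against 1 - specificity.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("ROC-AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Silhouette widths for a clustering
#'
#' For sample i, `a(i)` is the mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to any other cluster;
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, in `[-1, 1]`. Members of
#' singleton clusters get `s(i) = 0` by convention.
#'
#' @param x Numeric matrix of points (Euclidean distance) or a `dist`
#'   object.
#' @param cluster_labels Cluster assignment, one per sample; at least two
#'   distinct clusters.
#' @return Tibble with `observation`, `cluster`, `silhouette`; the mean
#'   width is `mean(result$silhouette)`.
#' @export
silhouette_score <- function(x, cluster_labels) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  labs <- as.character(cluster_labels)
  if (length(unique(labs)) < 2) abort("silhouette undefined for a single cluster")
  stopifnot(nrow(d) == length(labs))
  n <- nrow(d)
  sizes <- table(labs)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labs[i]
    if (sizes[[own]] == 1) { s[i] <- 0; next }
    a <- sum(d[i, labs == own]) / (sizes[[own]] - 1) # excludes self (d=0)
    b <- min(vapply(setdiff(unique(labs), own), function(cl) {
      mean(d[i, labs == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  tibble(observation = seq_len(n), cluster = labs, silhouette = s)
}

#' Masked-token restoration statistics
#'
#' For each masked position, the reference rank of the true token is the
#' number of vocabulary entries with strictly greater predicted probability,
#' ties counting one half (0 = perfect restoration). Top-k is the indicator
#' `rank < k` under the same convention; the per-position one-vs-rest AUC of
#' the true token's probability is `1 - rank / (V - 1)`. Averages of all
#' four statistics are reported.
#'
#' @param predicted_probs Numeric matrix `[positions x vocab]`, rows
#'   summing to 1.
#' @param true_ids Integer vector of true 0-based token ids.
#' @return An object of class `masking_eval_result`; `tidy()` gives the
#'   per-position table, `glance()` the averages (`avg_rank`, `top1`,
#'   `top3`, `avg_auc`).
#' @export
masking_eval <- function(predicted_probs, true_ids) {
  predicted_probs <- as.matrix(predicted_probs)
  V <- ncol(predicted_probs)
  stopifnot(nrow(predicted_probs) == length(true_ids))
  if (any(true_ids < 0 | true_ids >= V)) abort("true token id out of vocabulary")
  p_true <- predicted_probs[cbind(seq_along(true_ids), true_ids + 1L)]
  rank <- vapply(seq_along(true_ids), function(i) {
    row <- predicted_probs[i, ]
    sum(row > p_true[i]) + (sum(row == p_true[i]) - 1) / 2
  }, numeric(1))
  per_position <- tibble(
    position = seq_along(true_ids),
    true_id = as.integer(true_ids),
    rank = rank,
    top1 = as.numeric(rank < 1),
    top3 = as.numeric(rank < 3),
    auc = 1 - rank / (V - 1)
  )
  structure(
    list(per_position = per_position,
         summary = tibble(
           avg_rank = mean(rank),
           top1 = mean(per_position$top1),
           top3 = mean(per_position$top3),
           avg_auc = mean(per_position$auc),
           n_positions = length(true_ids)
         )),
    class = "masking_eval_result"
  )
}

#' @export
tidy.masking_eval_result <- function(x, ...) x$per_position

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.masking_eval_result <- function(x, ...) x$summary

#' @export
print.masking_eval_result <- function(x, ...) {
  cat("<masking_eval_result>\n")
  print(x$summary)
  invisible(x)
}

#' Single-character corruption benchmark
#'
#' For each segment, one uniformly chosen character per trial is corrupted;
#' every token overlapping it is mapped to `[MASK]`; the model predicts the
#' leftmost masked token and the restoration statistics are collected,
#' stratified by segment length and (when present) annotated feature type.
#'
#' @param model A model understood by [predict_token_probs()].
#' @param segments Tibble with a `sequence` column and optional
#'   `feature_type` and `length` columns.
#' @param tokenizer An [lca_tokenizer()].
#' @param n_corruptions Corruption trials per segment.
#' @param seed Integer seed.
#' @return Tibble keyed by (`length`, `feature_type`) with columns
#'   `avg_rank`, `top1`, `top3`, `avg_auc`, `n_positions`.
#' @export
run_corruption_benchmark <- function(model, segments, tokenizer,
                                     n_corruptions = 100, seed = 1) {
  stopifnot(nrow(segments) > 0)
  if (!"length" %in% names(segments)) {
    segments$length <- nchar(segments$sequence)
  }
  if (!"feature_type" %in% names(segments)) segments$feature_type <- "all"
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(segments))) {
      s <- segments$sequence[i]
      seg <- encode_segment(s, tokenizer)
      n_cov <- seg$n_covered_nt
      pos <- sample.int(n_cov, n_corruptions, replace = TRUE)
      ranks <- numeric(n_corruptions); aucs <- numeric(n_corruptions)
      top1 <- numeric(n_corruptions); top3 <- numeric(n_corruptions)
      for (t in seq_len(n_corruptions)) {
        cm <- corrupt_and_mask(s, pos[t], tokenizer)
        eval_tok <- cm$masked_tokens[1]
        probs <- predict_token_probs(model, cm$ids)
        me <- masking_eval(probs[eval_tok + 1L, , drop = FALSE],
                           cm$original_ids[eval_tok + 1L])
        ranks[t] <- me$summary$avg_rank
        top1[t] <- me$summary$top1
        top3[t] <- me$summary$top3
        aucs[t] <- me$summary$avg_auc
      }
      rows[[i]] <- tibble(
        segment = i,
        length = segments$length[i],
        feature_type = segments$feature_type[i],
        avg_rank = mean(ranks), top1 = mean(top1), top3 = mean(top3),
        avg_auc = mean(aucs), n_positions = n_corruptions
      )
    }
    bind_rows(rows) %>%
      group_by(.data$length, .data$feature_type) %>%
      summarise(
        avg_rank = stats::weighted.mean(.data$avg_rank, .data$n_positions),
        top1 = stats::weighted.mean(.data$top1, .data$n_positions),
        top3 = stats::weighted.mean(.data$top3, .data$n_positions),
        avg_auc = stats::weighted.mean(.data$avg_auc, .data$n_positions),
        n_positions = sum(.data$n_positions),
        .groups = "drop"
      )
  })
}

#' Pooled encoder embeddings of sequences
#'
#' Runs each sequence through a fitted model's encoder and pools the k-mer
#' token representations (special positions excluded) with one of the fixed
#' reductions. Batch-order invariant and deterministic.
#'
#' @param model A `dnalm_mlm_fit` or `dnalm_classifier_fit`.
#' @param sequences Character vector of DNA sequences.
#' @param pooling One of `"mean"`, `"sum"`, `"max"`, `"min"`.
#' @return Numeric matrix `[n x hidden_size]`.
#' @export
embed_segments <- function(model, sequences, pooling = "mean") {
  cfg <- model$model_cfg
  out <- matrix(NA_real_, length(sequences), cfg$encoder$hidden_size)
  for (i in seq_along(sequences)) {
    ids <- encode_segment(sequences[i], cfg$tokenizer)$ids
    S <- encoder_forward(model$params$encoder, ids, cfg$encoder)$S
    kmer_rows <- seq(2, length(ids) - 1) # drop [CLS]/[SEP]
    out[i, ] <- pool_fixed(S[kmer_rows, , drop = FALSE], pooling)
  }
  out
}
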