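#' Plant a motif into sequences at random positions
#'
#' Overwrites a uniformly chosen window of each sequence with `motif`.
#'
#' @param seqs Character vector of DNA sequences, each at least as long as
#'   the motif.
#' @param motif DNA string.
#' @param seed Optional integer seed.
#' @return Character vector with the motif planted.
#' @export
plant_motif <- function(seqs, motif, seed = NULL) {
  m <- nchar(motif)
  stopifnot(all(nchar(seqs) >= m))
  with_seed(seed, {
    pos <- 1L + floor(stats::runif(length(seqs)) * (nchar(seqs) - m + 1))
    paste0(
      substring(seqs, 1, pos - 1),
      motif,
      substring(seqs, pos + m, nchar(seqs))
    )
  })
}

#' Run a demonstration-scale training experiment
#'
#' Wires the whole pipeline on synthetic data with the `tiny_demo` preset:
#' fixture generation, tokenization, masking or dataset building, compact
#' encoder training, and evaluation. Three tasks are available:
#'
#' * `"mlm"` — masked-language-model pretraining on segments of a synthetic
#'   genome; reports the per-step masked-token loss.
#' * `"promoter"` — binary promoter classification on 81 nt records with a
#'   planted sigma70-like motif in the positives and the standard 40/40/20
#'   negative mix; reports held-out confusion metrics and ROC-AUC.
#' * `"phage"` — phage-vs-host segment classification on a genus-labelled
#'   synthetic collection with parent-level splits.
#'
#' @param task One of `"mlm"`, `"promoter"`, `"phage"`.
#' @param preset Encoder preset (default `"tiny_demo"`; the full-size
#'   presets are far beyond CPU demo scale).
#' @param seed Integer seed controlling fixtures, splits and training.
#' @param n_records Total promoter records (positives + negatives) before
#'   the 80/20 train/test partition used at demo scale (default 2500:
#'   2000 train, 500 test).
#' @param steps MLM optimization steps (default 200).
#' @param epochs Classifier epochs.
#' @param motif Planted promoter motif (10 nt, AT-rich sigma70 flavour).
#' @param opt Optimizer settings; see [adamw_defaults()].
#' @return An object of class `dnalm_demo_fit` with the fitted model, the
#'   loss history, the dataset, held-out predictions and a one-row metrics
#'   tibble (`glance()`).
#' @export
run_demo_training <- function(task = c("promoter", "mlm", "phage"),
                              preset = "tiny_demo", seed = 1,
                              n_records = 2500, steps = 200, epochs = 6,
                              motif = "TTGACATAAT",
                              opt = adamw_defaults(lr = 1e-3)) {
  task <- match.arg(task)
  model_cfg <- make_encoder_config(preset)
  switch(task,
    mlm = demo_mlm(model_cfg, seed, steps, opt),
    promoter = demo_promoter(model_cfg, seed, n_records, epochs, motif, opt),
    phage = demo_phage(model_cfg, seed, epochs, opt)
  )
}

demo_mlm <- function(model_cfg, seed, steps, opt) {
  genome <- generate_synthetic_genome(
    synthetic_genome_spec(n_contigs = 2, contig_length_range = c(30000, 40000),
                          seed = seed)
  )
  segs <- bind_rows(lapply(seq_len(nrow(genome$contigs)), function(i) {
    segment_contiguous(genome$contigs[i, ], 128)
  }))
  segs <- segs[nchar(segs$sequence) == 128, ]
  segs <- segs[seq_len(min(500, nrow(segs))), ]
  fit <- fit_mlm_demo(segs$sequence, model_cfg, steps = steps, opt = opt,
                      seed = seed)
  lh <- fit$loss_history
  head_mean <- mean(lh$loss[1:10], na.rm = TRUE)
  tail_mean <- mean(lh$loss[(nrow(lh) - 9):nrow(lh)], na.rm = TRUE)
  structure(
    list(task = "mlm", fit = fit, loss_history = lh,
         metrics = tibble(initial_loss = head_mean, final_loss = tail_mean,
                          n_segments = nrow(segs), steps = steps)),
    class = "dnalm_demo_fit"
  )
}

demo_promoter <- function(model_cfg, seed, n_records, epochs, motif, opt) {
  n_pos <- n_records %/% 2
  genome <- generate_synthetic_genome(
    synthetic_genome_spec(n_contigs = 2, contig_length_range = c(40000, 50000),
                          motif = motif, seed = seed)
  )
  positives <- with_seed(seed + 1000L, {
    plant_motif(vapply(seq_len(n_pos), function(i) random_dna(81, gc = 0.45),
                       character(1)), motif)
  })
  cfg <- promoter_build_config(
    split_fractions = c(train = 0.8, validation = 0, test = 0.2),
    seed = seed
  )
  records <- build_promoter_dataset(positives, genome$contigs,
                                    genome$annotations, cfg)
  train <- dplyr::filter(records, .data$split == "train")
  test <- dplyr::filter(records, .data$split == "test")
  fit <- fit_classifier_demo(train, model_cfg, epochs = epochs, opt = opt,
                             seed = seed)
  preds <- predict(fit, test)
  cc <- confusion_counts(preds$label, preds$.pred)
  metrics <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN) %>%
    mutate(auc = roc_auc(preds$.prob_1, preds$label),
           n_train = nrow(train), n_test = nrow(test))
  structure(
    list(task = "promoter", fit = fit, loss_history = fit$loss_history,
         records = records, predictions = preds, metrics = metrics),
    class = "dnalm_demo_fit"
  )
}

demo_phage <- function(model_cfg, seed, epochs, opt) {
  # enough parent species per class that the 0.8/0.1/0.1 parent-level split
  # leaves both classes represented in every partition
  coll <- generate_synthetic_phage_collection(
    n_genera = 3, hosts_per_genus = 3, phages_per_genus = 5,
    host_length_range = c(8000, 12000), phage_length_range = c(3000, 6000),
    seed = seed
  )
  cfg <- phage_build_config(genus_bp_cap = 40000, max_upsample_coverage = 2,
                            segment_lengths = 122, include_revcomp = FALSE,
                            seed = seed)
  records <- build_phage_dataset(coll$phages, coll$hosts, cfg)
  train <- dplyr::filter(records, .data$split == "train")
  test <- dplyr::filter(records, .data$split == "test")
  if (nrow(train) > 800) {
    # records arrive grouped by class; subsample without losing either one
    train <- with_seed(seed + 1L, train[sample.int(nrow(train), 800), ])
  }
  fit <- fit_classifier_demo(train, model_cfg, epochs = epochs, opt = opt,
                             seed = seed)
  preds <- predict(fit, test)
  cc <- confusion_counts(preds$label, preds$.pred)
  metrics <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN) %>%
    mutate(auc = roc_auc(preds$.prob_1, preds$label),
           n_train = nrow(train), n_test = nrow(test))
  structure(
    list(task = "phage", fit = fit, loss_history = fit$loss_history,
         records = records, predictions = preds, metrics = metrics),
    class = "dnalm_demo_fit"
  )
}

#' @export
print.dnalm_demo_fit <- function(x, ...) {
  cat(sprintf("<dnalm_demo_fit> task = %s\n", x$task))
  print(x$metrics)
  invisible(x)
}

#' Tidy the loss history of a demo fit
#'
#' @param x A `dnalm_demo_fit`.
#' @param ... Unused.
#' @return Tibble with one row per step or epoch and the training loss.
#' @export
tidy.dnalm_demo_fit <- function(x, ...) x$loss_history

#' One-row metrics summary of a demo fit
#'
#' @param x A `dnalm_demo_fit`.
#' @param ... Unused.
#' @return One-row tibble of final metrics.
#' @export
glance.dnalm_demo_fit <- function(x, ...) x$metrics
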