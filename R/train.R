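# ---------------------------------------------------------------------------
# AdamW over nested parameter lists
# ---------------------------------------------------------------------------

# Leaves named after weight matrices/embeddings receive weight decay;
# biases and layer-norm parameters do not.
DECAYED_LEAVES <- c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "emb", "pos",
                    "Wm", "Wout")

adamw_new <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' AdamW optimizer defaults
#'
#' The decoupled-weight-decay Adam variant with the defaults used for
#' fine-tuning in this family of models: `beta1 = 0.95`, `beta2 = 0.98`,
#' `eps = 5e-5` (documented default; `eps = 1e-8` is the common
#' standard-value alternative), `weight_decay = 0.01`.
#'
#' @param lr Learning rate.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Denominator stabilizer.
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @return A list of optimizer settings.
#' @export
adamw_defaults <- function(lr = 4e-4, beta1 = 0.95, beta2 = 0.98,
                           eps = 5e-5, weight_decay = 0.01) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

adamw_step <- function(params, grads, state, opt) {
  state$t <- state$t + 1L
  bc1 <- 1 - opt$beta1^state$t
  bc2 <- 1 - opt$beta2^state$t
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        named <- !is.null(nms) && nzchar(nms[i])
        key <- if (named) nms[i] else i
        leaf_name <- if (named) nms[i] else name
        r <- walk(p[[key]], g[[key]], m[[key]], v[[key]], leaf_name)
        p[[key]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    upd <- (m / bc1) / (sqrt(v / bc2) + opt$eps)
    if (name %in% DECAYED_LEAVES) upd <- upd + opt$weight_decay * p
    list(p = p - opt$lr * upd, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, name = "")
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# ---------------------------------------------------------------------------
# Demo-scale masked-language-model training
# ---------------------------------------------------------------------------

#' Train a tiny masked-language model on CPU
#'
#' Wires tokenization, leakage-aware masking, the compact encoder, the MLM
#' head and the masked-token loss into a demonstration-scale training loop.
#' Not a route to the full-size pretrained models; it exists to exercise
#' and test the pipeline end to end.
#'
#' @param sequences Character vector of training segments.
#' @param model_cfg A preset from [make_encoder_config()] (default
#'   `tiny_demo`).
#' @param masking_cfg A [masking_config()].
#' @param steps Optimization steps.
#' @param batch_size Segments per step.
#' @param opt Optimizer settings from [adamw_defaults()].
#' @param seed Integer seed: fixes batching, masking and initialization.
#' @return An object of class `dnalm_mlm_fit` with the parameters, config
#'   and per-step loss history.
#' @export
fit_mlm_demo <- function(sequences,
                         model_cfg = make_encoder_config("tiny_demo"),
                         masking_cfg = masking_config(),
                         steps = 200, batch_size = 8,
                         opt = adamw_defaults(lr = 1e-3), seed = 1) {
  tok <- model_cfg$tokenizer
  enc_cfg <- model_cfg$encoder
  segs <- lapply(sequences, encode_segment, tokenizer = tok)
  V <- enc_cfg$vocab_size
  h <- enc_cfg$hidden_size
  with_seed(seed, {
    params <- list(
      encoder = init_encoder_params(enc_cfg),
      head = list(Wm = matrix(stats::rnorm(h * V, sd = 0.02), h, V),
                  bm = numeric(V))
    )
    state <- adamw_new(params)
    losses <- numeric(steps)
    for (step in seq_len(steps)) {
      idx <- sample.int(length(segs), min(batch_size, length(segs)))
      batch <- make_mlm_batch(segs[idx], masking_cfg, vocab_size = V)
      step_loss <- 0; n_masked <- 0L
      grads <- NULL
      for (b in seq_along(idx)) {
        ids <- batch$input_ids[b, ]
        real <- seq_len(length(segs[[idx[b]]]$ids))
        ids <- ids[real]
        mpos <- which(batch$mask[b, real])
        if (length(mpos) == 0) next
        labels <- batch$labels[b, real][mpos]
        fw <- encoder_forward(params$encoder, ids, enc_cfg, keep_cache = TRUE)
        Sm <- fw$S[mpos, , drop = FALSE]
        logits <- Sm %*% params$head$Wm + rep(params$head$bm, each = length(mpos))
        probs <- softmax_rows(logits)
        ll <- mlm_loss(probs, labels)
        step_loss <- step_loss + ll$sum
        n_masked <- n_masked + ll$n_masked
        dlogits <- probs
        dlogits[cbind(seq_along(mpos), labels + 1L)] <-
          dlogits[cbind(seq_along(mpos), labels + 1L)] - 1
        g_head <- list(Wm = crossprod(Sm, dlogits), bm = colSums(dlogits))
        dS <- matrix(0, length(ids), h)
        dS[mpos, ] <- dlogits %*% t(params$head$Wm)
        g_enc <- encoder_backward(params$encoder, fw$cache, dS, enc_cfg)
        grads <- accumulate_grads(grads, list(encoder = g_enc, head = g_head))
      }
      if (is.null(grads) || n_masked == 0) { losses[step] <- NA_real_; next }
      grads <- scale_grads(grads, 1 / n_masked)
      upd <- adamw_step(params, grads, state, opt)
      params <- upd$params; state <- upd$state
      losses[step] <- step_loss / n_masked
      if (!is.finite(losses[step])) abort("non-finite MLM loss: diverged")
    }
    structure(
      list(params = params, model_cfg = model_cfg, masking_cfg = masking_cfg,
           loss_history = tibble(step = seq_len(steps), loss = losses),
           task = "mlm"),
      class = "dnalm_mlm_fit"
    )
  })
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  walk <- function(a, b) {
    if (is.list(a)) {
      for (i in seq_along(a)) a[[i]] <- walk(a[[i]], b[[i]])
      a
    } else {
      a + b
    }
  }
  walk(acc, g)
}

scale_grads <- function(g, s) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else x * s
  }
  walk(g)
}

#' Per-token probability predictions of a masked-language model
#'
#' Generic interface used by the corruption benchmark: given token ids
#' (0-based, with specials), return a `[T x vocab]` matrix of next-token
#' probabilities per position.
#'
#' @param model A fitted model or baseline.
#' @param ids Integer token id vector.
#' @param ... Method-specific arguments.
#' @return Numeric probability matrix with rows summing to 1.
#' @export
predict_token_probs <- function(model, ids, ...) UseMethod("predict_token_probs")

#' @export
predict_token_probs.dnalm_mlm_fit <- function(model, ids, ...) {
  enc_cfg <- model$model_cfg$encoder
  fw <- encoder_forward(model$params$encoder, ids, enc_cfg)
  logits <- fw$S %*% model$params$head$Wm +
    rep(model$params$head$bm, each = length(ids))
  softmax_rows(logits)
}

#' Uniform-probability baseline language model
#'
#' Assigns equal probability to every k-mer token (specials excluded), the
#' reference point for restoration-rank comparisons: its expected reference
#' rank is `(V - 1) / 2` over the k-mer vocabulary.
#'
#' @param vocab_size Total vocabulary size including specials.
#' @return An object of class `uniform_lm`.
#' @export
uniform_lm <- function(vocab_size) {
  structure(list(vocab_size = vocab_size), class = "uniform_lm")
}

#' @export
predict_token_probs.uniform_lm <- function(model, ids, ...) {
  V <- model$vocab_size
  p <- rep(0, V)
  p[(N_SPECIAL + 1):V] <- 1 / (V - N_SPECIAL)
  matrix(p, nrow = length(ids), ncol = V, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Demo-scale sequence classification training
# ---------------------------------------------------------------------------

#' Train the weighted-pooling sequence classifier at demo scale
#'
#' End-to-end training of the compact encoder plus the attention-weighted
#' pooling head on binary-labeled records.
#'
#' @param records Labeled-records tibble (`sequence`, `label`).
#' @param model_cfg A preset from [make_encoder_config()].
#' @param epochs Passes over the training records.
#' @param batch_size Records per optimizer step.
#' @param opt Optimizer settings from [adamw_defaults()].
#' @param dropout_prob Dropout on the pooled representation during training.
#' @param seed Integer seed.
#' @return An object of class `dnalm_classifier_fit`.
#' @export
fit_classifier_demo <- function(records,
                                model_cfg = make_encoder_config("tiny_demo"),
                                epochs = 4, batch_size = 32,
                                opt = adamw_defaults(lr = 1e-3),
                                dropout_prob = 0.1, seed = 1) {
  tok <- model_cfg$tokenizer
  enc_cfg <- model_cfg$encoder
  ids_list <- lapply(records$sequence, function(s) encode_segment(s, tok)$ids)
  y <- records$label
  h <- enc_cfg$hidden_size
  with_seed(seed, {
    params <- list(
      encoder = init_encoder_params(enc_cfg),
      head = list(W1 = stats::rnorm(h, sd = 1 / sqrt(h)), b1 = 0,
                  Wout = matrix(stats::rnorm(h * 2, sd = 1 / sqrt(h)), h, 2),
                  bout = c(0, 0))
    )
    state <- adamw_new(params)
    n <- length(ids_list)
    epoch_losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1, n)]
        grads <- NULL
        for (i in bidx) {
          r <- classifier_fwd_bwd(params, ids_list[[i]], y[i], enc_cfg,
                                  dropout_prob)
          ep_loss <- ep_loss + r$loss
          grads <- accumulate_grads(grads, r$grads)
        }
        grads <- scale_grads(grads, 1 / length(bidx))
        upd <- adamw_step(params, grads, state, opt)
        params <- upd$params; state <- upd$state
      }
      epoch_losses[ep] <- ep_loss / n
      if (!is.finite(epoch_losses[ep])) abort("non-finite classification loss: diverged")
    }
    structure(
      list(params = params, model_cfg = model_cfg,
           loss_history = tibble(epoch = seq_len(epochs), loss = epoch_losses),
           task = "classification"),
      class = "dnalm_classifier_fit"
    )
  })
}

# Forward + backward of encoder -> attention weights -> weighted pool ->
# dropout -> affine map -> softmax cross-entropy, for one record.
classifier_fwd_bwd <- function(params, ids, label, enc_cfg, dropout_prob) {
  fw <- encoder_forward(params$encoder, ids, enc_cfg, keep_cache = TRUE)
  S <- fw$S
  T_ <- nrow(S)
  hd <- params$head
  scores <- drop(S %*% hd$W1) + hd$b1
  w <- softmax_vec(scores)
  P <- drop(crossprod(S, w))
  if (dropout_prob > 0) {
    keep <- stats::runif(length(P)) >= dropout_prob
    Pd <- P * keep / (1 - dropout_prob)
  } else {
    keep <- NULL
    Pd <- P
  }
  logits <- drop(crossprod(hd$Wout, Pd)) + hd$bout
  probs <- softmax_vec(logits)
  loss <- -log(max(probs[label + 1L], 1e-12))

  dlogits <- probs
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  g_Wout <- outer(Pd, dlogits)
  g_bout <- dlogits
  dPd <- drop(hd$Wout %*% dlogits)
  dP <- if (is.null(keep)) dPd else dPd * keep / (1 - dropout_prob)
  dS <- outer(w, dP)
  dw <- drop(S %*% dP)
  dscores <- w * (dw - sum(dw * w))
  dS <- dS + outer(dscores, hd$W1)
  g_W1 <- drop(crossprod(S, dscores))
  g_b1 <- sum(dscores)
  g_enc <- encoder_backward(params$encoder, fw$cache, dS, enc_cfg)
  list(
    loss = loss,
    grads = list(encoder = g_enc,
                 head = list(W1 = g_W1, b1 = g_b1, Wout = g_Wout, bout = g_bout))
  )
}

#' Predict with a fitted demo classifier
#'
#' @param object A `dnalm_classifier_fit`.
#' @param newdata Tibble with a `sequence` column.
#' @param ... Unused.
#' @return The input tibble with `.prob_1` (probability of class 1) and
#'   `.pred` (0/1 at threshold 0.5) appended.
#' @export
predict.dnalm_classifier_fit <- function(object, newdata, ...) {
  tok <- object$model_cfg$tokenizer
  enc_cfg <- object$model_cfg$encoder
  hd <- object$params$head
  prob1 <- vapply(newdata$sequence, function(s) {
    ids <- encode_segment(s, tok)$ids
    S <- encoder_forward(object$params$encoder, ids, enc_cfg)$S
    logits <- classify(S, structure(hd, class = "classifier_head"))
    softmax_vec(logits)[2]
  }, numeric(1), USE.NAMES = FALSE)
  newdata %>% mutate(.prob_1 = prob1, .pred = as.integer(prob1 >= 0.5))
}
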