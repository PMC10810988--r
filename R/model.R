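#' Encoder configuration
#'
#' Architecture hyperparameters for the encoder family. The full-size
#' presets describe 384-dimensional, 6-layer, 6-head encoders with a
#' 3072-dimensional GELU feed-forward expansion; `tiny_demo` is a
#' desk-scale variant small enough to train on one CPU in the test suite.
#' The compact encoder shipped with this package uses learned absolute
#' position embeddings.
#'
#' @param hidden_size Token representation width; must be divisible by
#'   `n_heads`.
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads per block.
#' @param intermediate_size Feed-forward expansion width.
#' @param vocab_size Token vocabulary size (from the tokenizer).
#' @param max_positions Token slots including specials.
#' @param hidden_dropout_prob Dropout probability on the pooled
#'   representation in the classifier head.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(hidden_size = 384, n_layers = 6, n_heads = 6,
                           intermediate_size = 3072, vocab_size = 4101,
                           max_positions = 1024, hidden_dropout_prob = 0.1) {
  if (hidden_size %% n_heads != 0) {
    abort("`hidden_size` must be divisible by `n_heads`")
  }
  structure(
    list(
      hidden_size = as.integer(hidden_size),
      n_layers = as.integer(n_layers),
      n_heads = as.integer(n_heads),
      intermediate_size = as.integer(intermediate_size),
      vocab_size = as.integer(vocab_size),
      max_positions = as.integer(max_positions),
      hidden_dropout_prob = hidden_dropout_prob,
      activation = "gelu"
    ),
    class = "encoder_config"
  )
}

#' Named encoder + tokenizer presets
#'
#' `mini` (k = 6, shift = 1, 1024 positions, 1027 nt context), `mini_c`
#' (k = 1, 9-token vocabulary, 1022 nt context), `mini_long` (k = 6,
#' shift = 2, 2048 positions, 4096 nt context) — all 384-hidden, 6-layer,
#' 6-head — and `tiny_demo` (k = 6, shift = 1, 32-hidden, 2-layer, 2-head,
#' 128 positions) for CPU-scale experiments.
#'
#' @param preset One of `"mini"`, `"mini_c"`, `"mini_long"`, `"tiny_demo"`.
#' @return List with elements `encoder` ([encoder_config()]) and
#'   `tokenizer` ([lca_tokenizer()]).
#' @examples
#' cfg <- make_encoder_config("mini")
#' covered_nt(cfg$encoder$max_positions, cfg$tokenizer$k, cfg$tokenizer$shift)
#' @export
make_encoder_config <- function(preset = c("mini", "mini_c", "mini_long", "tiny_demo")) {
  preset <- match.arg(preset)
  switch(preset,
    mini = list(
      tokenizer = lca_tokenizer(k = 6, shift = 1, max_positions = 1024),
      encoder = encoder_config(vocab_size = 4101, max_positions = 1024)
    ),
    mini_c = list(
      tokenizer = lca_tokenizer(k = 1, shift = 1, max_positions = 1024),
      encoder = encoder_config(vocab_size = 9, max_positions = 1024)
    ),
    mini_long = list(
      tokenizer = lca_tokenizer(k = 6, shift = 2, max_positions = 2048),
      encoder = encoder_config(vocab_size = 4101, max_positions = 2048)
    ),
    tiny_demo = list(
      tokenizer = lca_tokenizer(k = 6, shift = 1, max_positions = 128),
      encoder = encoder_config(hidden_size = 32, n_layers = 2, n_heads = 2,
                               intermediate_size = 64, vocab_size = 4101,
                               max_positions = 128)
    )
  )
}

# ---------------------------------------------------------------------------
# Fixed pooling reductions and the weighted-pooling classification head
# ---------------------------------------------------------------------------

#' Pool token representations with a fixed reduction
#'
#' Mean, sum, per-dimension max or per-dimension min over the unmasked
#' positions of a sequence output `S`.
#'
#' @param S Numeric matrix `[T x hidden_size]` of token representations.
#' @param method One of `"mean"`, `"sum"`, `"max"`, `"min"`.
#' @param attention_mask Logical length-`T` vector; `FALSE` marks padding.
#' @return Numeric vector of length `hidden_size`.
#' @examples
#' pool_fixed(rbind(c(1, 2), c(3, 4)), "mean")
#' @export
pool_fixed <- function(S, method = c("mean", "sum", "max", "min"),
                       attention_mask = NULL) {
  method <- match.arg(method)
  S <- as.matrix(S)
  if (is.null(attention_mask)) attention_mask <- rep(TRUE, nrow(S))
  if (!any(attention_mask)) abort("all positions are masked: nothing to pool")
  S <- S[attention_mask, , drop = FALSE]
  switch(method,
    mean = colMeans(S),
    sum = colSums(S),
    max = apply(S, 2, max),
    min = apply(S, 2, min)
  )
}

#' Create weighted-pooling classifier head parameters
#'
#' The head scores each position with the linear map `W1 . s_i + b1`,
#' converts scores to a probability distribution over positions with a
#' softmax, pools `S` by the weighted sum, and maps the pooled vector to
#' two logits through an affine output map.
#'
#' @param hidden_size Representation width.
#' @param seed Optional seed for the random initialization.
#' @return An object of class `classifier_head`: `W1` (length-`hidden_size`
#'   vector), `b1` (scalar), `Wout` (`hidden_size x 2`), `bout` (length 2).
#' @export
classifier_head <- function(hidden_size, seed = NULL) {
  with_seed(seed, {
    sd0 <- 1 / sqrt(hidden_size)
    structure(
      list(
        W1 = stats::rnorm(hidden_size, sd = sd0),
        b1 = 0,
        Wout = matrix(stats::rnorm(hidden_size * 2, sd = sd0), hidden_size, 2),
        bout = c(0, 0)
      ),
      class = "classifier_head"
    )
  })
}

#' Position weights of the classification head
#'
#' `w = softmax(W1 S^T + b1)` over positions; padding positions are
#' excluded by a `-Inf` pre-softmax score, so the weights form a valid
#' probability distribution over the real positions.
#'
#' @param S Numeric matrix `[T x hidden_size]`.
#' @param head A [classifier_head()].
#' @param attention_mask Logical length-`T` vector; `FALSE` marks padding.
#' @return Numeric probability vector of length `T` (zeros at padding).
#' @export
attention_weights <- function(S, head, attention_mask = NULL) {
  S <- as.matrix(S)
  scores <- drop(S %*% head$W1) + head$b1
  if (!is.null(attention_mask)) scores[!attention_mask] <- -Inf
  softmax_vec(scores)
}

softmax_vec <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

#' Weighted sum of token representations
#'
#' `P = sum_i w_i s_i`. With uniform weights this equals mean pooling.
#'
#' @param S Numeric matrix `[T x hidden_size]`.
#' @param w Numeric weight vector of length `T` summing to 1.
#' @return Numeric vector of length `hidden_size`.
#' @export
weighted_pool <- function(S, w) {
  S <- as.matrix(S)
  if (length(w) != nrow(S)) abort("weight length must match the number of positions")
  drop(crossprod(S, w))
}

#' Classify a sequence output with the weighted-pooling head
#'
#' Computes `logits = output_map(dropout(weighted_pool(S, attention_weights(S))))`.
#' Dropout applies only during training; inference is deterministic.
#'
#' @inheritParams attention_weights
#' @param dropout_prob Dropout probability on the pooled vector.
#' @param training Apply dropout (TRUE) or the identity (FALSE).
#' @return Numeric vector of two logits.
#' @export
classify <- function(S, head, attention_mask = NULL, dropout_prob = 0,
                     training = FALSE) {
  w <- attention_weights(S, head, attention_mask)
  P <- weighted_pool(S, w)
  if (training && dropout_prob > 0) {
    keep <- stats::runif(length(P)) >= dropout_prob
    P <- P * keep / (1 - dropout_prob)
  }
  drop(crossprod(head$Wout, P)) + head$bout
}

# ---------------------------------------------------------------------------
# Compact transformer encoder: forward and manual backward, CPU scale
# ---------------------------------------------------------------------------

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)), xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

init_encoder_params <- function(config, seed = NULL) {
  h <- config$hidden_size
  V <- config$vocab_size
  I <- config$intermediate_size
  with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(
        Wq = rn(h, h), bq = numeric(h),
        Wk = rn(h, h), bk = numeric(h),
        Wv = rn(h, h), bv = numeric(h),
        Wo = rn(h, h), bo = numeric(h),
        ln1_g = rep(1, h), ln1_b = numeric(h),
        W1 = rn(h, I), b1 = numeric(I),
        W2 = rn(I, h), b2 = numeric(h),
        ln2_g = rep(1, h), ln2_b = numeric(h)
      )
    })
    list(
      emb = rn(V, h),
      pos = rn(config$max_positions, h),
      layers = layers
    )
  })
}

# Forward pass for one sequence of token ids (0-based). Returns the sequence
# output S and, when requested, a cache for the backward pass.
encoder_forward <- function(params, ids, config, attention_mask = NULL,
                            keep_cache = FALSE) {
  T_ <- length(ids)
  if (is.null(attention_mask)) attention_mask <- ids != PAD_ID
  nh <- config$n_heads
  hd <- config$hidden_size %/% nh
  scale <- 1 / sqrt(hd)
  att_bias <- ifelse(attention_mask, 0, -Inf)

  X <- params$emb[ids + 1L, , drop = FALSE] + params$pos[seq_len(T_), , drop = FALSE]
  cache <- list(ids = ids, attention_mask = attention_mask, layers = list())

  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    lc <- list(X_in = X)
    Q <- X %*% p$Wq + rep(p$bq, each = T_)
    K <- X %*% p$Wk + rep(p$bk, each = T_)
    V <- X %*% p$Wv + rep(p$bv, each = T_)
    O <- matrix(0, T_, config$hidden_size)
    lc$Q <- Q; lc$K <- K; lc$V <- V; lc$A <- vector("list", nh)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * hd + 1):(hh * hd)
      scores <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scale
      scores <- sweep(scores, 2, att_bias, `+`)
      A <- t(apply(scores, 1, softmax_vec))
      if (T_ == 1) A <- matrix(A, 1, 1)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      lc$A[[hh]] <- A
    }
    lc$O_pre <- O
    O <- O %*% p$Wo + rep(p$bo, each = T_)
    ln1 <- layernorm_fwd(X + O, p$ln1_g, p$ln1_b)
    lc$ln1 <- ln1
    X1 <- ln1$y
    H_pre <- X1 %*% p$W1 + rep(p$b1, each = T_)
    H <- gelu(H_pre)
    lc$X1 <- X1; lc$H_pre <- H_pre; lc$H <- H
    F2 <- H %*% p$W2 + rep(p$b2, each = T_)
    ln2 <- layernorm_fwd(X1 + F2, p$ln2_g, p$ln2_b)
    lc$ln2 <- ln2
    X <- ln2$y
    cache$layers[[l]] <- lc
  }
  list(S = X, cache = if (keep_cache) cache else NULL)
}

# Backward pass: dS is the gradient at the sequence output. Returns gradients
# in the same structure as params.
encoder_backward <- function(params, cache, dS, config) {
  T_ <- length(cache$ids)
  nh <- config$n_heads
  hd <- config$hidden_size %/% nh
  scale <- 1 / sqrt(hd)
  grads <- list(
    emb = matrix(0, nrow(params$emb), ncol(params$emb)),
    pos = matrix(0, nrow(params$pos), ncol(params$pos)),
    layers = vector("list", length(params$layers))
  )
  dX <- dS
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    lc <- cache$layers[[l]]
    g <- list()

    b2w <- layernorm_bwd(dX, lc$ln2, p$ln2_g)
    g$ln2_g <- b2w$dg; g$ln2_b <- b2w$db
    dres2 <- b2w$dx # gradient of (X1 + F2)
    dF2 <- dres2
    g$W2 <- crossprod(lc$H, dF2)
    g$b2 <- colSums(dF2)
    dH <- dF2 %*% t(p$W2)
    dH_pre <- dH * gelu_grad(lc$H_pre)
    g$W1 <- crossprod(lc$X1, dH_pre)
    g$b1 <- colSums(dH_pre)
    dX1 <- dres2 + dH_pre %*% t(p$W1)

    b1w <- layernorm_bwd(dX1, lc$ln1, p$ln1_g)
    g$ln1_g <- b1w$dg; g$ln1_b <- b1w$db
    dres1 <- b1w$dx # gradient of (X + O Wo + bo)
    g$Wo <- crossprod(lc$O_pre, dres1)
    g$bo <- colSums(dres1)
    dO <- dres1 %*% t(p$Wo)

    dQ <- matrix(0, T_, config$hidden_size)
    dK <- matrix(0, T_, config$hidden_size)
    dV <- matrix(0, T_, config$hidden_size)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * hd + 1):(hh * hd)
      A <- lc$A[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, lc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dscores <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dscores %*% lc$K[, cols, drop = FALSE] * scale
      dK[, cols] <- crossprod(dscores, lc$Q[, cols, drop = FALSE]) * scale
    }
    X_in <- lc$X_in
    g$Wq <- crossprod(X_in, dQ); g$bq <- colSums(dQ)
    g$Wk <- crossprod(X_in, dK); g$bk <- colSums(dK)
    g$Wv <- crossprod(X_in, dV); g$bv <- colSums(dV)
    dX <- dres1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    grads$layers[[l]] <- g
  }
  # embedding + position gradients
  ids1 <- cache$ids + 1L
  for (i in seq_len(T_)) {
    grads$emb[ids1[i], ] <- grads$emb[ids1[i], ] + dX[i, ]
  }
  grads$pos[seq_len(T_), ] <- grads$pos[seq_len(T_), , drop = FALSE] + dX
  grads
}
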