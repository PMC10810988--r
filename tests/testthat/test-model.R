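test_that("fixed pooling reductions follow their definitions", {
  S <- rbind(c(1, 2), c(3, 4))
  expect_equal(pool_fixed(S, "mean"), c(2, 3))
  expect_equal(pool_fixed(S, "sum"), c(4, 6))
  expect_equal(pool_fixed(rbind(c(1, 5), c(3, 2)), "max"), c(3, 5))
  expect_equal(pool_fixed(rbind(c(1, 5), c(3, 2)), "min"), c(1, 2))
  # single row: all four reductions coincide
  one <- matrix(c(7, -2), 1)
  for (m in c("mean", "sum", "max", "min")) {
    expect_equal(pool_fixed(one, m), c(7, -2))
  }
  # masked positions are excluded
  S3 <- rbind(c(1, 2), c(100, 100), c(3, 4))
  expect_equal(pool_fixed(S3, "mean", attention_mask = c(TRUE, FALSE, TRUE)), c(2, 3))
  expect_error(pool_fixed(S3, "mean", attention_mask = rep(FALSE, 3)), "masked")
})

test_that("attention weights are a shift-invariant probability distribution", {
  head <- structure(list(W1 = c(0, 0), b1 = 0,
                         Wout = diag(2), bout = c(0, 0)),
                    class = "classifier_head")
  S <- matrix(rnorm(8), 4, 2)
  w <- attention_weights(S, head)
  expect_equal(w, rep(0.25, 4)) # constant scores -> uniform
  expect_equal(attention_weights(S[1, , drop = FALSE], head), 1)
  # hand softmax: scores (0, log 3) -> weights (0.25, 0.75)
  head2 <- structure(list(W1 = c(1, 0), b1 = 0, Wout = diag(2), bout = c(0, 0)),
                     class = "classifier_head")
  S2 <- rbind(c(0, 5), c(log(3), 5))
  expect_equal(attention_weights(S2, head2), c(0.25, 0.75))
  # shift invariance: adding a constant score to all positions changes nothing
  head3 <- structure(list(W1 = c(1, 0), b1 = 17, Wout = diag(2), bout = c(0, 0)),
                     class = "classifier_head")
  expect_equal(attention_weights(S2, head3), c(0.25, 0.75))
  # padding excluded via -Inf
  w3 <- attention_weights(S, head, attention_mask = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(w3[3:4], c(0, 0))
  expect_equal(sum(w3), 1)
})

test_that("weighted pooling matches hand evaluation and reduces to the mean", {
  S <- rbind(c(0, 0), c(4, 8))
  expect_equal(weighted_pool(S, c(0.25, 0.75)), c(3, 6))
  expect_equal(weighted_pool(S, c(0, 1)), c(4, 8)) # one-hot selects a row
  withr::with_seed(81, {
    S2 <- matrix(rnorm(40), 8, 5)
    expect_equal(weighted_pool(S2, rep(1 / 8, 8)), pool_fixed(S2, "mean"))
  })
  expect_error(weighted_pool(S, c(1, 0, 0)), "length")
})

test_that("classify composes attention, pooling and the affine map; dropout off at inference", {
  withr::with_seed(82, {
    S <- matrix(rnorm(6), 3, 2)
    head <- structure(list(W1 = rnorm(2), b1 = 0.3,
                           Wout = matrix(rnorm(4), 2, 2), bout = c(0.1, -0.2)),
                      class = "classifier_head")
  })
  # manual composition oracle
  w <- attention_weights(S, head)
  P <- weighted_pool(S, w)
  expected <- drop(crossprod(head$Wout, P)) + head$bout
  expect_equal(classify(S, head), expected)
  expect_equal(classify(S, head), classify(S, head)) # deterministic off-training
  # zero output map: logits (0,0) whatever the input
  zero_head <- structure(list(W1 = c(1, 1), b1 = 0,
                              Wout = matrix(0, 2, 2), bout = c(0, 0)),
                         class = "classifier_head")
  expect_equal(classify(S, zero_head), c(0, 0))
})

test_that("presets reproduce the model-family arithmetic", {
  mini <- make_encoder_config("mini")
  expect_equal(covered_nt(mini$encoder$max_positions, mini$tokenizer$k,
                          mini$tokenizer$shift), 1027L)
  expect_equal(mini$encoder$hidden_size, 384L)
  expect_equal(mini$encoder$intermediate_size, 3072L)
  expect_equal(mini$tokenizer$vocab_size, 4101L)
  mini_c <- make_encoder_config("mini_c")
  expect_equal(mini_c$tokenizer$vocab_size, 9L)
  expect_equal(covered_nt(mini_c$encoder$max_positions, 1, 1), 1022L)
  mini_long <- make_encoder_config("mini_long")
  expect_equal(covered_nt(mini_long$encoder$max_positions, 6, 2), 4096L)
  tiny <- make_encoder_config("tiny_demo")
  expect_equal(tiny$encoder$hidden_size %% tiny$encoder$n_heads, 0L)
  expect_error(make_encoder_config("huge"))
  expect_error(encoder_config(hidden_size = 10, n_heads = 3), "divisible")
})

test_that("encoder backward agrees with finite differences", {
  cfg <- dnalm:::encoder_config(hidden_size = 8, n_layers = 2, n_heads = 2,
                                intermediate_size = 16, vocab_size = 21,
                                max_positions = 16)
  withr::with_seed(83, {
    params <- list(
      encoder = dnalm:::init_encoder_params(cfg),
      head = list(W1 = rnorm(8, sd = 0.3), b1 = 0,
                  Wout = matrix(rnorm(16, sd = 0.3), 8, 2), bout = c(0, 0))
    )
    ids <- c(2L, sample(5:20, 6, replace = TRUE), 3L)
  })
  r <- dnalm:::classifier_fwd_bwd(params, ids, 1L, cfg, dropout_prob = 0)
  eps <- 1e-5
  probe <- list(
    list(list("encoder", "layers", 1L, "Wq"), 5L),
    list(list("encoder", "layers", 2L, "W2"), 9L),
    list(list("encoder", "layers", 1L, "ln2_g"), 3L),
    list(list("encoder", "emb"), as.integer(ids[2] + 1L)),
    list(list("encoder", "pos"), 2L),
    list(list("head", "W1"), 4L),
    list(list("head", "Wout"), 6L)
  )
  get_leaf <- function(x, path) Reduce(`[[`, as.list(path), x)
  for (pr in probe) {
    path <- pr[[1]]; idx <- pr[[2]]
    leaf <- get_leaf(params, path)
    leaf[idx] <- leaf[idx] + eps
    p2 <- purrr::assign_in(params, as.list(path), leaf)
    num <- (dnalm:::classifier_fwd_bwd(p2, ids, 1L, cfg, 0)$loss - r$loss) / eps
    ana <- get_leaf(r$grads, path)[idx]
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("classification logits are invariant to trailing padding", {
  cfg <- make_encoder_config("tiny_demo")
  withr::with_seed(84, {
    params <- dnalm:::init_encoder_params(cfg$encoder)
  })
  s <- dnalm:::random_dna(40)
  ids <- encode_segment(s, cfg$tokenizer)$ids
  ids_padded <- c(ids, rep(0L, 10))
  head <- classifier_head(cfg$encoder$hidden_size, seed = 85)
  S1 <- dnalm:::encoder_forward(params, ids, cfg$encoder)$S
  S2 <- dnalm:::encoder_forward(params, ids_padded, cfg$encoder)$S
  real <- seq_along(ids)
  expect_equal(S1, S2[real, ], tolerance = 1e-10)
  l1 <- classify(S1, head)
  l2 <- classify(S2, head, attention_mask = c(rep(TRUE, length(ids)), rep(FALSE, 10)))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("AdamW recorded defaults match the documented settings", {
  opt <- adamw_defaults()
  expect_equal(opt$beta1, 0.95)
  expect_equal(opt$beta2, 0.98)
  expect_equal(opt$eps, 5e-5)
  expect_equal(opt$weight_decay, 0.01)
})
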