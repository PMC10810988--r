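test_that("mask expansion matches brute-force window intersection", {
  brute <- function(masked_nt, k, shift, n_tokens) {
    hit <- logical(n_tokens)
    for (j in seq_len(n_tokens)) {
      win <- ((j - 1) * shift + 1):((j - 1) * shift + k)
      hit[j] <- any(win %in% masked_nt)
    }
    which(hit)
  }
  # interior single nucleotide, k = 6 shift = 1: six tokens
  expect_equal(expand_mask_to_overlaps(7, 6, 1, 13), 2:7)
  # left edge masks only the first token
  expect_equal(expand_mask_to_overlaps(1, 6, 1, 13), 1L)
  # 2 nt span masks k + span - 1 = 7 tokens
  expect_equal(expand_mask_to_overlaps(c(7, 8), 6, 1, 13), 2:8)
  withr::with_seed(21, {
    for (trial in 1:50) {
      k <- sample(1:6, 1)
      shift <- sample(1:k, 1)
      n_tokens <- sample(5:30, 1)
      n_nt <- k + (n_tokens - 1) * shift
      masked_nt <- sample.int(n_nt, sample(1:4, 1))
      expect_equal(expand_mask_to_overlaps(masked_nt, k, shift, n_tokens),
                   brute(masked_nt, k, shift, n_tokens))
    }
  })
})

test_that("no-leak audit: every token overlapping a hidden nucleotide is masked", {
  configs <- list(c(6, 1), c(6, 2), c(1, 1))
  withr::with_seed(22, {
    for (cfg in configs) {
      k <- cfg[1]; shift <- cfg[2]
      tok <- lca_tokenizer(k, shift, max_positions = 600)
      mc <- masking_config(seed = NULL)
      for (trial in 1:20) {
        s <- dnalm:::random_dna(sample(60:400, 1))
        seg <- encode_segment(s, tok)
        batch <- make_mlm_batch(list(seg), mc)
        masked_tok <- which(batch$mask[1, ]) - 1L # k-mer index
        hidden_nt <- batch$hidden_nt[[1]]
        if (length(hidden_nt) == 0) next
        # the masked set is exactly the overlap closure of the hidden
        # nucleotides: no unmasked token touches a hidden position, and no
        # token is masked without reason
        closure <- expand_mask_to_overlaps(hidden_nt, k, shift, length(seg$tokens))
        expect_equal(masked_tok, closure)
        # an interior hidden nucleotide masks at least k/shift tokens (6 for
        # k = 6, shift = 1)
        if (k == 6 && shift == 1) {
          interior <- hidden_nt[hidden_nt > k & hidden_nt <= seg$n_covered_nt - k]
          for (p in interior) {
            expect_gte(sum(masked_tok %in% ((p - k + 1):p)), 6)
          }
        }
      }
    }
  })
})

test_that("specials are never masked and labels sit exactly under the mask", {
  tok <- lca_tokenizer(6, 1, max_positions = 200)
  segs <- lapply(random_seqs(32, 150, seed = 23), encode_segment, tokenizer = tok)
  batch <- make_mlm_batch(segs, masking_config(seed = 9))
  n_pos <- length(segs[[1]]$ids)
  expect_false(any(batch$mask[, 1]))
  expect_false(any(batch$mask[, n_pos]))
  expect_equal(!is.na(batch$labels), batch$mask)
  # labels store original ids: where kept (p3) input equals label
  expect_true(all(batch$labels[batch$mask] >= 5))
  # determinism under the config seed
  batch2 <- make_mlm_batch(segs, masking_config(seed = 9))
  expect_identical(batch, batch2)
  # mixed tokenizer configs refuse
  seg1 <- encode_segment("ACGTACGTACGT", lca_tokenizer(6, 1))
  seg2 <- encode_segment("ACGTACGTACGT", lca_tokenizer(6, 2))
  expect_error(make_mlm_batch(list(seg1, seg2), masking_config()), "share")
})

test_that("empirical masked-token fraction hits the 15% target within 1% at 1e6 tokens", {
  tok <- lca_tokenizer(6, 1, max_positions = 5010)
  mc <- masking_config(target_mask_fraction = 0.15, span_nt = 2, seed = 24)
  seqs <- random_seqs(100, 5000, seed = 25) # ~4995 tokens each
  segs <- lapply(seqs, encode_segment, tokenizer = tok)
  n_tok <- 0; n_masked <- 0
  withr::with_seed(26, {
    batch <- make_mlm_batch(segs, masking_config(target_mask_fraction = 0.15,
                                                 span_nt = 2, seed = NULL))
    kmer_cols <- 2:(ncol(batch$mask) - 1)
    n_masked <- sum(batch$mask)
    n_tok <- sum(vapply(segs, function(s) length(s$tokens), integer(1)))
  })
  expect_gt(n_tok, 4e5)
  frac <- n_masked / n_tok
  expect_gt(frac, 0.14)
  expect_lt(frac, 0.16)
})

test_that("noise proportions follow p1/p2/p3 within 1% at 1e5 masked tokens", {
  ids <- rep(100L, 1.2e5)
  masked <- seq_along(ids)
  mc <- masking_config(p1 = 0.8, p2 = 0.1, p3 = 0.1)
  withr::with_seed(27, {
    out <- apply_noise(ids, masked, mc, vocab_size = 4101)
  })
  p_mask <- mean(out == 4L)
  p_keep <- mean(out == 100L)
  p_rand <- 1 - p_mask - p_keep
  expect_lt(abs(p_mask - 0.8), 0.01)
  # random draws can collide with the original id; correction term is ~1/4096
  expect_lt(abs(p_rand - 0.1), 0.011)
  expect_lt(abs(p_keep - 0.1), 0.011)
  expect_true(all(out >= 4))
  # degenerate settings
  out1 <- apply_noise(ids[1:100], 1:100, masking_config(p1 = 1, p2 = 0, p3 = 0), 4101)
  expect_true(all(out1 == 4L))
  out3 <- apply_noise(ids[1:100], 1:100, masking_config(p1 = 0, p2 = 0, p3 = 1), 4101)
  expect_equal(out3, ids[1:100])
})

test_that("legacy phase-1 style configs (wide span, p1 = 0.9) are accepted", {
  mc <- masking_config(target_mask_fraction = 0.15, span_nt = 5, p1 = 0.9,
                       p2 = 0.05, p3 = 0.05, seed = 1)
  tok <- lca_tokenizer(6, 1, max_positions = 140)
  segs <- lapply(random_seqs(4, 128, seed = 28), encode_segment, tokenizer = tok)
  batch <- make_mlm_batch(segs, mc)
  expect_true(sum(batch$mask) > 0)
})

test_that("masked-token loss matches the hand-evaluated negative log likelihood", {
  # one-hot correct predictions: loss 0
  probs <- diag(4)
  ll <- mlm_loss(probs, labels = 0:3)
  expect_equal(ll$sum, 0)
  # uniform over V: sum is n * log(V)
  V <- 4101
  probs_u <- matrix(1 / V, nrow = 10, ncol = V)
  llu <- mlm_loss(probs_u, labels = rep(7L, 10))
  expect_equal(llu$sum, 10 * log(V))
  # hand-evaluated two-position case
  p <- matrix(0.05, nrow = 2, ncol = 8)
  p[1, 3] <- 0.5; p[1, -3] <- 0.5 / 7
  p[2, 5] <- 0.25; p[2, -5] <- 0.75 / 7
  ll2 <- mlm_loss(p, labels = c(2L, 4L))
  expect_equal(ll2$sum, -(log(0.5) + log(0.25)))
  expect_equal(ll2$mean, -(log(0.5) + log(0.25)) / 2)
  # oracle equivalence with an independent cross-entropy-with-ignore loop
  withr::with_seed(29, {
    n <- 50; V2 <- 30
    pr <- matrix(stats::rexp(n * V2), n, V2)
    pr <- pr / rowSums(pr)
    labs <- sample(0:(V2 - 1), n, replace = TRUE)
    mask <- sample(c(TRUE, FALSE), n, replace = TRUE)
    labs_na <- ifelse(mask, labs, NA_integer_)
    oracle <- 0
    for (i in seq_len(n)) {
      if (mask[i]) oracle <- oracle - log(pr[i, labs[i] + 1])
    }
    expect_equal(mlm_loss(pr, labs_na)$sum, oracle)
  })
})
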