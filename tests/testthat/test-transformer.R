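test_that("temporal encoding matches the scalar oracle and stays in [-1,1]", {
  expect_equal(temporal_encode(0, 6), c(1, 0, 1, 0, 1, 0))
  # divisors at M = 2 are 10000^0 (j=1) and 10000^1 (j=2)
  expect_equal(temporal_encode(10000, 2), c(cos(10000), sin(1)))
  set.seed(21)
  for (i in 1:50) {
    t <- runif(1, 0, 500)
    M <- sample(1:24, 1)
    expect_equal(as.vector(temporal_encode(t, M)),
                 temporal_encode_oracle(t, M), tolerance = 1e-12)
  }
  z <- temporal_encode(runif(40, 0, 1e4), 16, drop = FALSE)
  expect_true(all(z >= -1 & z <= 1))
})

test_that("embed_sequence adds code embedding and temporal encoding", {
  st <- tiny_state()
  M <- st$config$d_model
  # all times zero: rows are U column + the constant encoding of t = 0
  X <- embed_sequence(c(1L, 3L), c(0, 0), st)
  expect_equal(X[1, ], st$params$U[, 1] + temporal_encode(0, M))
  # same code, different times: rows differ by z(t1) - z(t2) exactly
  X2 <- embed_sequence(c(2L, 2L), c(1.5, 4), st)
  expect_equal(X2[1, ] - X2[2, ],
               temporal_encode(1.5, M) - temporal_encode(4, M))
  # elementwise oracle on a random batch
  set.seed(5)
  ids <- sample(1:5, 4, TRUE); times <- cumsum(runif(4))
  X3 <- embed_sequence(ids, times, st)
  for (i in seq_along(ids)) {
    for (j in seq_len(M)) {
      expect_equal(X3[i, j],
                   st$params$U[j, ids[i]] + temporal_encode_oracle(
                     times[i], M)[j], tolerance = 1e-9)
    }
  }
  expect_error(embed_sequence(99L, 0, st), "out of range")
})

test_that("causal mask marks exactly the strict upper triangle", {
  expect_false(any(causal_mask(1)))
  m3 <- causal_mask(3)
  expect_equal(which(m3), which(upper.tri(m3)))
  expect_equal(sum(m3), 3L)  # {(1,2),(1,3),(2,3)}
})

test_that("masked attention rows are causal probability vectors", {
  st <- tiny_state()
  set.seed(8)
  L <- 5
  X <- matrix(rnorm(L * st$config$d_model), L)
  res <- masked_attention_layer(X, st, layer = 1)
  for (A in res$attention) {
    expect_equal(rowSums(A), rep(1, L), tolerance = 1e-12)
    expect_true(all(A[upper.tri(A)] == 0))
    expect_equal(A[1, ], c(1, rep(0, L - 1)))  # row 1 sees only itself
  }
})

test_that("single-head attention equals a per-row softmax loop oracle", {
  cf <- transformer_config(K = 4, n_layers = 1, n_heads = 1, d_model = 6,
                           d_qk = 3, d_ff = 8, max_len = 6, seed = 2)
  st <- tiny_state(cf)
  set.seed(9)
  L <- 4
  X <- matrix(rnorm(L * 6), L)
  res <- masked_attention_layer(X, st, layer = 1)
  Q <- X %*% st$params$Wq1; K <- X %*% st$params$Wk1
  V <- X %*% st$params$Wv1
  S_oracle <- matrix(0, L, 6)
  for (i in seq_len(L)) {
    e <- sapply(seq_len(i), function(j) sum(Q[i, ] * K[j, ]) / sqrt(3))
    a <- exp(e - max(e)); a <- a / sum(a)
    S_oracle[i, ] <- colSums(V[seq_len(i), , drop = FALSE] * a)
  }
  expect_equal(res$S, S_oracle, tolerance = 1e-6)
})

test_that("feed_forward matches its closed form", {
  st <- tiny_state()
  cf <- st$config
  set.seed(10)
  S <- matrix(rnorm(3 * cf$d_model), 3)
  # zero first layer: every row collapses to b2
  st0 <- st
  st0$params$W11 <- st0$params$W11 * 0
  st0$params$b11 <- st0$params$b11 * 0
  H0 <- feed_forward(S, st0, layer = 1)
  for (i in 1:3) expect_equal(H0[i, ], st0$params$b21)
  # row-wise oracle
  H <- feed_forward(S, st, layer = 1)
  for (i in 1:3) {
    z <- as.vector(S[i, ] %*% st$params$W11) + st$params$b11
    expect_equal(H[i, ],
                 as.vector(pmax(z, 0) %*% st$params$W21) + st$params$b21,
                 tolerance = 1e-9)
  }
})

test_that("forward is future-blind and composes attention with FFN", {
  vocab <- toy_vocab(5)
  for (residual in c(FALSE, TRUE)) {
    st <- tiny_state(tiny_config(use_residual = residual))
    seq5 <- random_sequence(vocab, 5, seed = 31)
    H <- transformer_forward(seq5, st, vocab)$H
    # editing events after position i leaves rows 1..i unchanged
    seq_mut <- seq5
    seq_mut$codes[4:5] <- rev(seq_mut$codes[4:5])
    seq_mut$times[4:5] <- seq_mut$times[4:5] + 10
    H_mut <- transformer_forward(seq_mut, st, vocab)$H
    expect_equal(H_mut[1:3, ], H[1:3, ], tolerance = 1e-6)
    # truncating after position i reproduces rows 1..i
    seq_tr <- seq5
    seq_tr$codes <- seq_tr$codes[1:3]; seq_tr$times <- seq_tr$times[1:3]
    H_tr <- transformer_forward(seq_tr, st, vocab)$H
    expect_equal(H_tr[1:3, ], H[1:3, ], tolerance = 1e-6)
  }
  # one-layer model equals masked_attention_layer followed by feed_forward
  cf1 <- transformer_config(K = 5, n_layers = 1, n_heads = 2, d_model = 8,
                            d_qk = 4, d_ff = 10, max_len = 6, seed = 3)
  st1 <- tiny_state(cf1)
  seq4 <- random_sequence(toy_vocab(5), 4, seed = 7)
  cp <- clip_pad(seq4, vocab, 6)
  fw <- transformer_forward(seq4, st1, vocab)
  X <- embed_sequence(cp$ids, cp$times, st1)
  S <- masked_attention_layer(X, st1, layer = 1, valid = cp$mask)$S
  expect_equal(fw$H[1:4, ], feed_forward(S, st1, layer = 1)[1:4, ],
               tolerance = 1e-9)
})

test_that("predict_next emits probability rows and argmax labels", {
  st <- tiny_state()
  set.seed(12)
  H <- matrix(rnorm(4 * st$config$d_model), 4)
  pr <- predict_next(H, st)
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-12)
  # brute-force argmax over the logits
  logits <- H %*% st$params$W_event
  for (i in 1:4) expect_equal(pr$labels[i], which.max(logits[i, ]))
  st0 <- st; st0$params$W_event <- st0$params$W_event * 0
  V <- ncol(st$params$W_event)
  expect_equal(predict_next(H, st0)$probs,
               matrix(1 / V, 4, V), tolerance = 1e-12)
  expect_equal(pr$t_hat, as.vector(H %*% st$params$w_time))
})

test_that("losses match their loop oracles", {
  expect_equal(loss_time(c(0, 1), t_hat = 3), 4)     # single squared error
  set.seed(13)
  times <- cumsum(runif(6)); t_hat <- rnorm(5)
  expect_equal(loss_time(times, t_hat),
               sum(sapply(2:6, function(i) (times[i] - t_hat[i - 1])^2)))
  expect_equal(loss_time(times, times[2:6]), 0)
  expect_error(loss_time(times[1], numeric(0)), ">= 2")

  K <- 4
  probs <- matrix(1 / K, 3, K)
  expect_equal(loss_event(c(1L, 3L, 2L), probs), 3 * log(K))
  perfect <- diag(K)[c(2, 4, 1), ]
  expect_equal(loss_event(c(2L, 4L, 1L), perfect), 0)
  set.seed(14)
  P <- softmax_rows <- exp(matrix(rnorm(12), 3)); P <- P / rowSums(P)
  tg <- c(2L, 1L, 4L)
  expect_equal(loss_event(tg, P),
               -sum(sapply(1:3, function(i) log(P[i, tg[i]]))))
})

test_that("total_loss is the weighted sum over sequences", {
  vocab <- toy_vocab(5)
  st <- tiny_state(tiny_config(alpha_time = 1, alpha_event = 1))
  seqs <- list(random_sequence(vocab, 4, seed = 41, id = "A"),
               random_sequence(vocab, 3, seed = 42, id = "B"))
  tl <- total_loss(seqs, st, vocab)
  # oracle: per-sequence forward + per-position losses
  oracle <- 0
  for (s in seqs) {
    fw <- transformer_forward(s, st, vocab)
    L <- length(s$codes)
    pr <- predict_next(fw$H, st)
    ids <- encode_codes(vocab, s$codes)
    oracle <- oracle + loss_time(s$times, pr$t_hat[1:(L - 1)]) +
      loss_event(ids[2:L], pr$probs[1:(L - 1), , drop = FALSE])
  }
  expect_equal(tl$loss, oracle, tolerance = 1e-8)
  expect_gte(tl$loss, 0)
  # alpha_time = 0 drops the time term
  st0 <- tiny_state(tiny_config(alpha_time = 0))
  tl0 <- total_loss(seqs, st0, vocab)
  expect_equal(tl0$loss, tl0$loss_event)
})

test_that("analytic gradients match central finite differences", {
  for (residual in c(FALSE, TRUE)) {
    # sd 0.25: large enough to clear ReLU kinks at the finite-difference
    # step, small enough that no softmax probability hits the 1e-12 floor
    st <- tiny_state(tiny_config(use_residual = residual), sd = 0.25,
                     seed = 55)
    set.seed(56)
    batch <- list(
      ids = rbind(c(1L, 2L, 3L, 4L, 5L, 0L), c(2L, 2L, 1L, 0L, 0L, 0L)),
      times = matrix(cumsum(runif(12)), 2, 6),
      mask = rbind(c(rep(TRUE, 5), FALSE), c(rep(TRUE, 3), rep(FALSE, 3))))
    res <- midrp:::mct_loss_and_grads(batch, st)
    th0 <- midrp:::flatten_params(st$params)
    gan <- midrp:::flatten_params(res$grads[names(st$params)])
    loss_fn <- function(th) {
      st2 <- st
      st2$params <- midrp:::unflatten_params(th, st$params)
      midrp:::mct_loss_and_grads(batch, st2, want_grads = FALSE)$loss
    }
    idx <- sort(sample(length(th0), 60))
    eps <- 1e-5
    gnum <- vapply(idx, function(i) {
      tp <- th0; tp[i] <- tp[i] + eps; fp <- loss_fn(tp)
      tp[i] <- th0[i] - eps; fm <- loss_fn(tp)
      (fp - fm) / (2 * eps)
    }, numeric(1))
    expect_equal(gnum, gan[idx], tolerance = 1e-5)
  }
})

test_that("pretraining reduces loss, learns a Markov chain, and is seeded", {
  sim <- simulate_event_sequences(400, codes = synthetic_codes(8),
                                  len_range = c(3L, 10L), seed = 61)
  vocab <- build_vocabulary(sim$sequences)
  cf <- transformer_config(K = vocab$K, n_layers = 2, n_heads = 2,
                           d_model = 16, d_qk = 8, d_ff = 32, max_len = 10,
                           epochs = 6, batch_size = 64, lr = 3e-3,
                           use_residual = TRUE, seed = 5)
  st <- pretrain_transformer(sim$sequences$sequences, vocab, cf)
  traj <- st$trajectory
  expect_lte(traj$loss[nrow(traj)], traj$loss[1])
  # beats the marginal-frequency baseline computed from the generator
  codes_all <- unlist(lapply(sim$sequences$sequences, `[[`, "codes"))
  marginal_baseline <- max(table(codes_all)) / length(codes_all)
  acc <- next_event_accuracy(sim$sequences$sequences, st, vocab)
  expect_gt(acc, marginal_baseline)
  # identical rerun under the same seed
  st2 <- pretrain_transformer(sim$sequences$sequences, vocab, cf)
  expect_identical(st$trajectory$loss, st2$trajectory$loss)
  expect_equal(st$params, st2$params, tolerance = 0)
})

test_that("representation extraction follows the case/control rules", {
  vocab <- toy_vocab(5)
  st <- tiny_state()
  target <- vocab$id2code[2]
  # case with target first: zero vector
  s1 <- structure(list(sample_id = "C1",
                       codes = c(target, vocab$id2code[c(1, 3)]),
                       times = c(0, 1, 2)), class = "event_sequence")
  expect_equal(extract_representation(s1, target, TRUE, st, vocab),
               numeric(st$config$d_model))
  # case with target at position 3: hidden row 2, leak-free
  s2 <- structure(list(sample_id = "C2",
                       codes = c(vocab$id2code[c(1, 3)], target,
                                 vocab$id2code[4]),
                       times = c(0, 1, 2, 3)), class = "event_sequence")
  v <- extract_representation(s2, target, TRUE, st, vocab)
  expect_equal(v, transformer_forward(s2, st, vocab)$H[2, ])
  s2_cut <- s2
  s2_cut$codes <- s2_cut$codes[1:2]; s2_cut$times <- s2_cut$times[1:2]
  expect_equal(v, transformer_forward(s2_cut, st, vocab)$H[2, ],
               tolerance = 1e-6)
  # control: last valid row
  s3 <- random_sequence(vocab, 4, seed = 77, id = "K1")
  s3$codes[s3$codes == target] <- vocab$id2code[1]
  expect_equal(extract_representation(s3, target, FALSE, st, vocab),
               transformer_forward(s3, st, vocab)$H[4, ])
  expect_error(extract_representation(s3, target, TRUE, st, vocab),
               "no .* diagnosis")
  expect_error(extract_representation(s2, target, FALSE, st, vocab),
               "carries")
})

test_that("attention export matches a recomputed forward pass", {
  vocab <- toy_vocab(5)
  st <- tiny_state()
  s <- random_sequence(vocab, 4, seed = 81)
  out <- export_attention(s, st, vocab)
  expect_length(out, st$config$n_layers)
  expect_length(out[[1]], st$config$n_heads)
  X <- embed_sequence(encode_codes(vocab, s$codes), s$times, st)
  ref <- masked_attention_layer(X, st, layer = 1)$attention
  for (h in seq_along(ref)) {
    A <- out[[1]][[h]]
    expect_equal(unname(A), ref[[h]][1:4, 1:4], tolerance = 1e-9)
    expect_true(all(A[upper.tri(A)] == 0))
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(rownames(A), s$codes)
  }
  # written files round-trip
  dir <- withr::local_tempdir()
  export_attention(s, st, vocab, path = dir)
  f <- file.path(dir, "attention_layer1_head1.tsv")
  expect_true(file.exists(f))
  back <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(out[[1]][[1]]), tolerance = 1e-6)
})

test_that("checkpoints round-trip through JSON", {
  vocab <- toy_vocab(4)
  cf <- transformer_config(K = vocab$K, n_layers = 1, n_heads = 2,
                           d_model = 8, d_qk = 4, d_ff = 10, max_len = 5,
                           seed = 2)
  st <- tiny_state(cf)
  path <- withr::local_tempfile(fileext = ".json")
  save_transformer(st, vocab, path)
  ck <- load_transformer(path)
  expect_equal(ck$state$params, st$params, tolerance = 1e-12)
  expect_equal(ck$vocab$code2id, vocab$code2id)
  s <- random_sequence(vocab, 4, seed = 9)
  expect_equal(transformer_forward(s, ck$state, ck$vocab)$H,
               transformer_forward(s, st, vocab)$H, tolerance = 1e-12)
})
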