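## Causally masked Transformer over timestamped diagnosis sequences.
##
## The model embeds each event as (learned code embedding + sinusoidal
## temporal encoding), applies n blocks of masked multi-head self-attention
## followed by a position-wise feed-forward network, and predicts the next
## event type (softmax over the vocabulary) and the next event time (linear
## head) from each position. By default the blocks follow the printed
## attention/FFN composition with no residual connections or layer norm;
## `use_residual = TRUE` switches to standard post-norm residual blocks.
## Forward and reverse-mode gradients are implemented by hand on BLAS-backed
## matrix ops; batches are processed jointly via a block-diagonal attention
## mask so padded and foreign positions receive exactly zero weight.

#' Transformer hyperparameter configuration
#'
#' @param K vocabulary size (number of distinct diagnosis codes; an extra
#'   unknown slot is allocated internally).
#' @param n_layers number of attention blocks (default 4).
#' @param n_heads attention heads per block (default 4).
#' @param d_model embedding / hidden width M (default 128).
#' @param d_qk per-head query/key width (default 128).
#' @param d_ff feed-forward inner width (default 256).
#' @param max_len model sequence length; longer histories keep the most
#'   recent \code{max_len} events.
#' @param alpha_event,alpha_time non-negative weights of the next-event
#'   cross-entropy and next-time squared-error losses.
#' @param use_residual logical; enable residual + layer-norm blocks.
#' @param lr,epochs,batch_size Adam learning rate, training epochs and
#'   minibatch size for \code{\link{pretrain_transformer}}.
#' @param seed integer RNG seed controlling initialization and batching.
#' @return list of class \code{transformer_config}.
#' @export
transformer_config <- function(K, n_layers = 4L, n_heads = 4L,
                               d_model = 128L, d_qk = 128L, d_ff = 256L,
                               max_len = 32L, alpha_event = 1,
                               alpha_time = 0.01, use_residual = FALSE,
                               lr = 1e-3, epochs = 10L, batch_size = 64L,
                               seed = 1L) {
  if (d_model %% n_heads != 0L) {
    stop_midrp("d_model (%d) must be divisible by n_heads (%d)",
               d_model, n_heads)
  }
  if (max_len < 2L) stop_midrp("max_len must be >= 2")
  if (alpha_event < 0 || alpha_time < 0) {
    stop_midrp("loss weights must be non-negative")
  }
  structure(list(K = as.integer(K), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_model = as.integer(d_model),
                 d_qk = as.integer(d_qk), d_v = as.integer(d_model / n_heads),
                 d_ff = as.integer(d_ff), max_len = as.integer(max_len),
                 alpha_event = alpha_event, alpha_time = alpha_time,
                 use_residual = isTRUE(use_residual),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "transformer_config")
}

## Number of embedding/logit columns: K codes + 1 unknown slot.
vocab_cols <- function(config) config$K + 1L

#' Initialize transformer weights
#'
#' Gaussian init (sd 0.02) for weight matrices, zeros for biases; seeded.
#' @param config a \code{transformer_config}.
#' @return list of class \code{transformer_state} holding \code{params} and
#'   the \code{config}.
#' @export
init_transformer <- function(config) {
  set.seed(config$seed)
  M <- config$d_model; H <- config$n_heads
  V <- vocab_cols(config)
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  params <- list(U = rmat(M, V))
  for (l in seq_len(config$n_layers)) {
    params[[paste0("Wq", l)]] <- rmat(M, H * config$d_qk)
    params[[paste0("Wk", l)]] <- rmat(M, H * config$d_qk)
    params[[paste0("Wv", l)]] <- rmat(M, H * config$d_v)
    params[[paste0("W1", l)]] <- rmat(M, config$d_ff)
    params[[paste0("b1", l)]] <- numeric(config$d_ff)
    params[[paste0("W2", l)]] <- rmat(config$d_ff, M)
    params[[paste0("b2", l)]] <- numeric(M)
    if (config$use_residual) {
      params[[paste0("g1", l)]] <- rep(1, M)
      params[[paste0("be1", l)]] <- numeric(M)
      params[[paste0("g2", l)]] <- rep(1, M)
      params[[paste0("be2", l)]] <- numeric(M)
    }
  }
  params$w_time <- numeric(M)
  params$W_event <- rmat(M, V)
  structure(list(params = params, config = config),
            class = "transformer_state")
}

#' Sinusoidal temporal encoding
#'
#' Component j (1-based) of the encoding of time t is
#' \code{cos(t / 10000^((j-1)/M))} for odd j and \code{sin(t / 10000^(j/M))}
#' for even j, replacing the usual positional encoding with a function of the
#' continuous event time.
#'
#' @param t numeric vector of times.
#' @param M encoding dimension.
#' @return length(t) x M matrix (a plain vector if t is scalar and
#'   \code{drop = TRUE}).
#' @param drop return a vector for scalar t.
#' @export
temporal_encode <- function(t, M, drop = TRUE) {
  j <- seq_len(M)
  expo <- ifelse(j %% 2L == 1L, (j - 1) / M, j / M)
  scaled <- outer(t, 10000^expo, `/`)
  odd <- j %% 2L == 1L
  z <- matrix(0, length(t), M)
  z[, odd] <- cos(scaled[, odd, drop = FALSE])
  z[, !odd] <- sin(scaled[, !odd, drop = FALSE])
  if (drop && length(t) == 1L) z <- drop(z)
  z
}

#' Embed a tokenized sequence
#'
#' Row i of the result is the code embedding U[, id_i] plus the temporal
#' encoding z(t_i). Padded positions (id 0) carry only the temporal encoding
#' of time 0 and are masked downstream.
#'
#' @param ids integer token ids (0 = pad).
#' @param times numeric event times, same length.
#' @param state a \code{transformer_state}.
#' @return L x M embedding matrix.
#' @export
embed_sequence <- function(ids, times, state) {
  if (length(ids) != length(times)) stop_midrp("ids/times length mismatch")
  V <- ncol(state$params$U)
  if (any(ids < 0L | ids > V)) stop_midrp("token id out of range [0, %d]", V)
  M <- state$config$d_model
  X <- matrix(0, length(ids), M)
  nz <- ids > 0L
  if (any(nz)) X[nz, ] <- t(state$params$U[, ids[nz], drop = FALSE])
  X + temporal_encode(times, M, drop = FALSE)
}

#' Strictly causal attention mask
#'
#' @param L sequence length.
#' @return L x L logical matrix; TRUE marks a masked (future) position, i.e.
#'   entry (i, j) is TRUE iff j > i.
#' @export
causal_mask <- function(L) {
  m <- matrix(FALSE, L, L)
  m[upper.tri(m)] <- TRUE
  m
}

## Block-diagonal allowed-attention matrix for a padded batch:
## position (b, i) may attend to (b, j) iff j <= i and j is a real event.
batch_allowed <- function(mask) {
  B <- nrow(mask); L <- ncol(mask)
  lt <- !causal_mask(L)
  allowed <- kronecker(diag(B), lt) > 0
  allowed[, !as.vector(t(mask))] <- FALSE
  allowed
}

## Multi-head masked attention on stacked rows X (n x M).
## Returns S (n x M, concatenated head outputs) and per-head caches.
attention_forward <- function(X, Wq, Wk, Wv, H, d_qk, d_v, allowed,
                              keep_attn = FALSE) {
  Q <- X %*% Wq; K <- X %*% Wk; Vv <- X %*% Wv
  n <- nrow(X)
  S <- matrix(0, n, H * d_v)
  A_list <- vector("list", H)
  for (h in seq_len(H)) {
    qc <- ((h - 1L) * d_qk + 1L):(h * d_qk)
    vc <- ((h - 1L) * d_v + 1L):(h * d_v)
    E <- tcrossprod(Q[, qc, drop = FALSE], K[, qc, drop = FALSE]) / sqrt(d_qk)
    E[!allowed] <- -Inf
    A <- softmax_rows(E)
    S[, vc] <- A %*% Vv[, vc, drop = FALSE]
    A_list[[h]] <- A
  }
  list(S = S, Q = Q, K = K, V = Vv, A = A_list)
}

attention_backward <- function(dS, att, X, Wq, Wk, Wv, H, d_qk, d_v) {
  dX <- matrix(0, nrow(X), ncol(X))
  dQ <- matrix(0, nrow(X), H * d_qk)
  dK <- dQ
  dV <- matrix(0, nrow(X), H * d_v)
  for (h in seq_len(H)) {
    qc <- ((h - 1L) * d_qk + 1L):(h * d_qk)
    vc <- ((h - 1L) * d_v + 1L):(h * d_v)
    A <- att$A[[h]]
    dO <- dS[, vc, drop = FALSE]
    dA <- tcrossprod(dO, att$V[, vc, drop = FALSE])
    dV[, vc] <- crossprod(A, dO)
    dE <- A * (dA - rowSums(dA * A))
    dQ[, qc] <- dE %*% att$K[, qc, drop = FALSE] / sqrt(d_qk)
    dK[, qc] <- crossprod(dE, att$Q[, qc, drop = FALSE]) / sqrt(d_qk)
  }
  list(dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV),
       dX = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv))
}

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_sd
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

#' One masked multi-head attention layer (single sequence)
#'
#' Computes per-head scaled dot-product attention
#' softmax(Q K' / sqrt(d_qk) + mask) V with the strict causal mask, and
#' concatenates the head outputs.
#'
#' @param X L x M input matrix.
#' @param state a \code{transformer_state}.
#' @param layer layer index (weights to use).
#' @param valid optional logical validity vector (padded positions FALSE).
#' @return list with \code{S} (L x M output) and \code{attention} (list of
#'   per-head L x L post-softmax matrices).
#' @export
masked_attention_layer <- function(X, state, layer = 1L, valid = NULL) {
  cf <- state$config
  if (ncol(X) != cf$d_model) stop_midrp("X must have %d columns", cf$d_model)
  L <- nrow(X)
  if (is.null(valid)) valid <- rep(TRUE, L)
  allowed <- batch_allowed(matrix(valid, 1L, L))
  att <- attention_forward(X, state$params[[paste0("Wq", layer)]],
                           state$params[[paste0("Wk", layer)]],
                           state$params[[paste0("Wv", layer)]],
                           cf$n_heads, cf$d_qk, cf$d_v, allowed)
  list(S = att$S, attention = att$A)
}

#' Position-wise feed-forward network
#'
#' H = ReLU(S W1 + b1) W2 + b2, applied row-wise.
#' @param S L x M input.
#' @param state a \code{transformer_state}.
#' @param layer layer index.
#' @return L x M output matrix.
#' @export
feed_forward <- function(S, state, layer = 1L) {
  p <- state$params
  Z1 <- S %*% p[[paste0("W1", layer)]] +
    rep(p[[paste0("b1", layer)]], each = nrow(S))
  pmax(Z1, 0) %*% p[[paste0("W2", layer)]] +
    rep(p[[paste0("b2", layer)]], each = nrow(S))
}

## Full stacked forward over a padded batch. Returns hidden rows (n x M,
## sequence-major) and, when cache = TRUE, everything backward needs.
mct_forward <- function(ids, times, mask, state, cache = FALSE) {
  cf <- state$config; p <- state$params
  B <- nrow(ids); L <- ncol(ids)
  ids_flat <- as.vector(t(ids))
  X <- embed_sequence(ids_flat, as.vector(t(times)), state)
  allowed <- batch_allowed(mask)
  layers <- vector("list", cf$n_layers)
  for (l in seq_len(cf$n_layers)) {
    att <- attention_forward(X, p[[paste0("Wq", l)]], p[[paste0("Wk", l)]],
                             p[[paste0("Wv", l)]], cf$n_heads, cf$d_qk,
                             cf$d_v, allowed)
    if (cf$use_residual) {
      A1 <- X + att$S
      ln1 <- ln_forward(A1, p[[paste0("g1", l)]], p[[paste0("be1", l)]])
      Z1 <- ln1$y %*% p[[paste0("W1", l)]] +
        rep(p[[paste0("b1", l)]], each = nrow(X))
      R <- pmax(Z1, 0)
      Fo <- R %*% p[[paste0("W2", l)]] + rep(p[[paste0("b2", l)]],
                                             each = nrow(X))
      ln2 <- ln_forward(ln1$y + Fo, p[[paste0("g2", l)]],
                        p[[paste0("be2", l)]])
      out <- ln2$y
      if (cache) layers[[l]] <- list(X = X, att = att, ln1 = ln1, Z1 = Z1,
                                     R = R, ln2 = ln2)
    } else {
      Z1 <- att$S %*% p[[paste0("W1", l)]] +
        rep(p[[paste0("b1", l)]], each = nrow(X))
      R <- pmax(Z1, 0)
      out <- R %*% p[[paste0("W2", l)]] + rep(p[[paste0("b2", l)]],
                                              each = nrow(X))
      if (cache) layers[[l]] <- list(X = X, att = att, Z1 = Z1, R = R)
    }
    X <- out
  }
  res <- list(H = X, ids_flat = ids_flat, B = B, L = L)
  if (cache) res$layers <- layers
  res
}

## Reverse pass: dH is the gradient on the final hidden rows. Returns a
## named grads list aligned with state$params (heads excluded).
mct_backward <- function(dH, fwd, state) {
  cf <- state$config; p <- state$params
  grads <- list()
  dX <- dH
  for (l in rev(seq_len(cf$n_layers))) {
    cc <- fwd$layers[[l]]
    if (cf$use_residual) {
      lb2 <- ln_backward(dX, cc$ln2, p[[paste0("g2", l)]])
      grads[[paste0("g2", l)]] <- lb2$dg
      grads[[paste0("be2", l)]] <- lb2$db
      dA2 <- lb2$dx
      dR <- dA2 %*% t(p[[paste0("W2", l)]])
      grads[[paste0("W2", l)]] <- crossprod(cc$R, dA2)
      grads[[paste0("b2", l)]] <- colSums(dA2)
      dZ1 <- dR * (cc$Z1 > 0)
      grads[[paste0("W1", l)]] <- crossprod(cc$ln1$y, dZ1)
      grads[[paste0("b1", l)]] <- colSums(dZ1)
      dN1 <- dA2 + dZ1 %*% t(p[[paste0("W1", l)]])
      lb1 <- ln_backward(dN1, cc$ln1, p[[paste0("g1", l)]])
      grads[[paste0("g1", l)]] <- lb1$dg
      grads[[paste0("be1", l)]] <- lb1$db
      ab <- attention_backward(lb1$dx, cc$att, cc$X,
                               p[[paste0("Wq", l)]], p[[paste0("Wk", l)]],
                               p[[paste0("Wv", l)]], cf$n_heads, cf$d_qk,
                               cf$d_v)
      dX <- lb1$dx + ab$dX
    } else {
      dR <- dX %*% t(p[[paste0("W2", l)]])
      grads[[paste0("W2", l)]] <- crossprod(cc$R, dX)
      grads[[paste0("b2", l)]] <- colSums(dX)
      dZ1 <- dR * (cc$Z1 > 0)
      grads[[paste0("W1", l)]] <- crossprod(cc$att$S, dZ1)
      grads[[paste0("b1", l)]] <- colSums(dZ1)
      dS <- dZ1 %*% t(p[[paste0("W1", l)]])
      ab <- attention_backward(dS, cc$att, cc$X,
                               p[[paste0("Wq", l)]], p[[paste0("Wk", l)]],
                               p[[paste0("Wv", l)]], cf$n_heads, cf$d_qk,
                               cf$d_v)
      dX <- ab$dX
    }
    grads[[paste0("Wq", l)]] <- ab$dWq
    grads[[paste0("Wk", l)]] <- ab$dWk
    grads[[paste0("Wv", l)]] <- ab$dWv
  }
  dU <- matrix(0, cf$d_model, ncol(p$U))
  nz <- fwd$ids_flat > 0L
  if (any(nz)) {
    agg <- rowsum(dX[nz, , drop = FALSE], group = fwd$ids_flat[nz])
    dU[, as.integer(rownames(agg))] <- t(agg)
  }
  grads$U <- dU
  grads
}

#' Forward pass over one event sequence
#'
#' Runs the full stack of masked attention + feed-forward blocks. Row i of
#' the returned hidden matrix depends only on events at positions <= i.
#'
#' @param seq an \code{event_sequence}, or a list with \code{ids} and
#'   \code{times} already tokenized.
#' @param state a \code{transformer_state}.
#' @param vocab an \code{event_vocabulary} (needed when \code{seq} holds raw
#'   codes).
#' @param pad logical; clip/pad to the model's \code{max_len} (default) or
#'   run at the native length.
#' @return list with \code{H} (L x M hidden rows), \code{ids}, \code{times},
#'   \code{mask}.
#' @export
transformer_forward <- function(seq, state, vocab = NULL, pad = TRUE) {
  if (!is.null(seq$codes)) {
    if (is.null(vocab)) stop_midrp("vocab required for raw code sequences")
    if (pad) {
      cp <- clip_pad(seq, vocab, state$config$max_len)
    } else {
      cp <- list(ids = encode_codes(vocab, seq$codes), times = seq$times,
                 mask = rep(TRUE, length(seq$codes)))
    }
  } else {
    cp <- seq
    if (is.null(cp$mask)) cp$mask <- rep(TRUE, length(cp$ids))
  }
  L <- length(cp$ids)
  fwd <- mct_forward(matrix(cp$ids, 1L, L), matrix(cp$times, 1L, L),
                     matrix(cp$mask, 1L, L), state)
  list(H = fwd$H, ids = cp$ids, times = cp$times, mask = cp$mask)
}

#' Next-event and next-time predictions from hidden rows
#'
#' Position i predicts event i+1: a scalar time from the linear time head
#' and a probability vector over the vocabulary from the event head.
#'
#' @param H L x M hidden matrix.
#' @param state a \code{transformer_state}.
#' @return list with \code{t_hat} (length L), \code{probs} (L x V rows
#'   summing to 1), \code{labels} (argmax ids).
#' @export
predict_next <- function(H, state) {
  t_hat <- as.vector(H %*% state$params$w_time)
  logits <- H %*% state$params$W_event
  probs <- softmax_rows(logits)
  list(t_hat = t_hat, probs = probs, labels = max.col(probs, "first"))
}

#' Squared-error loss on next-event times
#'
#' Sum over target positions i = 2..I of (t_i - that_i)^2, where that_i is
#' predicted from the hidden row at i - 1.
#' @param times true times, length I >= 2.
#' @param t_hat predicted times for positions 2..I (length I - 1), e.g.
#'   \code{predict_next(H, state)$t_hat[1:(I-1)]}.
#' @return non-negative scalar.
#' @export
loss_time <- function(times, t_hat) {
  I <- length(times)
  if (I < 2L) stop_midrp("sequence must have >= 2 events")
  if (length(t_hat) != I - 1L) stop_midrp("need %d predictions", I - 1L)
  sum((times[2:I] - t_hat)^2)
}

#' Cross-entropy loss on next-event types
#'
#' Sum over target positions i = 2..I of -log p_i[c_i]; probabilities are
#' floored at 1e-12 inside the log.
#' @param target_ids true ids at positions 2..I (length I - 1).
#' @param probs (I - 1) x V matrix of predicted probabilities (row r
#'   predicts position r + 1).
#' @return non-negative scalar.
#' @export
loss_event <- function(target_ids, probs) {
  if (length(target_ids) != nrow(probs)) stop_midrp("row/target mismatch")
  pk <- probs[cbind(seq_along(target_ids), target_ids)]
  sum(-log(pmax(pk, 1e-12)))
}

## Joint loss and all parameter gradients for one padded batch.
mct_loss_and_grads <- function(batch, state, want_grads = TRUE) {
  cf <- state$config; p <- state$params
  fwd <- mct_forward(batch$ids, batch$times, batch$mask, state,
                     cache = want_grads)
  B <- fwd$B; L <- fwd$L
  lens <- rowSums(batch$mask)
  pred_rows <- integer(0); targ_rows <- integer(0)
  for (b in seq_len(B)) {
    if (lens[b] >= 2L) {
      base <- (b - 1L) * L
      pred_rows <- c(pred_rows, base + seq_len(lens[b] - 1L))
      targ_rows <- c(targ_rows, base + 2:lens[b])
    }
  }
  Hp <- fwd$H[pred_rows, , drop = FALSE]
  t_true <- as.vector(t(batch$times))[targ_rows]
  c_true <- fwd$ids_flat[targ_rows]
  t_hat <- as.vector(Hp %*% p$w_time)
  probs <- softmax_rows(Hp %*% p$W_event)
  l_time <- sum((t_true - t_hat)^2)
  l_event <- sum(-log(pmax(probs[cbind(seq_along(c_true), c_true)], 1e-12)))
  out <- list(loss = cf$alpha_event * l_event + cf$alpha_time * l_time,
              loss_event = l_event, loss_time = l_time,
              n_targets = length(c_true),
              accuracy = mean(max.col(probs, "first") == c_true))
  if (!want_grads) return(out)
  dlogits <- probs
  dlogits[cbind(seq_along(c_true), c_true)] <-
    dlogits[cbind(seq_along(c_true), c_true)] - 1
  dlogits <- cf$alpha_event * dlogits
  dt <- cf$alpha_time * 2 * (t_hat - t_true)
  dH <- matrix(0, nrow(fwd$H), cf$d_model)
  dH[pred_rows, ] <- outer(dt, p$w_time) + dlogits %*% t(p$W_event)
  grads <- mct_backward(dH, fwd, state)
  grads$w_time <- as.vector(crossprod(Hp, dt))
  grads$W_event <- crossprod(Hp, dlogits)
  out$grads <- grads
  out
}

#' Joint pretraining objective over a batch of sequences
#'
#' Sum over sequences of alpha_event * (next-event cross entropy) +
#' alpha_time * (next-time squared error), padded positions excluded.
#'
#' @param seqs list of \code{event_sequence} objects.
#' @param state a \code{transformer_state}.
#' @param vocab an \code{event_vocabulary}.
#' @param chunk_size sequences per forward pass (memory for the block
#'   attention matrix grows with the square of chunk_size * max_len).
#' @return list with \code{loss}, \code{loss_event}, \code{loss_time},
#'   \code{accuracy} (next-event accuracy over target positions).
#' @export
total_loss <- function(seqs, state, vocab, chunk_size = 64L) {
  tot <- c(loss = 0, loss_event = 0, loss_time = 0)
  acc_num <- 0; n_targets <- 0
  for (start in seq(1L, length(seqs), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(seqs))
    batch <- batch_sequences(seqs[idx], vocab, state$config$max_len)
    res <- mct_loss_and_grads(batch, state, want_grads = FALSE)
    tot <- tot + c(res$loss, res$loss_event, res$loss_time)
    acc_num <- acc_num + res$accuracy * res$n_targets
    n_targets <- n_targets + res$n_targets
  }
  list(loss = tot[[1L]], loss_event = tot[[2L]], loss_time = tot[[3L]],
       n_targets = n_targets, accuracy = acc_num / n_targets)
}

#' Pretrain the causal Transformer
#'
#' Minimizes \code{\link{total_loss}} by minibatch Adam. Deterministic for a
#' fixed \code{config$seed} (initialization, shuffling and updates all draw
#' from the seeded RNG).
#'
#' @param seqs list of \code{event_sequence} objects (training corpus).
#' @param vocab an \code{event_vocabulary} built from the training corpus.
#' @param config a \code{transformer_config}.
#' @param verbose print per-epoch losses.
#' @return a \code{transformer_state} with an extra \code{trajectory}
#'   data.frame (epoch, loss, loss_event, loss_time, accuracy).
#' @export
pretrain_transformer <- function(seqs, vocab, config, verbose = FALSE) {
  if (length(seqs) < 1L) stop_midrp("need at least one training sequence")
  state <- init_transformer(config)
  opt <- adam_init(state$params)
  n <- length(seqs)
  traj <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- c(loss = 0, loss_event = 0, loss_time = 0)
    acc_num <- 0; acc_den <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- batch_sequences(seqs[idx], vocab, config$max_len)
      res <- mct_loss_and_grads(batch, state)
      if (!is.finite(res$loss)) {
        stop_midrp("training diverged at epoch %d (loss=%g)", ep, res$loss)
      }
      tot <- tot + c(res$loss, res$loss_event, res$loss_time)
      acc_num <- acc_num + res$accuracy * res$n_targets
      acc_den <- acc_den + res$n_targets
      upd <- adam_step(state$params, res$grads, opt, lr = config$lr)
      state$params <- upd$params
      opt <- upd$state
    }
    traj[[ep]] <- data.frame(epoch = ep, loss = tot[[1]],
                             loss_event = tot[[2]], loss_time = tot[[3]],
                             accuracy = acc_num / acc_den)
    if (verbose) {
      message(sprintf("epoch %d: loss %.3f acc %.3f", ep, tot[[1]],
                      acc_num / acc_den))
    }
  }
  state$trajectory <- do.call(rbind, traj)
  state
}

#' Next-event accuracy of a trained model on held-out sequences
#' @param seqs list of \code{event_sequence}.
#' @param state trained \code{transformer_state}.
#' @param vocab an \code{event_vocabulary}.
#' @return fraction of target positions whose argmax prediction is correct.
#' @export
next_event_accuracy <- function(seqs, state, vocab) {
  total_loss(seqs, state, vocab)$accuracy
}

#' Extract a patient's medical-history embedding
#'
#' For a case whose first target-disease diagnosis sits at clipped position
#' j: the hidden row at j - 1 (the representation of the last event strictly
#' before diagnosis), or the zero vector when the diagnosis is the first
#' event. For a control: the hidden row of the last real event. Causal
#' masking guarantees the extracted vector never sees the diagnosis or
#' anything after it.
#'
#' @param seq an \code{event_sequence}.
#' @param target_code 3-character target-disease code.
#' @param is_case logical.
#' @param state a \code{transformer_state}.
#' @param vocab an \code{event_vocabulary}.
#' @return numeric M-vector.
#' @export
extract_representation <- function(seq, target_code, is_case, state, vocab) {
  has_target <- target_code %in% seq$codes
  if (is_case && !has_target) {
    stop_midrp("case %s has no %s diagnosis", seq$sample_id, target_code)
  }
  if (!is_case && has_target) {
    stop_midrp("control %s carries a %s diagnosis", seq$sample_id,
               target_code)
  }
  fw <- transformer_forward(seq, state, vocab)
  M <- state$config$d_model
  if (is_case) {
    tid <- encode_codes(vocab, target_code)
    j <- match(tid, fw$ids[fw$mask])
    if (is.na(j) || j == 1L) return(numeric(M))
    fw$H[j - 1L, ]
  } else {
    fw$H[max(which(fw$mask)), ]
  }
}

#' Embeddings for a whole cohort
#'
#' Applies \code{\link{extract_representation}} to every sample and returns
#' a matrix with one row per sample.
#'
#' @param seqs named list of \code{event_sequence} (names = sample ids).
#' @param roles named character vector "case"/"control" per sample id.
#' @param target_code target-disease code.
#' @param state,vocab trained model and vocabulary.
#' @return numeric matrix (samples x M) with rownames = sample ids.
#' @export
extract_cohort_embeddings <- function(seqs, roles, target_code, state,
                                      vocab) {
  ids <- names(roles)
  emb <- matrix(0, length(ids), state$config$d_model,
                dimnames = list(ids, NULL))
  for (id in ids) {
    emb[id, ] <- extract_representation(seqs[[id]], target_code,
                                        roles[[id]] == "case", state, vocab)
  }
  emb
}

#' Export post-softmax attention matrices
#'
#' Recomputes the forward pass for one sequence and returns, for every layer
#' and head, the L x L attention matrix over real positions, with rows and
#' columns labelled by ICD codes. Rows sum to 1 and the strict upper
#' triangle is exactly zero.
#'
#' @param seq an \code{event_sequence}.
#' @param state,vocab trained model and vocabulary.
#' @param path optional directory; when given, each matrix is written as
#'   \code{attention_layer<l>_head<h>.tsv}.
#' @return nested list \code{[[layer]][[head]]} of matrices.
#' @export
export_attention <- function(seq, state, vocab, path = NULL) {
  cp <- clip_pad(seq, vocab, state$config$max_len)
  L <- sum(cp$mask)
  fwd <- mct_forward(matrix(cp$ids, 1L), matrix(cp$times, 1L),
                     matrix(cp$mask, 1L), state, cache = TRUE)
  labels <- decode_ids(vocab, cp$ids[seq_len(L)])
  out <- lapply(fwd$layers, function(layer) {
    lapply(layer$att$A, function(A) {
      A <- A[seq_len(L), seq_len(L), drop = FALSE]
      dimnames(A) <- list(labels, labels)
      A
    })
  })
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (l in seq_along(out)) {
      for (h in seq_along(out[[l]])) {
        utils::write.table(out[[l]][[h]],
                           file.path(path, sprintf(
                             "attention_layer%d_head%d.tsv", l, h)),
                           sep = "\t", quote = FALSE, col.names = NA)
      }
    }
  }
  out
}

#' Save a trained transformer to JSON
#' @param state a \code{transformer_state}.
#' @param vocab the training \code{event_vocabulary}.
#' @param path output file.
#' @export
save_transformer <- function(state, vocab, path) {
  obj <- list(config = unclass(state$config),
              params = lapply(state$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), x = as.vector(p))
                else list(dim = NULL, x = as.vector(p))
              }),
              vocab_codes = vocab$id2code)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a transformer saved by \code{\link{save_transformer}}
#' @param path checkpoint path.
#' @return list with \code{state} and \code{vocab}.
#' @export
load_transformer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(transformer_config,
                    obj$config[setdiff(names(obj$config), "d_v")])
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) {
      matrix(p$x, p$dim[1L], p$dim[2L])
    } else {
      as.numeric(p$x)
    }
  })
  state <- structure(list(params = params, config = config),
                     class = "transformer_state")
  list(state = state, vocab = build_vocabulary(obj$vocab_codes))
}
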