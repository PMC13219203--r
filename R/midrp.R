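## Multi-source risk integrator.
##
## The genetic branch is a logistic model on the polygenic risk score
## (logit L_genetic = w_s * x_s + b_s, probability P by sigmoid). The
## non-genetic branch maps each factor x_j (a lifestyle/physical feature
## vector or the M-dimensional history embedding) through phi_j =
## tanh(W_j x_j) in R^2 (one component per class), stacks the N pairs into
## an N x 2 matrix, Hadamard-weights it by a learnable Gamma in R^{N x 2},
## and sums each class column into a class logit; Q is the two-class
## softmax. Training jointly minimizes the genetic cross-entropy, a KL(Q||P)
## posterior-regularization term and the non-genetic cross-entropy, weighted
## 1 / alpha / beta. The risk score is the sum of the two class-1 logits.

#' Bundle integrator inputs
#'
#' @param x_s numeric vector of polygenic risk scores (one per sample).
#' @param factors named list of numeric matrices, each n x d_j; the history
#'   embedding enters as one factor of dimension M. Plain vectors are
#'   treated as single-column matrices.
#' @param y 0/1 labels (may be NULL for prediction-only data).
#' @return list of class \code{midrp_data}.
#' @export
midrp_data <- function(x_s, factors, y = NULL) {
  factors <- lapply(factors, function(f) {
    if (is.null(dim(f))) matrix(f, ncol = 1L) else as.matrix(f)
  })
  n <- length(x_s)
  bad <- vapply(factors, function(f) nrow(f) != n, logical(1))
  if (any(bad)) stop_midrp("factor row count != number of samples")
  if (!is.null(y) && (length(y) != n || !all(y %in% 0:1))) {
    stop_midrp("y must be 0/1 and match x_s")
  }
  structure(list(x_s = as.numeric(x_s), factors = factors, y = y, n = n),
            class = "midrp_data")
}

#' Integrator hyperparameters
#' @param alpha weight of the KL posterior-regularization term (default 1).
#' @param beta weight of the non-genetic cross-entropy (default 1).
#' @param lr Adam learning rate (default 0.05, full-batch).
#' @param epochs training iterations (default 300).
#' @param seed RNG seed for initialization.
#' @return list of class \code{midrp_config}.
#' @export
midrp_config <- function(alpha = 1, beta = 1, lr = 0.05, epochs = 300L,
                         seed = 1L) {
  if (alpha < 0 || beta < 0) stop_midrp("alpha, beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "midrp_config")
}

init_midrp_params <- function(data, config) {
  set.seed(config$seed)
  N <- length(data$factors)
  params <- list(w_s = stats::rnorm(1, sd = 0.1), b_s = 0,
                 Gamma = matrix(stats::rnorm(2 * N, sd = 0.1), N, 2))
  for (j in seq_len(N)) {
    d <- ncol(data$factors[[j]])
    params[[paste0("W_", j)]] <- matrix(stats::rnorm(2 * d, sd = 0.1), 2, d)
  }
  params
}

#' Genetic-branch logit
#' @param x_s polygenic risk score(s).
#' @param params integrator parameters.
#' @return numeric vector w_s * x_s + b_s.
#' @export
midrp_genetic_logit <- function(x_s, params) {
  params$w_s * x_s + params$b_s
}

#' Genetic-branch class probabilities
#' @param x_s polygenic risk score(s).
#' @param params integrator parameters.
#' @return matrix with columns \code{p1} = P(y = 1) (sigmoid of the logit)
#'   and \code{p0} = 1 - p1.
#' @export
midrp_genetic_prob <- function(x_s, params) {
  p1 <- stats::plogis(midrp_genetic_logit(x_s, params))
  cbind(p1 = p1, p0 = 1 - p1)
}

#' Per-factor transform phi
#'
#' phi_j = tanh(W_j x_j), a 2-vector with one component per class
#' (component 1 for y = 0, component 2 for y = 1).
#' @param x_j factor value: a d-vector (one sample) or n x d matrix.
#' @param w_j 2 x d weight matrix.
#' @return 2-vector, or n x 2 matrix for matrix input.
#' @export
midrp_factor_transform <- function(x_j, w_j) {
  if (is.null(dim(x_j))) {
    if (length(x_j) != ncol(w_j)) stop_midrp("factor dimension mismatch")
    return(as.vector(tanh(w_j %*% x_j)))
  }
  if (ncol(x_j) != ncol(w_j)) stop_midrp("factor dimension mismatch")
  tanh(x_j %*% t(w_j))
}

## Class logits of the non-genetic branch: n x 2 matrix (col 1: y=0,
## col 2: y=1), each column the Gamma-weighted sum of its phi column.
midrp_class_logits <- function(data, params) {
  N <- length(data$factors)
  if (nrow(params$Gamma) != N) stop_midrp("Gamma rows != factor count")
  L <- matrix(0, data$n, 2L)
  for (j in seq_len(N)) {
    phi <- midrp_factor_transform(data$factors[[j]],
                                  params[[paste0("W_", j)]])
    L <- L + phi * rep(params$Gamma[j, ], each = data$n)
  }
  L
}

#' Non-genetic class logits for one or all samples
#' @param data a \code{midrp_data}.
#' @param params integrator parameters.
#' @return n x 2 matrix of class logits (columns y = 0, y = 1).
#' @export
midrp_nongenetic_logits <- function(data, params) {
  midrp_class_logits(data, params)
}

#' Summed non-genetic output
#'
#' The grand sum of the Gamma-weighted phi stack (both class columns),
#' i.e. the sum of the two class logits.
#' @param data a \code{midrp_data}.
#' @param params integrator parameters.
#' @return numeric vector, one value per sample.
#' @export
midrp_nongenetic_logit <- function(data, params) {
  rowSums(midrp_class_logits(data, params))
}

#' Non-genetic posterior Q
#'
#' Two-class softmax of the class logits.
#' @param data a \code{midrp_data}.
#' @param params integrator parameters.
#' @return matrix with columns \code{q1} = Q(y = 1), \code{q0} = Q(y = 0).
#' @export
midrp_q_distribution <- function(data, params) {
  Q <- softmax_rows(midrp_class_logits(data, params))
  cbind(q1 = Q[, 2L], q0 = Q[, 1L])
}

#' Mean KL(Q || P) posterior-regularization term
#' @param data a \code{midrp_data}.
#' @param params integrator parameters.
#' @return non-negative scalar; 0 iff Q = P on every sample.
#' @export
midrp_kl <- function(data, params) {
  P <- midrp_genetic_prob(data$x_s, params)
  Q <- midrp_q_distribution(data, params)
  kl <- rowSums(Q * (log(pmax(Q, 1e-12)) - log(pmax(P, 1e-12))))
  mean(kl)
}

#' Joint training objective
#'
#' mean CE(P, y) + alpha * mean KL(Q || P) + beta * mean CE(Q, y).
#' @param data labeled \code{midrp_data}.
#' @param params integrator parameters.
#' @param alpha,beta loss weights.
#' @return scalar loss.
#' @export
midrp_objective <- function(data, params, alpha = 1, beta = 1) {
  midrp_loss_and_grads(data, params, alpha, beta, want_grads = FALSE)$loss
}

midrp_loss_and_grads <- function(data, params, alpha, beta,
                                 want_grads = TRUE) {
  n <- data$n; y <- data$y
  g <- midrp_genetic_logit(data$x_s, params)
  p1 <- stats::plogis(g)
  Lng <- midrp_class_logits(data, params)           # cols: y=0, y=1
  Q <- softmax_rows(Lng)
  logP <- cbind(log(pmax(1 - p1, 1e-12)), log(pmax(p1, 1e-12)))
  logQ <- log(pmax(Q, 1e-12))
  ce_p <- mean(-logP[cbind(seq_len(n), y + 1L)])
  ce_q <- mean(-logQ[cbind(seq_len(n), y + 1L)])
  d <- logQ - logP
  kl <- mean(rowSums(Q * d))
  out <- list(loss = ce_p + alpha * kl + beta * ce_q,
              ce_p = ce_p, ce_q = ce_q, kl = kl)
  if (!want_grads) return(out)
  Y1 <- matrix(0, n, 2L)
  Y1[cbind(seq_len(n), y + 1L)] <- 1
  dg <- ((p1 - y) + alpha * (p1 - Q[, 2L])) / n
  dl <- (beta * (Q - Y1) + alpha * Q * (d - rowSums(Q * d))) / n
  grads <- list(w_s = sum(dg * data$x_s), b_s = sum(dg),
                Gamma = matrix(0, length(data$factors), 2L))
  for (j in seq_along(data$factors)) {
    Xj <- data$factors[[j]]
    Wj <- params[[paste0("W_", j)]]
    phi <- tanh(Xj %*% t(Wj))
    grads$Gamma[j, ] <- colSums(dl * phi)
    dphi <- dl * rep(params$Gamma[j, ], each = n)
    dA <- dphi * (1 - phi * phi)
    grads[[paste0("W_", j)]] <- crossprod(dA, Xj)
  }
  out$grads <- grads
  out
}

#' Train the integrator
#'
#' Full-batch Adam on the joint objective; deterministic for a fixed seed.
#'
#' @param data labeled training \code{midrp_data}.
#' @param config a \code{midrp_config}.
#' @param verbose print progress every 50 epochs.
#' @return list of class \code{midrp_model}: \code{params},
#'   \code{trajectory} (per-epoch loss components), \code{config}.
#' @export
train_midrp <- function(data, config = midrp_config(), verbose = FALSE) {
  if (is.null(data$y)) stop_midrp("training data must be labeled")
  params <- init_midrp_params(data, config)
  opt <- adam_init(params)
  traj <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    res <- midrp_loss_and_grads(data, params, config$alpha, config$beta)
    if (!is.finite(res$loss)) stop_midrp("training diverged at epoch %d", ep)
    upd <- adam_step(params, res$grads, opt, lr = config$lr)
    params <- upd$params
    opt <- upd$state
    traj[[ep]] <- data.frame(epoch = ep, loss = res$loss, ce_p = res$ce_p,
                             kl = res$kl, ce_q = res$ce_q)
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("epoch %d: loss %.4f", ep, res$loss))
    }
  }
  structure(list(params = params, trajectory = do.call(rbind, traj),
                 config = config),
            class = "midrp_model")
}

#' Fused risk score
#'
#' R = L_genetic(y = 1) + L_non-genetic(y = 1), both terms taken as class-1
#' log-odds: the genetic term is w_s * x_s + b_s (the log-odds behind the
#' sigmoid of P) and the non-genetic term is the class margin
#' L(y = 1) - L(y = 0) of the Gamma-weighted phi stack, which is the
#' identifiable log-odds behind the two-class softmax of Q (a softmax logit
#' is only defined up to a per-sample constant; the margin is its canonical
#' representative, exactly as the genetic logit is for the sigmoid).
#' @param data a \code{midrp_data}.
#' @param model a \code{midrp_model} (or bare parameter list).
#' @return numeric risk-score vector.
#' @export
risk_score <- function(data, model) {
  params <- model$params %||% model
  lng <- midrp_class_logits(data, params)
  midrp_genetic_logit(data$x_s, params) + (lng[, 2L] - lng[, 1L])
}

#' One-hot / z-score factor encoding for the integrator
#'
#' Numeric columns are z-scored with training-split mean/sd; categorical
#' columns are one-hot encoded over training-split levels. Each feature
#' becomes one factor; an optional embedding matrix is appended as a final
#' factor named \code{"embedding"}.
#'
#' @param features data.frame of imputed features.
#' @param train_rows index of training rows (statistics source).
#' @param embeddings optional n x M numeric matrix.
#' @return named list of n x d factor matrices.
#' @export
encode_factors <- function(features, train_rows = seq_len(nrow(features)),
                           embeddings = NULL) {
  factors <- list()
  for (nm in names(features)) {
    x <- features[[nm]]
    if (is.numeric(x)) {
      mu <- mean(x[train_rows]); sdv <- stats::sd(x[train_rows])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      factors[[nm]] <- matrix((x - mu) / sdv, ncol = 1L)
    } else {
      lev <- sort(unique(as.character(x[train_rows])))
      m <- matrix(0, length(x), length(lev),
                  dimnames = list(NULL, lev))
      hit <- match(as.character(x), lev)
      ok <- !is.na(hit)
      m[cbind(which(ok), hit[ok])] <- 1
      factors[[nm]] <- m
    }
  }
  if (!is.null(embeddings)) factors[["embedding"]] <- as.matrix(embeddings)
  factors
}
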