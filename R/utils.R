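#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_midrp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_midrp <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Row-wise softmax with support for -Inf masked entries
#'
#' Rows consisting entirely of -Inf yield all-zero rows rather than NaN.
#' @param e numeric matrix of logits, possibly containing -Inf.
#' @return matrix of the same shape whose finite rows sum to 1.
#' @keywords internal
softmax_rows <- function(e) {
  m <- apply(e, 1L, max)
  m[!is.finite(m)] <- 0
  a <- exp(e - m)
  a[!is.finite(a)] <- 0
  s <- rowSums(a)
  s[s == 0] <- 1
  a / s
}

## Adam optimizer over a flat named list of numeric arrays.
adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Flatten/unflatten helpers used by the finite-difference gradient checks.
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    val <- theta[pos:(pos + n - 1L)]
    dim(val) <- dim(template[[nm]])
    out[[nm]] <- val
    pos <- pos + n
  }
  out
}
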