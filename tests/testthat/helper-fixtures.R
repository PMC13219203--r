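# Shared fixtures: tiny models and corpora built in code.

tiny_config <- function(K = 5L, alpha_time = 0.5, seed = 3L, ...) {
  transformer_config(K = K, n_layers = 2L, n_heads = 2L, d_model = 8L,
                     d_qk = 4L, d_ff = 10L, max_len = 6L,
                     alpha_time = alpha_time, seed = seed, ...)
}

# random state away from ReLU kinks (init sd 0.02 leaves pre-activations
# within finite-difference epsilon of zero)
tiny_state <- function(config = tiny_config(), sd = 0.5, seed = 99L) {
  st <- init_transformer(config)
  set.seed(seed)
  st$params <- lapply(st$params, function(p) {
    q <- stats::rnorm(length(p), sd = sd)
    dim(q) <- dim(p)
    q
  })
  st
}

random_sequence <- function(vocab, L, seed = NULL, id = "S1") {
  if (!is.null(seed)) set.seed(seed)
  structure(list(sample_id = id,
                 codes = sample(vocab$id2code, L, replace = TRUE),
                 times = cumsum(stats::runif(L, 0.1, 1))),
            class = "event_sequence")
}

toy_vocab <- function(K = 5L) build_vocabulary(synthetic_codes(K))

write_tmp_events <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent scalar oracle for the temporal encoding
temporal_encode_oracle <- function(t, M) {
  z <- numeric(M)
  for (j in seq_len(M)) {
    z[j] <- if (j %% 2 == 1) cos(t / 10000^((j - 1) / M))
            else sin(t / 10000^(j / M))
  }
  z
}
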