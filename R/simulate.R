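## Synthetic-data generators with exported ground truth.
##
## Three worlds are simulated: (1) comorbidity-structured diagnosis
## sequences from a first-order Markov chain over 3-character codes with
## exponential waiting times and optional precursor -> target enrichment;
## (2) a liability-model case-control cohort with known genetic
## (polygenic-score), feature and history effects; (3) exposure/outcome GWAS
## summary-statistic pairs with planted causal effects, linkage
## disequilibrium, palindromic and allele-flipped rows. Every generator is
## bit-reproducible under a fixed seed and attaches its ground truth, so
## downstream estimates can be checked against known answers.

#' Default synthetic code inventory
#' @param K number of distinct 3-character codes.
#' @return character vector like "A00", "A01", ...
#' @export
synthetic_codes <- function(K) {
  sprintf("%s%02d", LETTERS[(seq_len(K) - 1L) %/% 100L + 1L],
          (seq_len(K) - 1L) %% 100L)
}

#' Build a learnable Markov transition matrix
#'
#' Each code has one dominant successor (probability \code{dominant}); the
#' remaining mass is uniform over the other codes. The dominant successor
#' of code j is code j + 1 (cyclic) shuffled by the seed, giving a chain
#' whose Bayes-optimal next-event accuracy is \code{dominant}.
#'
#' @param K number of codes.
#' @param dominant probability of the dominant successor (default 0.7).
#' @param seed RNG seed for the successor permutation.
#' @return K x K row-stochastic matrix.
#' @export
markov_transition_matrix <- function(K, dominant = 0.7, seed = 1L) {
  set.seed(seed)
  succ <- sample.int(K)
  P <- matrix((1 - dominant) / (K - 1), K, K)
  for (j in seq_len(K)) {
    if (succ[j] == j) succ[j] <- if (j == K) 1L else j + 1L
    P[j, ] <- (1 - dominant) / (K - 1)
    P[j, succ[j]] <- dominant
  }
  P
}

#' Analytic Bayes accuracy of the generating chain
#'
#' Expected next-event accuracy of the Bayes predictor (argmax of the true
#' transition row) over a corpus of sequences with the given lengths,
#' marginalizing the state distribution position by position.
#'
#' @param trans K x K transition matrix.
#' @param init initial state distribution (default uniform).
#' @param lengths integer vector of sequence lengths in the corpus.
#' @return scalar expected accuracy.
#' @export
markov_bayes_accuracy <- function(trans, init = NULL, lengths) {
  K <- nrow(trans)
  if (is.null(init)) init <- rep(1 / K, K)
  rowmax <- apply(trans, 1L, max)
  max_len <- max(lengths)
  acc_by_pos <- numeric(max_len - 1L)
  d <- init
  for (i in seq_len(max_len - 1L)) {
    acc_by_pos[i] <- sum(d * rowmax)
    d <- as.vector(d %*% trans)
  }
  len_tab <- table(lengths)
  num <- 0; den <- 0
  for (nm in names(len_tab)) {
    L <- as.integer(nm); cnt <- len_tab[[nm]]
    num <- num + cnt * sum(acc_by_pos[seq_len(L - 1L)])
    den <- den + cnt * (L - 1L)
  }
  num / den
}

#' Simulate diagnosis-event sequences
#'
#' First code from \code{init}, subsequent codes from the Markov chain,
#' inter-event gaps Exponential(\code{rate}). When \code{target_code} and
#' \code{precursor_codes} are given, transitions out of a precursor code
#' are re-weighted so the target follows with probability
#' \code{target_prob}, planting a comorbidity signal; the returned truth
#' holds the effective transition matrix actually sampled from.
#'
#' @param n_samples number of patients.
#' @param codes code inventory (default \code{synthetic_codes(20)}).
#' @param trans transition matrix (default
#'   \code{markov_transition_matrix(K)}).
#' @param init initial distribution (default uniform).
#' @param rate exponential rate of inter-event gaps in model time units
#'   (default 1).
#' @param len_range inclusive range of sequence lengths (default c(3, 30)).
#' @param target_code,precursor_codes,target_prob optional comorbidity
#'   planting (see above).
#' @param seed RNG seed.
#' @return list of class \code{sim_sequences}: \code{events} (data.frame
#'   sample_id, code, time), \code{sequences} (an
#'   \code{event_sequence_set}), and \code{truth} (transition matrix, init,
#'   lengths, bayes_accuracy).
#' @export
simulate_event_sequences <- function(n_samples, codes = synthetic_codes(20),
                                     trans = NULL, init = NULL, rate = 1,
                                     len_range = c(3L, 30L),
                                     target_code = NULL,
                                     precursor_codes = character(0),
                                     target_prob = 0.5, seed = 1L) {
  K <- length(codes)
  if (is.null(trans)) trans <- markov_transition_matrix(K, seed = seed)
  if (is.null(init)) init <- rep(1 / K, K)
  stopifnot(nrow(trans) == K, all(abs(rowSums(trans) - 1) < 1e-8),
            rate > 0)
  eff <- trans
  if (!is.null(target_code) && length(precursor_codes) > 0L) {
    ti <- match(target_code, codes)
    for (pc in match(precursor_codes, codes)) {
      row <- eff[pc, ]
      row[ti] <- 0
      row <- row / sum(row) * (1 - target_prob)
      row[ti] <- target_prob
      eff[pc, ] <- row
    }
  }
  set.seed(seed)
  lengths <- sample(len_range[1L]:len_range[2L], n_samples, replace = TRUE)
  ids <- sprintf("S%05d", seq_len(n_samples))
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    L <- lengths[s]
    st <- integer(L)
    st[1L] <- sample.int(K, 1L, prob = init)
    for (i in seq_len(L - 1L)) {
      st[i + 1L] <- sample.int(K, 1L, prob = eff[st[i], ])
    }
    gaps <- stats::rexp(L - 1L, rate)
    out[[s]] <- data.frame(sample_id = ids[s], code = codes[st],
                           time = c(0, cumsum(gaps)),
                           stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  structure(list(events = events,
                 sequences = assemble_sequences(events),
                 truth = list(transition = eff, init = init, codes = codes,
                              lengths = lengths,
                              bayes_accuracy = markov_bayes_accuracy(
                                eff, init, lengths))),
            class = "sim_sequences")
}

#' Simulate a liability-model cohort over existing sequences
#'
#' Disease labels are drawn from a logistic liability combining a standard
#' normal polygenic score, numeric and categorical lifestyle features with
#' known effects, and an indicator of planted precursor codes in the
#' sample's history. Labeled cases have a target-code diagnosis injected at
#' a random point of their timeline (controls have any target diagnosis
#' removed), baselines are drawn uniformly over each sample's observed span
#' so both prevalent (pre-baseline) and incident cases occur, and
#' missingness is injected at a configurable rate. The Bayes-optimal risk
#' score (the true liability) is exported for oracle comparisons.
#'
#' @param sim a \code{sim_sequences} object.
#' @param target_code target-disease code (must be in the inventory).
#' @param precursor_codes codes whose presence raises disease risk.
#' @param b_prs polygenic-score effect (default 1).
#' @param b_comorbid precursor-indicator effect (default 1).
#' @param feature_effects named numeric vector of numeric-feature effects
#'   (default two features at 0.5 and -0.5).
#' @param intercept liability intercept (default -1; controls prevalence).
#' @param missing_rate per-cell missingness in the feature table.
#' @param self_report_rate fraction of cases flagged as self-reported.
#' @param seed RNG seed.
#' @return list of class \code{sim_cohort}: \code{participants}
#'   (sample_id, baseline, self_report, prs, label), \code{features}
#'   (data.frame with NAs), \code{sequences} (with injected/removed target
#'   events), and \code{truth} (effects and true_logit).
#' @export
simulate_cohort <- function(sim, target_code, precursor_codes = character(0),
                            b_prs = 1, b_comorbid = 1,
                            feature_effects = c(f1 = 0.5, f2 = -0.5),
                            intercept = -1, missing_rate = 0.02,
                            self_report_rate = 0.1, seed = 1L) {
  set.seed(seed)
  seqs <- sim$sequences$sequences
  ids <- names(seqs)
  n <- length(ids)
  prs <- stats::rnorm(n)
  feats <- as.data.frame(lapply(feature_effects, function(.) stats::rnorm(n)))
  names(feats) <- names(feature_effects)
  has_precursor <- vapply(seqs, function(s) {
    any(s$codes %in% precursor_codes)
  }, logical(1))
  true_logit <- intercept + b_prs * prs +
    as.matrix(feats) %*% feature_effects + b_comorbid * has_precursor
  true_logit <- as.vector(true_logit)
  label <- stats::rbinom(n, 1L, stats::plogis(true_logit))
  ## reconcile histories with labels: cases carry the target code, controls
  ## never do
  other <- setdiff(unique(unlist(lapply(seqs, `[[`, "codes"))), target_code)
  for (k in seq_len(n)) {
    s <- seqs[[k]]
    hit <- s$codes == target_code
    if (any(hit)) {       # recode, not delete, so lengths are preserved
      s$codes[hit] <- sample(other, sum(hit), replace = TRUE)
    }
    if (label[k] == 1L) {
      pos <- sample(seq_along(s$codes), 1L)
      codes2 <- append(s$codes, target_code, after = pos)
      times2 <- append(s$times, s$times[pos] + stats::runif(1, 0, 0.5),
                       after = pos)
      ord <- order(times2)
      s$codes <- codes2[ord]
      s$times <- times2[ord]
    }
    seqs[[k]] <- s
  }
  baseline <- vapply(seqs, function(s) {
    stats::runif(1, min(s$times), max(s$times) + 0.5)
  }, numeric(1))
  self_report <- label == 1L & stats::runif(n) < self_report_rate
  for (nm in names(feats)) {
    miss <- stats::runif(n) < missing_rate
    feats[[nm]][miss] <- NA
  }
  structure(list(
    participants = data.frame(sample_id = ids, baseline = baseline,
                              self_report = self_report, prs = prs,
                              label = label, stringsAsFactors = FALSE),
    features = feats,
    sequences = seqs,
    truth = list(intercept = intercept, b_prs = b_prs,
                 b_comorbid = b_comorbid, feature_effects = feature_effects,
                 has_precursor = has_precursor, true_logit = true_logit)),
    class = "sim_cohort")
}

#' Simulate a liability cohort from the integrator's own model family
#'
#' Directly generates PRS, factor vectors and labels from a logistic model
#' whose logit is linear in the PRS and in each factor, so the Bayes-optimal
#' score is the true logit itself. Used to test parameter recovery and
#' near-Bayes discrimination of the trained integrator.
#'
#' @param n number of samples.
#' @param b_prs PRS effect.
#' @param factor_effects named list; each element is the true weight vector
#'   of one factor (its length sets the factor dimension).
#' @param intercept liability intercept.
#' @param seed RNG seed.
#' @return list: \code{data} (a labeled \code{midrp_data}),
#'   \code{true_logit}, and \code{truth} (the coefficients).
#' @export
simulate_liability_data <- function(n, b_prs = 1,
                                    factor_effects = list(
                                      lifestyle = 0.8,
                                      embedding = c(1, -0.5, rep(0, 6))),
                                    intercept = -0.5, seed = 1L) {
  set.seed(seed)
  prs <- stats::rnorm(n)
  logit <- intercept + b_prs * prs
  factors <- list()
  for (nm in names(factor_effects)) {
    w <- factor_effects[[nm]]
    X <- matrix(stats::rnorm(n * length(w)), n, length(w))
    factors[[nm]] <- X
    logit <- logit + as.vector(X %*% w)
  }
  y <- stats::rbinom(n, 1L, stats::plogis(logit))
  list(data = midrp_data(prs, factors, y), true_logit = logit,
       truth = list(intercept = intercept, b_prs = b_prs,
                    factor_effects = factor_effects))
}

random_alleles <- function(n) {
  ## non-palindromic pairs only (A/G, A/C, T/G, T/C and swaps)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
}

#' Simulate an exposure GWAS with two outcome GWAS and an LD table
#'
#' Instrument effects on the exposure are drawn with the stated standard
#' error; outcome effects are \code{true_effect} times the true exposure
#' effect plus independent noise for each of the two outcome studies.
#' Variants are placed far apart (outside the clumping window) except one
#' planted high-r^2 pair and one low-r^2 pair; weak / rare variants, one
#' palindromic variant and one allele-flipped outcome row are injected to
#' exercise filtering and harmonization.
#'
#' @param n_instruments number of valid instruments (default 50).
#' @param true_effect causal exposure -> outcome effect (0 = null).
#' @param se_x exposure standard error (default 0.005).
#' @param se_y outcome standard error (default 0.02).
#' @param seed RNG seed.
#' @return list of class \code{sim_gwas}: \code{exposure},
#'   \code{outcome1}, \code{outcome2} (GWAS data.frames with \code{pos}),
#'   \code{ld} (variant_id_1, variant_id_2, r2), and \code{truth}.
#' @export
simulate_gwas_pair <- function(n_instruments = 50, true_effect = 0.3,
                               se_x = 0.005, se_y = 0.02, seed = 1L) {
  set.seed(seed)
  n_extra <- 4L      # weak, rare, palindromic, flipped
  n <- n_instruments + n_extra
  ids <- sprintf("rs%04d", seq_len(n))
  pos <- seq_len(n) * 2e7          # 20 Mb apart: outside a 10 Mb window
  al <- random_alleles(n)
  gamma <- sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.05, 0.10)
  eaf <- stats::runif(n, 0.05, 0.95)
  beta_x <- gamma + stats::rnorm(n, sd = se_x)
  exposure <- data.frame(variant_id = ids, effect_allele = al[, 1L],
                         other_allele = al[, 2L], eaf = eaf,
                         beta = beta_x, se = se_x,
                         pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
                         pos = pos, stringsAsFactors = FALSE)
  iw <- n_instruments + 1L
  exposure$pval[iw] <- 2e-5                     # weak: fails p filter
  exposure$eaf[iw + 1L] <- 0.995                # rare: fails MAF filter
  exposure$effect_allele[iw + 2L] <- "A"        # palindromic
  exposure$other_allele[iw + 2L] <- "T"
  make_outcome <- function() {
    by <- true_effect * gamma + stats::rnorm(n, sd = se_y)
    data.frame(variant_id = ids, effect_allele = al[, 1L],
               other_allele = al[, 2L], eaf = eaf, beta = by, se = se_y,
               pval = 2 * stats::pnorm(-abs(by / se_y)), pos = pos,
               stringsAsFactors = FALSE)
  }
  outcome1 <- make_outcome()
  outcome2 <- make_outcome()
  flip <- iw + 3L                               # allele-flipped in outcomes
  for (o in c("outcome1", "outcome2")) {
    oc <- get(o)
    oc$effect_allele[flip] <- al[flip, 2L]
    oc$other_allele[flip] <- al[flip, 1L]
    oc$beta[flip] <- -oc$beta[flip]
    oc$eaf[flip] <- 1 - oc$eaf[flip]
    assign(o, oc)
  }
  ## planted LD: variants 1-2 moved adjacent with r2 = 0.9 (one must be
  ## clumped away); variants 3-4 adjacent with negligible r2 (both kept)
  exposure$pos[2L] <- exposure$pos[1L] + 1e5
  exposure$pos[4L] <- exposure$pos[3L] + 1e5
  for (o in c("outcome1", "outcome2")) {
    oc <- get(o); oc$pos <- exposure$pos; assign(o, oc)
  }
  ld <- data.frame(variant_id_1 = ids[c(1L, 3L)],
                   variant_id_2 = ids[c(2L, 4L)],
                   r2 = c(0.9, 0.0005), stringsAsFactors = FALSE)
  structure(list(exposure = exposure, outcome1 = outcome1,
                 outcome2 = outcome2, ld = ld,
                 truth = list(true_effect = true_effect, gamma = gamma,
                              weak_id = ids[iw], rare_id = ids[iw + 1L],
                              palindromic_id = ids[iw + 2L],
                              flipped_id = ids[flip],
                              ld_pair = ids[1:2])),
            class = "sim_gwas")
}
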