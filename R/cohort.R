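## Cohort construction: case/control definition, baseline-time split,
## control sampling, and non-genetic feature preparation.

#' Assign a participant to train/test case status
#'
#' A participant whose earliest target-disease diagnosis precedes their
#' baseline (assessment-centre visit) is a training case; one whose first
#' diagnosis falls at or after baseline is a testing (incident) case;
#' self-reported disease puts a participant in the training set regardless
#' of diagnoses; everyone else is not a case.
#'
#' @param seq the participant's \code{event_sequence} (time-sorted).
#' @param baseline_time baseline on the same clock as the sequence times.
#' @param target_code 3-character target-disease code.
#' @param self_report logical self-reported disease flag.
#' @return one of "train", "test", "not_case".
#' @export
assign_case_split <- function(seq, baseline_time, target_code,
                              self_report = FALSE) {
  hit <- which(seq$codes == target_code)
  if (length(hit) > 0L) {
    first_t <- seq$times[hit[1L]]
    if (first_t < baseline_time) return("train")
    if (isTRUE(self_report)) return("train")
    return("test")
  }
  if (isTRUE(self_report)) return("train")
  "not_case"
}

#' Build the control pool
#'
#' Controls are participants never diagnosed with the target disease and
#' not self-reporting it.
#'
#' @param seqs named list of \code{event_sequence}.
#' @param target_code target-disease code.
#' @param self_report named logical vector per sample id (default all
#'   FALSE).
#' @return character vector of eligible control ids.
#' @export
build_control_pool <- function(seqs, target_code, self_report = NULL) {
  ids <- names(seqs)
  if (is.null(self_report)) {
    self_report <- stats::setNames(rep(FALSE, length(ids)), ids)
  }
  diagnosed <- vapply(seqs, function(s) target_code %in% s$codes, logical(1))
  ids[!diagnosed & !self_report[ids]]
}

#' Sample matched controls
#'
#' Uniform sampling without replacement from the control pool, split into
#' disjoint train and test control sets of the requested sizes.
#'
#' @param pool character vector of eligible control ids.
#' @param n_train,n_test control counts (match the case counts).
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} id vectors.
#' @export
sample_controls <- function(pool, n_train, n_test, seed = 1L) {
  if (length(pool) < n_train + n_test) {
    stop_midrp("control pool too small: need %d, have %d (short by %d)",
               n_train + n_test, length(pool),
               n_train + n_test - length(pool))
  }
  set.seed(seed)
  picked <- sample(pool, n_train + n_test)
  list(train = picked[seq_len(n_train)],
       test = picked[n_train + seq_len(n_test)])
}

#' Build a complete case-control cohort split
#'
#' Applies \code{\link{assign_case_split}} to every participant, builds the
#' control pool and samples the same number of controls as cases in each
#' split.
#'
#' @param seqs named list of \code{event_sequence}.
#' @param baselines named numeric vector of baseline times per id.
#' @param target_code target-disease code.
#' @param self_report named logical vector (optional).
#' @param seed control-sampling seed.
#' @return data.frame with sample_id, split ("train"/"test"), role
#'   ("case"/"control").
#' @export
build_cohort <- function(seqs, baselines, target_code, self_report = NULL,
                         seed = 1L) {
  ids <- names(seqs)
  if (is.null(self_report)) {
    self_report <- stats::setNames(rep(FALSE, length(ids)), ids)
  }
  split <- vapply(ids, function(id) {
    assign_case_split(seqs[[id]], baselines[[id]], target_code,
                      self_report[[id]])
  }, character(1))
  train_cases <- ids[split == "train"]
  test_cases <- ids[split == "test"]
  pool <- build_control_pool(seqs, target_code, self_report)
  ctl <- sample_controls(pool, length(train_cases), length(test_cases),
                         seed)
  data.frame(
    sample_id = c(train_cases, ctl$train, test_cases, ctl$test),
    split = c(rep("train", length(train_cases) + length(ctl$train)),
              rep("test", length(test_cases) + length(ctl$test))),
    role = c(rep("case", length(train_cases)),
             rep("control", length(ctl$train)),
             rep("case", length(test_cases)),
             rep("control", length(ctl$test))),
    stringsAsFactors = FALSE)
}

#' Drop high-missingness features
#'
#' Removes feature columns whose missing fraction (computed before any
#' imputation) exceeds \code{max_rate}; a column at exactly the threshold
#' is kept.
#'
#' @param table data.frame of features (rows = samples).
#' @param max_rate maximum tolerated missing fraction (default 0.05).
#' @return filtered data.frame with attribute \code{dropped}.
#' @export
filter_missingness <- function(table, max_rate = 0.05) {
  rate <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  dropped <- names(table)[rate > max_rate]
  out <- table[, rate <= max_rate, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Impute missing feature values (train-derived)
#'
#' Numeric columns: missing values replaced by the training-split median.
#' Categorical (factor/character) columns: training-split mode. Imputation
#' statistics are learned on the training rows only and reused verbatim for
#' test rows, so no test information leaks into the fill values.
#'
#' @param table data.frame of features.
#' @param train_rows logical or integer index of training rows.
#' @return list with \code{table} (imputed) and \code{values} (named list
#'   of the train-derived fill values).
#' @export
impute_features <- function(table, train_rows = seq_len(nrow(table))) {
  values <- list()
  for (nm in names(table)) {
    x <- table[[nm]]
    tr <- x[train_rows]
    if (all(is.na(tr))) {
      warn_midrp("feature '%s' entirely missing in training rows; dropped",
                 nm)
      table[[nm]] <- NULL
      next
    }
    if (is.numeric(x)) {
      fill <- stats::median(tr, na.rm = TRUE)
    } else {
      tab <- sort(table(tr), decreasing = TRUE)
      fill <- names(tab)[1L]
    }
    x[is.na(x)] <- fill
    table[[nm]] <- x
    values[[nm]] <- fill
  }
  list(table = table, values = values)
}

#' Univariable logistic screening of candidate features
#'
#' Fits, on the training split only, one logistic regression of the disease
#' label on each feature and keeps features whose likelihood-ratio p-value
#' is at most \code{alpha} (the LR test stays well-defined under complete
#' separation, where the Wald statistic degenerates). Degenerate fits are
#' marked untestable and excluded.
#'
#' @param table data.frame of (imputed) features, training rows only.
#' @param labels 0/1 disease labels aligned with the rows.
#' @param alpha p-value threshold (default 0.05; boundary kept).
#' @return data.frame with feature, p_value, keep, status.
#' @export
screen_candidates <- function(table, labels, alpha = 0.05) {
  stopifnot(length(labels) == nrow(table), all(labels %in% 0:1))
  rows <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    if (!is.numeric(x)) x <- factor(x)
    if ((is.factor(x) && nlevels(droplevels(x)) < 2L) ||
        (is.numeric(x) && stats::var(x) == 0)) {
      return(data.frame(feature = nm, p_value = NA_real_, keep = FALSE,
                        status = "untestable", stringsAsFactors = FALSE))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(labels ~ x, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(feature = nm, p_value = NA_real_, keep = FALSE,
                        status = "untestable", stringsAsFactors = FALSE))
    }
    ## likelihood-ratio p-value: unlike the Wald test it stays well-defined
    ## under complete separation (deviance drop is huge, p -> 0)
    p <- stats::pchisq(fit$null.deviance - fit$deviance,
                       df = fit$df.null - fit$df.residual,
                       lower.tail = FALSE)
    if (!is.finite(p)) {
      return(data.frame(feature = nm, p_value = NA_real_, keep = FALSE,
                        status = "untestable", stringsAsFactors = FALSE))
    }
    data.frame(feature = nm, p_value = p, keep = p <= alpha,
               status = "tested", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
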