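## Evaluation: discrimination/classification metrics and the overlap
## (Venn) analysis of correct predictions across models.

#' Classification metrics for a score vector
#'
#' AUROC is computed by the rank (Wilcoxon) statistic with ties averaged.
#' Accuracy, precision, recall and F1 are evaluated at \code{threshold};
#' the default threshold is the score median, \code{"youden"} picks the
#' ROC point maximizing sensitivity + specificity - 1.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param threshold numeric cut-off, or \code{"median"} (default) /
#'   \code{"youden"}.
#' @return list of class \code{metric_report}: auroc, accuracy, precision,
#'   recall, f1, threshold, n_pos, n_neg.
#' @export
compute_metrics <- function(scores, labels, threshold = "median") {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_midrp("AUROC undefined: need both classes, got %d pos / %d neg",
               n_pos, n_neg)
  }
  r <- rank(scores)     # ties averaged
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  if (identical(threshold, "median")) {
    thr <- stats::median(scores)
  } else if (identical(threshold, "youden")) {
    cand <- sort(unique(scores))
    youden <- vapply(cand, function(t) {
      sens <- mean(scores[labels == 1L] >= t)
      spec <- mean(scores[labels == 0L] < t)
      sens + spec - 1
    }, numeric(1))
    thr <- cand[which.max(youden)]
  } else {
    thr <- as.numeric(threshold)
  }
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(auroc = auroc, accuracy = mean(pred == labels),
                 precision = precision, recall = recall, f1 = f1,
                 threshold = thr, n_pos = n_pos, n_neg = n_neg),
            class = "metric_report")
}

#' Overlap (Venn) analysis of correct-prediction sets
#'
#' Counts, for 2 or 3 models, how many sample ids fall in each exclusive
#' region of the Venn diagram of correctly predicted ids.
#'
#' @param sets named list of 2 or 3 character vectors (ids each model got
#'   right).
#' @return data.frame with columns region (e.g. "A&B") and count, covering
#'   every non-empty membership pattern.
#' @export
overlap_analysis <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stop_midrp("overlap_analysis needs 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  ## enumerate all 2^k - 1 regions so empty regions report zero
  regions <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, FUN = paste, collapse = "&")
  }))
  counts <- vapply(regions, function(rg) sum(pattern == rg), integer(1))
  data.frame(region = regions, count = unname(counts),
             stringsAsFactors = FALSE)
}
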