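## Two-sample Mendelian randomization feature selection.
##
## For each candidate exposure (a lifestyle or physical feature) instruments
## are drawn from its GWAS, filtered for strength and frequency, purged of
## known-confounder SNPs, LD-clumped, harmonized against each of two
## independent outcome GWAS, and combined by inverse-variance weighting.
## The two IVW estimates are pooled by fixed-effect meta-analysis; an
## exposure is called causal only when the pooled effect is significant,
## heterogeneity is negligible (both I^2 and Cochran's Q p-value), and the
## 95% confidence interval excludes zero.

gwas_required_cols <- c("variant_id", "effect_allele", "other_allele",
                        "eaf", "beta", "se", "pval")

#' Read a GWAS summary-statistics table
#'
#' @param path TSV with columns variant_id, effect_allele, other_allele,
#'   eaf, beta, se, pval (extra columns kept).
#' @return validated data.frame.
#' @export
read_gwas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  validate_gwas(df, path)
}

validate_gwas <- function(df, label = "gwas") {
  miss <- setdiff(gwas_required_cols, names(df))
  if (length(miss) > 0L) {
    stop_midrp("%s lacks column(s): %s", label, paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$variant_id)) {
    stop_midrp("%s: duplicated variant_id", label)
  }
  if (any(df$se <= 0)) stop_midrp("%s: se must be > 0", label)
  df
}

#' Instrument strength and frequency filter
#'
#' Keeps variants whose exposure association p-value is at most
#' \code{p_max} and whose minor allele frequency is at least \code{maf_min}.
#'
#' @param exposure GWAS summary-statistics data.frame.
#' @param p_max association p-value ceiling (default 1e-5).
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @return filtered data.frame (warns when empty).
#' @export
filter_instruments <- function(exposure, p_max = 1e-5, maf_min = 0.01) {
  maf <- pmin(exposure$eaf, 1 - exposure$eaf)
  out <- exposure[exposure$pval <= p_max & maf >= maf_min, , drop = FALSE]
  if (nrow(out) == 0L) warn_midrp("no instruments survive filtering")
  rownames(out) <- NULL
  out
}

#' Remove known-confounder SNPs
#'
#' Drops instruments listed in a user-supplied exclusion file (e.g. SNPs
#' associated with other traits at genome-wide significance in an external
#' database).
#'
#' @param instruments GWAS data.frame.
#' @param exclusion_list character vector of variant ids to drop.
#' @return data.frame with attribute \code{n_excluded}.
#' @export
exclude_confounder_snps <- function(instruments, exclusion_list) {
  drop <- instruments$variant_id %in% exclusion_list
  out <- instruments[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warn_midrp("all instruments excluded as confounders")
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending exposure p-value and keeps a variant
#' unless its r^2 with an already-kept variant within \code{window_kb}
#' exceeds \code{r2_max}. An in-window pair with no LD entry is treated as
#' r^2 = 1 (a pair whose independence cannot be verified is never kept).
#'
#' @param instruments GWAS data.frame with a \code{pos} column (base pairs)
#'   or accompanied by \code{positions} (named vector, bp).
#' @param ld data.frame with columns variant_id_1, variant_id_2, r2
#'   (symmetric pairs need only one row).
#' @param r2_max clump r^2 threshold (default 0.001).
#' @param window_kb clump distance in kb (default 10000).
#' @param positions optional named numeric vector of bp positions.
#' @return pruned data.frame.
#' @export
ld_clump <- function(instruments, ld, r2_max = 0.001, window_kb = 10000,
                     positions = NULL) {
  if (nrow(instruments) == 0L) return(instruments)
  if (is.null(positions)) {
    if (is.null(instruments$pos)) {
      stop_midrp("ld_clump needs variant positions (pos column or argument)")
    }
    positions <- stats::setNames(instruments$pos, instruments$variant_id)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  r2map <- stats::setNames(ld$r2, key(ld$variant_id_1, ld$variant_id_2))
  ord <- order(instruments$pval)
  kept <- character(0)
  for (i in ord) {
    v <- instruments$variant_id[i]
    ok <- TRUE
    for (k in kept) {
      if (abs(positions[[v]] - positions[[k]]) <= window_kb * 1000) {
        r2 <- r2map[key(v, k)]
        if (is.na(r2)) r2 <- 1           # unverifiable pair: assume linked
        if (r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, v)
  }
  out <- instruments[match(kept, instruments$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  p <- paste(toupper(a1), toupper(a2))
  p %in% c("A T", "T A", "C G", "G C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins on variant id and aligns the outcome effect to the exposure
#' effect allele: when the alleles are swapped the outcome beta is negated
#' (and eaf flipped); palindromic (A/T, C/G) variants and irreconcilable
#' allele pairs are dropped with a report.
#'
#' @param exposure,outcome GWAS data.frames.
#' @return data.frame of class \code{instrument_set} with columns
#'   variant_id, beta_x, se_x, beta_y, se_y and attribute \code{dropped}
#'   (data.frame of variant_id, reason).
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)
  pal <- is_palindromic(ea_x, oa_x)
  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  bad <- !pal & !same & !swap
  beta_y <- ifelse(swap, -ou$beta, ou$beta)
  keep <- !pal & !bad
  dropped <- data.frame(
    variant_id = c(shared[pal], shared[bad]),
    reason = c(rep("palindromic", sum(pal)),
               rep("allele_mismatch", sum(bad))),
    stringsAsFactors = FALSE)
  out <- data.frame(variant_id = shared[keep],
                    beta_x = ex$beta[keep], se_x = ex$se[keep],
                    beta_y = beta_y[keep], se_y = ou$se[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Inverse-variance-weighted MR estimate
#'
#' Per-variant Wald ratios r_k = beta_y / beta_x with first-order variance
#' v_k = se_y^2 / beta_x^2 are pooled as beta = sum(r_k/v_k) / sum(1/v_k),
#' se = sqrt(1 / sum(1/v_k)), with a two-sided normal p-value. Variants with
#' beta_x = 0 are excluded with a warning.
#'
#' @param instruments an \code{instrument_set} (or data.frame with beta_x,
#'   se_x, beta_y, se_y).
#' @return list of class \code{mr_estimate}: beta, se, pval, n_snp.
#' @export
ivw <- function(instruments) {
  zero <- instruments$beta_x == 0
  if (any(zero)) {
    warn_midrp("%d instrument(s) with zero exposure beta excluded",
               sum(zero))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  if (nrow(instruments) == 0L) {
    stop_midrp("no usable instruments for IVW estimation")
  }
  ratio <- instruments$beta_y / instruments$beta_x
  v <- instruments$se_y^2 / instruments$beta_x^2
  w <- 1 / v
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(list(beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 n_snp = nrow(instruments)),
            class = "mr_estimate")
}

#' Fixed-effect meta-analysis of two MR estimates
#'
#' Precision-weighted pooling with Cochran's Q (1 degree of freedom for two
#' studies), I^2 = max(0, (Q - 1)/Q) on the [0, 1] fraction scale, and a
#' normal-approximation confidence interval.
#'
#' @param est1,est2 \code{mr_estimate} objects (or lists with beta, se).
#' @param conf_level confidence level of the pooled interval (default 0.95).
#' @return list of class \code{meta_result}: pooled_beta, pooled_se,
#'   fixed_p, ci_low, ci_high, Q, het_p, I2.
#' @export
fixed_effect_meta <- function(est1, est2, conf_level = 0.95) {
  b <- c(est1$beta, est2$beta)
  w <- 1 / c(est1$se, est2$se)^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  Q <- sum(w * (b - pooled)^2)
  df <- 1L
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(pooled_beta = pooled, pooled_se = pooled_se,
                 fixed_p = 2 * stats::pnorm(-abs(pooled / pooled_se)),
                 ci_low = pooled - zq * pooled_se,
                 ci_high = pooled + zq * pooled_se,
                 Q = Q,
                 het_p = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = max(0, (Q - df) / Q)),
            class = "meta_result")
}

#' Four-part causal decision rule
#'
#' An exposure is called causal iff the meta-analysis fixed-effect p-value
#' is below \code{p_fixed}, I^2 is below \code{i2_max}, the heterogeneity
#' p-value exceeds \code{het_p_min}, and the confidence interval excludes
#' zero. Failing criteria are enumerated in reason codes.
#'
#' @param meta a \code{meta_result}.
#' @param p_fixed fixed-effect p threshold (default 0.05).
#' @param i2_max I^2 ceiling on the fraction scale (default 0.05; set
#'   \code{i2_scale = "percent"} to interpret it on the 0-100 scale).
#' @param het_p_min heterogeneity-p floor (default 0.05).
#' @param i2_scale "fraction" or "percent".
#' @return list with \code{causal} (logical) and \code{reasons} (character
#'   codes of failed criteria; empty when causal).
#' @export
decide_causal <- function(meta, p_fixed = 0.05, i2_max = 0.05,
                          het_p_min = 0.05, i2_scale = c("fraction",
                                                         "percent")) {
  i2_scale <- match.arg(i2_scale)
  i2 <- if (i2_scale == "percent") meta$I2 * 100 else meta$I2
  reasons <- character(0)
  if (!(meta$fixed_p < p_fixed)) reasons <- c(reasons, "fixed_p")
  if (!(i2 < i2_max)) reasons <- c(reasons, "heterogeneity_i2")
  if (!(meta$het_p > het_p_min)) reasons <- c(reasons, "heterogeneity_p")
  if (!(meta$ci_high < 0 || meta$ci_low > 0)) {
    reasons <- c(reasons, "ci_spans_zero")
  }
  list(causal = length(reasons) == 0L, reasons = reasons)
}

#' Run the full MR pipeline for one exposure against one outcome
#' @param exposure exposure GWAS data.frame.
#' @param outcome outcome GWAS data.frame.
#' @param ld LD table (NULL skips clumping).
#' @param exclusion_list confounder SNP ids.
#' @param p_max,maf_min,r2_max,window_kb pipeline thresholds.
#' @return \code{mr_estimate}, or NULL when no instruments survive.
#' @export
mr_single <- function(exposure, outcome, ld = NULL,
                      exclusion_list = character(0), p_max = 1e-5,
                      maf_min = 0.01, r2_max = 0.001, window_kb = 10000) {
  ins <- filter_instruments(exposure, p_max, maf_min)
  ins <- exclude_confounder_snps(ins, exclusion_list)
  if (!is.null(ld)) ins <- ld_clump(ins, ld, r2_max, window_kb)
  harm <- harmonize(ins, outcome)
  if (nrow(harm) == 0L) return(NULL)
  ivw(harm)
}

#' Auto-select causally linked features
#'
#' For every candidate feature: instrument pipeline against each of the two
#' outcome GWAS, IVW on both pairs, fixed-effect meta-analysis, and the
#' four-part decision. Features with no surviving instruments are marked
#' untestable (never causal).
#'
#' @param exposures named list of exposure GWAS data.frames (one per
#'   feature).
#' @param outcome1,outcome2 the two outcome GWAS data.frames.
#' @param ld optional LD table shared by all features.
#' @param exclusion_list confounder SNP ids.
#' @param ... thresholds forwarded to \code{\link{mr_single}} and
#'   \code{\link{decide_causal}}.
#' @return data.frame with one row per feature: IVW betas/ses, pooled
#'   statistics, Q, I2, het_p, decision and reason codes.
#' @export
select_causal_features <- function(exposures, outcome1, outcome2, ld = NULL,
                                   exclusion_list = character(0), ...) {
  dots <- list(...)
  mr_args <- dots[names(dots) %in% c("p_max", "maf_min", "r2_max",
                                     "window_kb")]
  dec_args <- dots[names(dots) %in% c("p_fixed", "i2_max", "het_p_min",
                                      "i2_scale")]
  rows <- lapply(names(exposures), function(feat) {
    e1 <- do.call(mr_single, c(list(exposures[[feat]], outcome1, ld,
                                    exclusion_list), mr_args))
    e2 <- do.call(mr_single, c(list(exposures[[feat]], outcome2, ld,
                                    exclusion_list), mr_args))
    if (is.null(e1) || is.null(e2)) {
      return(data.frame(feature = feat, beta1 = NA, se1 = NA, beta2 = NA,
                        se2 = NA, pooled_beta = NA, pooled_se = NA,
                        fixed_p = NA, ci_low = NA, ci_high = NA, Q = NA,
                        het_p = NA, I2 = NA, causal = FALSE,
                        status = "untestable", reasons = "no_instruments",
                        stringsAsFactors = FALSE))
    }
    meta <- fixed_effect_meta(e1, e2)
    dec <- do.call(decide_causal, c(list(meta), dec_args))
    data.frame(feature = feat, beta1 = e1$beta, se1 = e1$se,
               beta2 = e2$beta, se2 = e2$se,
               pooled_beta = meta$pooled_beta, pooled_se = meta$pooled_se,
               fixed_p = meta$fixed_p, ci_low = meta$ci_low,
               ci_high = meta$ci_high, Q = meta$Q, het_p = meta$het_p,
               I2 = meta$I2, causal = dec$causal, status = "tested",
               reasons = paste(dec$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
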