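# Per-siRNA effect-size statistics for viability screens: survival-rate
# normalization, Cohen's d with a 95% CI, five-bin classification, and
# 2^-ddCt relative quantification.

# Canonical bin labels, ordered from strongest to no effect.
EFFECT_BINS <- c("large", "medium", "small", "very_small", "none")

#' Percent-of-reference survival rates
#'
#' Normalizes raw viability readings to a reference condition, per timepoint:
#' \code{100 * mean(condition) / mean(reference)}. The reference condition
#' maps to 100 at every timepoint by construction.
#'
#' @param readings Data frame with columns \code{condition},
#'   \code{replicate}, \code{timepoint_h}, \code{reading}.
#' @param reference_condition Label of the reference (negative control)
#'   condition.
#' @return Data frame with columns \code{condition}, \code{timepoint_h},
#'   \code{survival_pct}.
#' @export
survival_rate <- function(readings, reference_condition) {
  need <- c("condition", "timepoint_h", "reading")
  if (!all(need %in% names(readings)))
    ox_stop("readings must have columns condition, timepoint_h, reading",
            "invalid_parameter")
  tps <- sort(unique(readings$timepoint_h))
  ref <- readings[readings$condition == reference_condition, , drop = FALSE]
  if (nrow(ref) == 0L)
    ox_stop(sprintf("reference condition '%s' absent", reference_condition),
            "missing_reference")
  ref_mean <- tapply(ref$reading, ref$timepoint_h, mean)
  missing_tp <- setdiff(as.character(tps), names(ref_mean))
  if (length(missing_tp))
    ox_stop(sprintf("reference condition missing at timepoint(s): %s",
                    paste(missing_tp, collapse = ", ")), "missing_reference")
  if (any(ref_mean == 0))
    ox_stop("reference mean reading is zero at some timepoint",
            "missing_reference")
  agg <- stats::aggregate(reading ~ condition + timepoint_h, data = readings,
                          FUN = mean)
  agg$survival_pct <-
    100 * agg$reading / as.numeric(ref_mean[as.character(agg$timepoint_h)])
  agg <- agg[order(agg$condition, agg$timepoint_h),
             c("condition", "timepoint_h", "survival_pct")]
  rownames(agg) <- NULL
  agg
}

#' Cohen's d with a 95% confidence interval
#'
#' Standardized mean difference \code{(mean(test) - mean(control)) / s_p}
#' with the Bessel-corrected two-sample pooled SD
#' \code{s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))}. The 95%
#' CI uses the normal approximation \code{d +/- 1.96 * SE} with
#' \code{SE = sqrt((n1+n2)/(n1*n2) + d^2 / (2 (n1+n2)))}.
#'
#' @param test,control Numeric replicate vectors (each of length >= 2).
#' @return List with \code{delta}, \code{ci_low}, \code{ci_high},
#'   \code{n_test}, \code{n_control}.
#' @export
cohen_delta <- function(test, control) {
  test <- as.numeric(test); control <- as.numeric(control)
  n1 <- length(test); n2 <- length(control)
  if (n1 < 2L || n2 < 2L)
    ox_stop("each sample needs at least 2 replicates", "insufficient_data")
  if (anyNA(test) || anyNA(control) || any(!is.finite(c(test, control))))
    ox_stop("replicate values must be finite", "invalid_parameter")
  diff <- mean(test) - mean(control)
  sp2 <- ((n1 - 1) * stats::var(test) + (n2 - 1) * stats::var(control)) /
    (n1 + n2 - 2)
  sp <- sqrt(sp2)
  if (sp == 0) {
    if (diff != 0)
      ox_stop("zero pooled SD with unequal means: effect size is not finite",
              "infinite_effect")
    d <- 0
  } else {
    d <- diff / sp
  }
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(delta = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
       n_test = n1, n_control = n2)
}

#' Classify an effect size into the screen's five bins
#'
#' Bins: large (0.8, Inf); medium [0.5, 0.8]; small [0.2, 0.5);
#' very_small [0.01, 0.2); none (-Inf, 0.01). The convention keeps the
#' endpoint descriptions ">0.8" and "<0.01" literal; negative effects
#' (siRNAs reducing survival) classify by signed value and so fall in
#' "none" — the screen selects protection, not harm.
#'
#' @param delta Numeric vector of Cohen's d values (finite).
#' @return Character vector of bin labels.
#' @export
classify_effect <- function(delta) {
  if (any(!is.finite(delta)))
    ox_stop("delta must be finite", "invalid_input")
  ifelse(delta > 0.8, "large",
    ifelse(delta >= 0.5, "medium",
      ifelse(delta >= 0.2, "small",
        ifelse(delta >= 0.01, "very_small", "none"))))
}

#' Per-siRNA effect sizes across a screen
#'
#' Computes Cohen's d (test siRNA vs negative control), its 95% CI and bin
#' label for every (siRNA, timepoint) combination. Effects are computed per
#' timepoint; there is no cross-timepoint pooling.
#'
#' @inheritParams survival_rate
#' @param control_condition Label of the negative-control condition.
#' @return Data frame of class \code{screen_effects} with columns
#'   \code{sirna_id}, \code{timepoint_h}, \code{delta}, \code{ci_low},
#'   \code{ci_high}, \code{n_test}, \code{n_control}, \code{bin}.
#' @export
screen_effects <- function(readings, control_condition) {
  tps <- sort(unique(readings$timepoint_h))
  ids <- sort(setdiff(unique(readings$condition), control_condition))
  rows <- vector("list", length(ids) * length(tps))
  i <- 0L
  for (tp in tps) {
    ctl <- readings$reading[readings$condition == control_condition &
                              readings$timepoint_h == tp]
    for (id in ids) {
      tst <- readings$reading[readings$condition == id &
                                readings$timepoint_h == tp]
      cd <- cohen_delta(tst, ctl)
      i <- i + 1L
      rows[[i]] <- data.frame(sirna_id = id, timepoint_h = tp,
                              delta = cd$delta, ci_low = cd$ci_low,
                              ci_high = cd$ci_high, n_test = cd$n_test,
                              n_control = cd$n_control,
                              bin = classify_effect(cd$delta),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sirna_id, out$timepoint_h), ]
  rownames(out) <- NULL
  class(out) <- c("screen_effects", "data.frame")
  out
}

#' @export
print.screen_effects <- function(x, ...) {
  cat(sprintf("Screen effect sizes: %d siRNAs x %d timepoints\n",
              length(unique(x$sirna_id)), length(unique(x$timepoint_h))))
  NextMethod()
}

#' @export
summary.screen_effects <- function(object, ...) {
  tp <- min(object$timepoint_h)
  counts <- summarize_screen(object, tp)
  cat(sprintf("Bin counts at %g h:\n", tp))
  print(counts)
  invisible(counts)
}

#' Count siRNAs per effect-size bin at one timepoint
#'
#' @param results A \code{screen_effects} data frame.
#' @param timepoint Timepoint (hours) to tally.
#' @return Named integer vector over the five bins; sums to the number of
#'   distinct siRNAs at that timepoint.
#' @export
summarize_screen <- function(results, timepoint) {
  sub <- results[results$timepoint_h == timepoint, , drop = FALSE]
  if (nrow(sub) == 0L)
    ox_stop(sprintf("no results at timepoint %s", timepoint),
            "invalid_parameter")
  tab <- table(factor(sub$bin, levels = EFFECT_BINS))
  out <- as.integer(tab)
  names(out) <- EFFECT_BINS
  out
}

#' Relative fold change by the 2^-ddCt method
#'
#' \code{ddCt = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control};
#' the returned fold change is \code{2^-ddCt}, so \code{-log2(result)}
#' recovers ddCt exactly.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (finite, positive). The reference is the
#'   endogenous control transcript (e.g. cyclophilin A / PPIA).
#' @return Relative fold change (dimensionless).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    ox_stop("all four Ct values must be finite and positive",
            "invalid_parameter")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
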