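# Population-level quantification: proportions, modified Wald confidence
# intervals, Fisher exact comparisons, threshold calibration, spot-count
# histograms.

#' Modified Wald (Agresti-Coull) confidence interval for a proportion
#'
#' Computes the binomial proportion interval built on the adjusted estimate
#' `p~ = (x + 2) / (n + 4)` with normal half-width
#' `z * sqrt(p~ (1 - p~) / (n + 4))`, clipped to `[0, 1]`. For the default
#' 95% level the conventional `z = 1.96` is used (the add-2-successes /
#' add-2-failures form); other levels use the corresponding normal quantile.
#'
#' @param x Number of successes (`0 <= x <= n`).
#' @param n Number of trials (`> 0`).
#' @param confidence Confidence level, default `0.95`.
#' @return Named numeric vector `c(low, high)` as fractions.
#' @export
#' @examples
#' round(100 * modified_wald_ci(2571, 2695), 1)   # 94.5 96.1
#' round(100 * modified_wald_ci(277, 11753), 2)   # 2.10 2.65
modified_wald_ci <- function(x, n, confidence = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n <= 0 || x < 0 || x > n) {
    stop("need 0 <= x <= n and n > 0", call. = FALSE)
  }
  stopifnot(confidence > 0, confidence < 1)
  z <- if (isTRUE(all.equal(confidence, 0.95))) 1.96 else
    stats::qnorm(1 - (1 - confidence) / 2)
  pt <- (x + 2) / (n + 4)
  hw <- z * sqrt(pt * (1 - pt) / (n + 4))
  c(low = max(0, pt - hw), high = min(1, pt + hw))
}

#' Format a fraction as a percentage string
#'
#' Percentages below 1% are printed with two significant figures and larger
#' ones with three, mirroring common reporting precision for rare-event
#' frequencies; the raw fraction should always be carried alongside.
#'
#' @param p Fraction in `[0, 1]`.
#' @return Character vector like `"0.66%"` or `"95.4%"`.
#' @export
format_percent <- function(p) {
  pct <- 100 * p
  out <- ifelse(pct < 1, signif(pct, 2), signif(pct, 3))
  paste0(out, "%")
}

#' Proportion of event-positive nuclei
#'
#' @param summaries Per-nucleus event table as returned in
#'   `call_events()$nuclei` (QC-failing nuclei are dropped from the
#'   denominator).
#' @param event_class `"breakage"` or `"translocation"`.
#' @return List with `n_positive`, `n_total`, `proportion` and `percent`
#'   (formatted string).
#' @export
proportion_positive <- function(summaries,
                                event_class = c("breakage",
                                                "translocation")) {
  event_class <- match.arg(event_class)
  ok <- summaries[summaries$qc_pass, , drop = FALSE]
  n <- nrow(ok)
  if (n == 0L) stop("no QC-passing nuclei in this condition", call. = FALSE)
  pos <- sum(ok[[paste0(event_class, "_positive")]])
  p <- pos / n
  list(n_positive = pos, n_total = n, proportion = p,
       percent = format_percent(p))
}

#' Summarize one condition
#'
#' Event-positive proportion with its modified Wald confidence interval, as
#' one tidy row per condition and event class.
#'
#' @param summaries Per-nucleus event table (`call_events()$nuclei`).
#' @param label Condition label.
#' @param event_class `"breakage"` or `"translocation"`.
#' @param confidence CI level.
#' @return One-row data frame: `condition`, `event_class`,
#'   `n_nuclei_analyzed`, `n_positive`, `proportion`, `percent`, `ci_low`,
#'   `ci_high`.
#' @export
summarize_condition <- function(summaries, label,
                                event_class = c("breakage",
                                                "translocation"),
                                confidence = 0.95) {
  event_class <- match.arg(event_class)
  pp <- proportion_positive(summaries, event_class)
  ci <- modified_wald_ci(pp$n_positive, pp$n_total, confidence)
  data.frame(condition = label, event_class = event_class,
             n_nuclei_analyzed = pp$n_total, n_positive = pp$n_positive,
             proportion = pp$proportion, percent = pp$percent,
             ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
             stringsAsFactors = FALSE)
}

#' Fisher exact comparison of two conditions
#'
#' Two-sided Fisher exact test on the 2x2 table of event-positive /
#' event-negative nuclei in two conditions, using the standard count-data
#' convention (two-sided p-value as the sum of hypergeometric probabilities
#' of tables at most as probable as the observed one).
#'
#' @param a_pos,a_neg Positive / negative counts in the reference condition.
#' @param b_pos,b_neg Positive / negative counts in the comparison condition.
#' @return List of class `ba_comparison`: `table` (2x2 matrix), `p_value`,
#'   `fold_change` (ratio of positive proportions, comparison over
#'   reference; `NA` when the reference proportion is zero).
#' @export
#' @examples
#' fisher_exact_comparison(5, 5, 5, 5)$p_value   # 1
fisher_exact_comparison <- function(a_pos, a_neg, b_pos, b_neg) {
  counts <- c(a_pos, a_neg, b_pos, b_neg)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (a_pos + a_neg == 0 || b_pos + b_neg == 0) {
    stop("both conditions must contain nuclei", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(condition = c("a", "b"),
                                outcome = c("positive", "negative")))
  p <- stats::fisher.test(tab)$p.value
  pa <- a_pos / (a_pos + a_neg)
  pb <- b_pos / (b_pos + b_neg)
  fc <- if (pa > 0) pb / pa else NA_real_
  structure(list(table = tab, p_value = p, fold_change = fc),
            class = "ba_comparison")
}

#' Calibrate the proximity threshold from a negative-control condition
#'
#' Given the per-Red minimum Red/Green distances measured in a condition not
#' expected to contain breaks (post-QC), returns the smallest integer pixel
#' threshold `t` such that at least a `coverage` fraction of the distances
#' are `<= t`. With the default coverage of 99.8% this reproduces the
#' empirical choice of a 4-pixel threshold on the original calibration data.
#'
#' @param rg_min_distances Numeric vector of per-Red minimum Red/Green
#'   distances in pixels.
#' @param coverage Fraction of the distribution the threshold must cover.
#' @return Integer threshold in pixels.
#' @export
#' @examples
#' calibrate_threshold(c(rep(0.5, 998), 10, 12), coverage = 0.998)
calibrate_threshold <- function(rg_min_distances, coverage = 0.998) {
  if (length(rg_min_distances) == 0L) {
    stop("no distances supplied; a negative-control condition is required",
         call. = FALSE)
  }
  stopifnot(coverage > 0, coverage <= 1, all(rg_min_distances >= 0))
  for (t in seq_len(max(ceiling(max(rg_min_distances)), 1))) {
    if (mean(rg_min_distances <= t) >= coverage) return(t)
  }
  ceiling(max(rg_min_distances))
}

#' Spot-count histogram per channel
#'
#' Frequency of nuclei carrying 0, 1, 2, ... spots of one channel, over all
#' non-excluded nuclei (before the event-calling QC filter, so that missed
#' and extra detections remain visible). The first bin counts nuclei with
#' zero spots.
#'
#' @param nuclei Nucleus table (with `excluded` flags if available).
#' @param spots Spot table with `nucleus_id`, `channel` (and `field_id` when
#'   multiple fields are concatenated).
#' @param channel `"Green"`, `"Red"` or `"FarRed"`.
#' @return Data frame `n_spots`, `n_nuclei`, `frequency`; zero rows for an
#'   empty nucleus list.
#' @export
spot_count_histogram <- function(nuclei, spots,
                                 channel = c("Green", "Red", "FarRed")) {
  channel <- match.arg(channel)
  if ("excluded" %in% names(nuclei)) {
    nuclei <- nuclei[!nuclei$excluded, , drop = FALSE]
  }
  if (!nrow(nuclei)) {
    return(data.frame(n_spots = integer(0), n_nuclei = integer(0),
                      frequency = numeric(0)))
  }
  if (!"field_id" %in% names(nuclei)) nuclei$field_id <- "f001"
  if (!"field_id" %in% names(spots)) spots$field_id <- "f001"
  sp <- spots[spots$channel == channel, , drop = FALSE]
  key <- function(f, n) paste(f, n, sep = "\r")
  cnt <- table(factor(key(sp$field_id, sp$nucleus_id),
                      levels = key(nuclei$field_id, nuclei$nucleus_id)))
  tab <- table(as.integer(cnt))
  data.frame(n_spots = as.integer(names(tab)),
             n_nuclei = as.integer(tab),
             frequency = as.integer(tab) / nrow(nuclei))
}
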