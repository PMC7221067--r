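# 5-min segmentation of a corrected trace into (mass-corrected MR,
# activity index) points, and the standard-metabolic-rate extractor.

# per-sample mass-corrected metabolic rate over the fly segment
mr_series <- function(ct, rq = 1,
                      joule_coefficient = oxyjoule_coefficient(rq),
                      mass_exponent = 0.856) {
  flux <- ppm_to_flux(ct$co2_excess_ppm, ct$flow_ml_min)
  power <- flux_to_power(flux, rq = rq, joule_coefficient = joule_coefficient,
                         allow_negative = TRUE)
  mass_correct(power, ct$live_mass_mg, exponent = mass_exponent)
}

#' Summarize a recording into 5-min metabolic segments
#'
#' Tiles the baseline-corrected fly segment into consecutive,
#' non-overlapping windows of `segment_s` samples (default 300 s = 5 min).
#' Each window is reduced to its mean mass-corrected metabolic rate
#' (full chain: baseline correction, ppm to uL/h, uL/h to uW at the given
#' RQ, allometric mass correction) and its activity index. A trailing
#' partial window is dropped.
#'
#' @param trace A [resp_trace()].
#' @param segment_s Window length in seconds. Default 300.
#' @param rq,joule_coefficient,mass_exponent Conversion-chain parameters,
#'   see [flux_to_power()] and [mass_correct()].
#' @return A tibble with one row per segment: `fly_id`, `genotype`,
#'   `age_class`, `segment`, `t_start_s`, `mean_mr` (uW mg^-exponent) and
#'   `activity_index`. Empty (with a warning) if the fly segment is shorter
#'   than one window.
#' @export
segment_metrics <- function(trace, segment_s = 300, rq = 1,
                            joule_coefficient = oxyjoule_coefficient(rq),
                            mass_exponent = 0.856) {
  stopifnot(inherits(trace, "resp_trace"), segment_s >= 2)
  ct <- baseline_correct(trace)
  n_fly <- length(ct$co2_excess_ppm)
  k <- n_fly %/% segment_s
  empty <- tibble::tibble(fly_id = character(), genotype = character(),
                          age_class = character(), segment = integer(),
                          t_start_s = numeric(), mean_mr = numeric(),
                          activity_index = numeric())
  if (k == 0) {
    warning("fly segment (", n_fly, " s) shorter than one ", segment_s,
            "-s window; returning no segments")
    return(empty)
  }
  mr <- mr_series(ct, rq = rq, joule_coefficient = joule_coefficient,
                  mass_exponent = mass_exponent)
  used <- k * segment_s
  win <- rep(seq_len(k), each = segment_s)
  mean_mr <- as.numeric(tapply(mr[seq_len(used)], win, mean))
  act <- ct$activity[seq_len(used)]
  idx <- vapply(seq_len(k), function(w) {
    a <- act[((w - 1) * segment_s + 1):(w * segment_s)]
    activity_index(compute_ads(a), segment_s)
  }, numeric(1))

  tibble::tibble(
    fly_id = trace$fly_id,
    genotype = trace$genotype,
    age_class = trace$age_class,
    segment = seq_len(k),
    t_start_s = ct$time_s[seq(1, used, by = segment_s)],
    mean_mr = mean_mr,
    activity_index = idx
  )
}

#' Standard metabolic rate of a recording
#'
#' SMR is estimated as the lowest running-average mass-corrected metabolic
#' rate among quiescent windows: sliding windows of `window_s` samples
#' (step 1 s) over the fly segment, restricted to windows whose activity
#' index falls in the lowest `quiescence_quantile` of all windows of the
#' recording. If no window qualifies the global minimum sliding-window mean
#' is returned and flagged.
#'
#' @param trace A [resp_trace()].
#' @param window_s Sliding-window length in seconds. Default 300.
#' @param quiescence_quantile Quantile of window activity indices defining
#'   quiescence. Default 0.2.
#' @inheritParams segment_metrics
#' @return A scalar SMR in uW mg^-exponent, with attributes `window_s`,
#'   `quiescence_quantile`, `fallback` (TRUE when no quiescent window
#'   qualified) and `window_activity_index` (index of the selected window).
#' @export
standard_metabolic_rate <- function(trace, window_s = 300,
                                    quiescence_quantile = 0.2, rq = 1,
                                    joule_coefficient = oxyjoule_coefficient(rq),
                                    mass_exponent = 0.856) {
  stopifnot(inherits(trace, "resp_trace"), window_s >= 2,
            quiescence_quantile > 0, quiescence_quantile <= 1)
  ct <- baseline_correct(trace)
  n <- length(ct$co2_excess_ppm)
  if (n < window_s) {
    stop("fly segment (", n, " s) shorter than one ", window_s, "-s window")
  }
  mr <- mr_series(ct, rq = rq, joule_coefficient = joule_coefficient,
                  mass_exponent = mass_exponent)

  # sliding means via cumulative sums; window i covers samples i..i+w-1
  w <- as.integer(window_s)
  cs <- cumsum(mr)
  means <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
  d <- abs(diff(ct$activity))            # n-1 per-sample increments
  csd <- cumsum(d)
  # diffs inside window i are d[i .. i+w-2], i.e. w-1 of them
  sums <- csd[(w - 1):(n - 1)] - c(0, csd[seq_len(n - w)])
  idx <- sums / w * 60

  thr <- stats::quantile(idx, quiescence_quantile, names = FALSE)
  quiescent <- which(idx <= thr)
  fallback <- length(quiescent) == 0
  pool <- if (fallback) seq_along(means) else quiescent
  best <- pool[which.min(means[pool])]

  structure(means[best],
            window_s = w,
            quiescence_quantile = quiescence_quantile,
            fallback = fallback,
            window_activity_index = idx[best],
            class = c("smr", "numeric"))
}

#' @export
print.smr <- function(x, ...) {
  cat("SMR: ", format(unclass(x)[1]), " uW mg^-e  (window ",
      attr(x, "window_s"), " s, quiescence quantile ",
      attr(x, "quiescence_quantile"),
      if (isTRUE(attr(x, "fallback"))) ", FALLBACK: global minimum" else "",
      ")\n", sep = "")
  invisible(x)
}
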