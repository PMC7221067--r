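# Baseline drift correction: empty-chamber windows flank the fly segment;
# analyzer drift over the recording is removed assuming it is linear.

#' Subtract a linearly drifting CO2 baseline
#'
#' Fits the drift as the straight line through the two points
#' (center of pre-window, mean pre-window ppm) and
#' (center of post-window, mean post-window ppm), then subtracts it from the
#' raw CO2 channel over the fly segment. Negative corrected values are
#' retained, not clipped, so later averaging is unbiased. An alternative fit
#' (ordinary least squares over all baseline samples) is available via
#' `method = "ols"`.
#'
#' By construction of the two-point method, the corrected series has zero
#' mean over each baseline window.
#'
#' @param trace A [resp_trace()].
#' @param method `"two_point"` (default) or `"ols"`.
#' @return An object of class `corrected_trace`: the fly-segment time and
#'   CO2 excess series, the fitted drift line (intercept, slope in ppm and
#'   ppm/s), and the trace metadata carried through.
#' @export
baseline_correct <- function(trace, method = c("two_point", "ols")) {
  stopifnot(inherits(trace, "resp_trace"))
  method <- match.arg(method)
  ppm <- trace$data$co2_ppm
  tt <- trace$data$time_s
  if (any(!is.finite(ppm))) {
    stop("non-finite CO2 value at index ", which(!is.finite(ppm))[1])
  }
  pre <- trace$baseline_pre[1]:trace$baseline_pre[2]
  post <- trace$baseline_post[1]:trace$baseline_post[2]
  if (length(pre) < 1) stop("baseline window `baseline_pre` is empty")
  if (length(post) < 1) stop("baseline window `baseline_post` is empty")

  if (method == "two_point") {
    c_pre <- mean(tt[pre]); m_pre <- mean(ppm[pre])
    c_post <- mean(tt[post]); m_post <- mean(ppm[post])
    slope <- (m_post - m_pre) / (c_post - c_pre)
    intercept <- m_pre - slope * c_pre
  } else {
    fit <- stats::lm.fit(cbind(1, tt[c(pre, post)]), ppm[c(pre, post)])
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  }

  fly <- fly_segment_idx(trace)
  excess <- ppm[fly] - (intercept + slope * tt[fly])

  structure(
    list(
      time_s = tt[fly],
      co2_excess_ppm = excess,
      drift_intercept_ppm = unname(intercept),
      drift_slope_ppm_per_s = unname(slope),
      method = method,
      flow_ml_min = trace$flow_ml_min,
      fly_id = trace$fly_id,
      genotype = trace$genotype,
      age_class = trace$age_class,
      live_mass_mg = trace$live_mass_mg,
      activity = trace$data$activity[fly]
    ),
    class = "corrected_trace"
  )
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat("<corrected_trace> ", x$fly_id, ": ", length(x$co2_excess_ppm),
      " s fly segment\n  drift line: ", format(x$drift_intercept_ppm),
      " ppm + ", format(x$drift_slope_ppm_per_s), " ppm/s (",
      x$method, ")\n", sep = "")
  invisible(x)
}
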