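# RespTrace container: one synchronized 1-Hz recording plus annotations.

#' Construct a respirometry trace
#'
#' Bundles the synchronized 1-Hz channels of one recording (CO2 in ppm,
#' activity analog, chamber temperature) with its acquisition metadata:
#' STP-corrected flow rate, the index ranges of the two empty-chamber
#' baseline windows that flank the fly segment, and per-fly annotations.
#'
#' @param time_s Integer-valued time in seconds, strictly increasing with
#'   unit step (1 Hz acquisition).
#' @param co2_ppm CO2 channel in ppm.
#' @param activity Activity analog channel (arbitrary units).
#' @param temp_C Chamber temperature channel; a scalar is recycled.
#' @param flow_ml_min STP-corrected flow rate in mL/min, > 0.
#' @param baseline_pre,baseline_post Length-2 integer vectors `c(first, last)`
#'   of 1-based sample indices of the empty-chamber windows. The fly segment
#'   is everything strictly between them.
#' @param fly_id,genotype Character labels.
#' @param age_class `"young"` or `"old"`.
#' @param live_mass_mg Live mass in mg, > 0.
#' @param truth Optional named list of ground-truth generator parameters
#'   (carried by synthetic traces so tests never re-derive them).
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(time_s, co2_ppm, activity, temp_C = 25,
                       flow_ml_min, baseline_pre, baseline_post,
                       fly_id = "fly1", genotype = "control",
                       age_class = c("young", "old"),
                       live_mass_mg, truth = NULL) {
  age_class <- match.arg(age_class)
  n <- length(time_s)
  stopifnot(length(co2_ppm) == n, length(activity) == n)
  if (length(temp_C) == 1) temp_C <- rep(temp_C, n)
  stopifnot(length(temp_C) == n)

  dt <- diff(time_s)
  if (n < 2 || any(dt != 1)) {
    bad <- if (n < 2) 1L else which(dt != 1)[1]
    stop("time_s must increase in unit (1 s) steps; first violation at ",
         "index ", bad + 1L)
  }
  if (!is.finite(flow_ml_min) || flow_ml_min <= 0) {
    stop("flow_ml_min must be positive")
  }
  if (!is.finite(live_mass_mg) || live_mass_mg <= 0) {
    stop("live_mass_mg must be positive")
  }
  check_window <- function(w, name) {
    if (length(w) != 2 || any(!is.finite(w)) || w[1] > w[2] ||
        w[1] < 1 || w[2] > n) {
      stop("baseline window `", name, "` must be c(first, last) within 1..",
           n)
    }
    as.integer(w)
  }
  baseline_pre <- check_window(baseline_pre, "baseline_pre")
  baseline_post <- check_window(baseline_post, "baseline_post")
  if (baseline_pre[2] >= baseline_post[1]) {
    stop("baseline windows must be disjoint with the pre window first")
  }
  if (baseline_post[1] - baseline_pre[2] < 2) {
    stop("no fly segment between the baseline windows")
  }

  structure(
    list(
      data = tibble::tibble(time_s = as.numeric(time_s),
                            co2_ppm = as.numeric(co2_ppm),
                            activity = as.numeric(activity),
                            temp_C = as.numeric(temp_C)),
      flow_ml_min = as.numeric(flow_ml_min),
      baseline_pre = baseline_pre,
      baseline_post = baseline_post,
      fly_id = as.character(fly_id),
      genotype = as.character(genotype),
      age_class = age_class,
      live_mass_mg = as.numeric(live_mass_mg),
      truth = truth
    ),
    class = "resp_trace"
  )
}

# 1-based indices of the fly segment (strictly between the baseline windows)
fly_segment_idx <- function(trace) {
  (trace$baseline_pre[2] + 1L):(trace$baseline_post[1] - 1L)
}

#' @export
print.resp_trace <- function(x, ...) {
  n <- nrow(x$data)
  fly <- fly_segment_idx(x)
  cat("<resp_trace> ", x$fly_id, " (", x$genotype, ", ", x$age_class,
      ", ", format(x$live_mass_mg), " mg)\n", sep = "")
  cat("  ", n, " samples @ 1 Hz; flow ", format(x$flow_ml_min),
      " mL/min\n", sep = "")
  cat("  baselines [", x$baseline_pre[1], "-", x$baseline_pre[2], "] and [",
      x$baseline_post[1], "-", x$baseline_post[2], "]; fly segment ",
      length(fly), " s\n", sep = "")
  if (!is.null(x$truth)) cat("  carries synthetic ground truth\n")
  invisible(x)
}
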