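# Synthetic data with known ground truth: respirometry traces (drifting
# baseline + resting signal + activity-coupled component + noise), Gompertz
# survival cohorts, and climbing trials. All generators are pure functions
# of (spec, seed).

#' Specification of a synthetic respirometry recording
#'
#' Parameterizes [gen_resp_trace()]. The fly segment sits between two
#' empty-chamber baseline windows; activity follows a two-state
#' (rest/active) telegraph process with accelerometer-like jitter during
#' active states; metabolic power is `smr_uW` plus an activity-coupled
#' component with true slope `activity_coupling_uW` per activity-index
#' unit; the CO2 channel back-converts power through the exact inverse of
#' the ppm-to-uW chain and adds a linearly drifting baseline and Gaussian
#' analyzer noise.
#'
#' @param duration_s Total recording length in seconds. Default 1800.
#' @param baseline_pre_s,baseline_post_s Empty-chamber window lengths, s.
#' @param baseline_level_ppm Baseline CO2 level at t = 0, ppm.
#' @param drift_ppm_per_s Linear analyzer drift.
#' @param smr_uW True resting metabolic power, uW, > 0.
#' @param activity_coupling_uW True slope of power over activity index,
#'   uW per index unit, >= 0.
#' @param bout_rate_per_min Rest-to-active transition rate, bouts/min.
#' @param bout_mean_s Mean active-bout duration, s.
#' @param activity_amp Amplitude of the activity analog during bouts.
#' @param noise_sd_ppm SD of Gaussian analyzer noise on the CO2 channel.
#' @param mass_mg Live mass, mg.
#' @param flow_ml_min STP-corrected flow, mL/min. Default 50.
#' @param seed Integer seed; identical (spec, seed) give identical traces.
#' @param fly_id,genotype,age_class Labels stamped on the trace.
#' @param grid_s Alignment grid for the activity-coupled component, s
#'   (default 300, the segment length used throughout); see
#'   [gen_resp_trace()].
#' @return A `resp_synth_spec` list.
#' @export
resp_synth_spec <- function(duration_s = 1800L,
                            baseline_pre_s = 180L, baseline_post_s = 180L,
                            baseline_level_ppm = 5, drift_ppm_per_s = 0.001,
                            smr_uW = 17.637, activity_coupling_uW = 0,
                            bout_rate_per_min = 0.3, bout_mean_s = 60,
                            activity_amp = 1, noise_sd_ppm = 0.1,
                            mass_mg = 1.2, flow_ml_min = 50, seed = 1L,
                            fly_id = "synth1", genotype = "control",
                            age_class = "young", grid_s = 300L) {
  spec <- list(duration_s = as.integer(duration_s),
               baseline_pre_s = as.integer(baseline_pre_s),
               baseline_post_s = as.integer(baseline_post_s),
               baseline_level_ppm = baseline_level_ppm,
               drift_ppm_per_s = drift_ppm_per_s,
               smr_uW = smr_uW,
               activity_coupling_uW = activity_coupling_uW,
               bout_rate_per_min = bout_rate_per_min,
               bout_mean_s = bout_mean_s,
               activity_amp = activity_amp,
               noise_sd_ppm = noise_sd_ppm,
               mass_mg = mass_mg,
               flow_ml_min = flow_ml_min,
               seed = as.integer(seed),
               fly_id = fly_id, genotype = genotype, age_class = age_class,
               grid_s = as.integer(grid_s))
  if (spec$duration_s <= spec$baseline_pre_s + spec$baseline_post_s) {
    stop("inconsistent durations: duration_s (", spec$duration_s,
         ") must exceed baseline_pre_s + baseline_post_s (",
         spec$baseline_pre_s + spec$baseline_post_s, ")")
  }
  if (spec$baseline_level_ppm < 0 || spec$smr_uW <= 0 ||
      spec$activity_coupling_uW < 0 || spec$bout_rate_per_min < 0 ||
      spec$bout_mean_s <= 0 || spec$activity_amp <= 0 ||
      spec$noise_sd_ppm < 0 || spec$mass_mg <= 0 || spec$flow_ml_min <= 0) {
    stop("invalid resp_synth_spec: rates and amplitudes must be ",
         "non-negative, smr_uW/bout_mean_s/activity_amp/mass_mg/flow_ml_min ",
         "positive")
  }
  structure(spec, class = "resp_synth_spec")
}

# Discrete-time two-state telegraph chain at 1 Hz. p_on is the per-second
# rest->active probability, p_off the active->rest probability. Dwell times
# are geometric; draws are batched for speed.
telegraph_states <- function(n, p_on, p_off) {
  if (p_on <= 0) return(integer(n))
  states <- integer(0)
  while (length(states) < n) {
    m <- max(16L, ceiling(2 * n * max(p_on, p_off)))
    rest <- stats::rgeom(m, p_on) + 1L
    act <- stats::rgeom(m, p_off) + 1L
    states <- c(states,
                rep(rep(c(0L, 1L), m), times = as.vector(rbind(rest, act))))
  }
  states[seq_len(n)]
}

#' Generate a synthetic respirometry trace
#'
#' Simulates one recording under a [resp_synth_spec()]. The CO2 channel is
#' `baseline_level + drift * t + noise` throughout and additionally carries
#' the fly's signal during the fly segment: instantaneous power
#' `smr_uW + activity_coupling_uW * m(t)` back-converted to ppm through the
#' exact inverse of the conversion chain, where `m(t)` is the per-sample
#' absolute activity increment scaled to per-minute units (60 |da|). The
#' increment is reset at `grid_s` boundaries of the fly segment so that
#' every `grid_s`-window's mean power equals
#' `smr_uW + activity_coupling_uW * (that window's activity index)` exactly,
#' making both ground-truth parameters identifiable by the analysis chain
#' without bias. Ground truth is stored in the trace's `truth` field.
#'
#' @param spec A [resp_synth_spec()].
#' @return A [resp_trace()] with `truth` metadata.
#' @export
gen_resp_trace <- function(spec) {
  stopifnot(inherits(spec, "resp_synth_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$duration_s
    t <- seq.int(0L, n - 1L)
    pre <- c(1L, spec$baseline_pre_s)
    post <- c(n - spec$baseline_post_s + 1L, n)
    fly <- (pre[2] + 1L):(post[1] - 1L)
    n_fly <- length(fly)

    p_on <- spec$bout_rate_per_min / 60
    p_off <- 1 / spec$bout_mean_s
    state <- telegraph_states(n_fly, p_on, p_off)
    jitter <- stats::rnorm(n_fly)
    act_fly <- spec$activity_amp * state * jitter
    activity <- numeric(n)
    activity[fly] <- act_fly

    # instantaneous activity metric, grid-aligned (see roxygen above)
    m <- c(0, 60 * abs(diff(act_fly)))
    m[seq(1L, n_fly, by = spec$grid_s)] <- 0
    power <- spec$smr_uW + spec$activity_coupling_uW * m

    co2 <- spec$baseline_level_ppm + spec$drift_ppm_per_s * t
    co2[fly] <- co2[fly] + power_to_ppm(power, spec$flow_ml_min)
    if (spec$noise_sd_ppm > 0) {
      co2 <- co2 + stats::rnorm(n, sd = spec$noise_sd_ppm)
    }

    resp_trace(time_s = t, co2_ppm = co2, activity = activity, temp_C = 25,
               flow_ml_min = spec$flow_ml_min,
               baseline_pre = pre, baseline_post = post,
               fly_id = spec$fly_id, genotype = spec$genotype,
               age_class = spec$age_class, live_mass_mg = spec$mass_mg,
               truth = spec[c("smr_uW", "activity_coupling_uW",
                              "drift_ppm_per_s", "baseline_level_ppm",
                              "noise_sd_ppm", "mass_mg", "seed")])
  })
}

#' Specification of a synthetic survival cohort
#'
#' Per-genotype Gompertz mortality with hazard h(t) = a e^(b t); b = 0
#' degenerates to an exponential with rate a. Censoring is administrative
#' (fixed study end) plus independent random loss.
#'
#' @param groups Named list, one entry per genotype, each `c(a = , b = )`
#'   with baseline hazard `a` > 0 (per day) and acceleration `b` >= 0.
#' @param n_per_group Flies per genotype. Default 100.
#' @param censor_prob Probability a fly is lost (censored uniformly before
#'   its death time). Default 0.
#' @param study_end Administrative censoring time; `Inf` disables it.
#' @param time_unit `"days"` or `"hours"`.
#' @param condition Condition label stamped on all records.
#' @param seed Integer seed.
#' @return A `cohort_synth_spec` list.
#' @export
cohort_synth_spec <- function(groups, n_per_group = 100L, censor_prob = 0,
                              study_end = Inf,
                              time_unit = c("days", "hours"),
                              condition = "standard", seed = 1L) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.list(groups), length(groups) >= 1,
            !is.null(names(groups)), all(nzchar(names(groups))),
            n_per_group >= 1, censor_prob >= 0, censor_prob <= 1,
            study_end > 0)
  for (g in names(groups)) {
    p <- groups[[g]]
    if (!all(c("a", "b") %in% names(p)) || p[["a"]] <= 0 || p[["b"]] < 0) {
      stop("group `", g, "`: need Gompertz parameters a > 0 and b >= 0")
    }
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 censor_prob = censor_prob, study_end = study_end,
                 time_unit = time_unit, condition = condition,
                 seed = as.integer(seed)),
            class = "cohort_synth_spec")
}

#' Gompertz survival function
#'
#' S(t) = exp(-(a/b)(e^(bt) - 1)) for b > 0; exp(-a t) when b = 0.
#'
#' @param t Time (same unit as the hazard parameters).
#' @param a Baseline hazard, > 0.
#' @param b Hazard acceleration, >= 0.
#' @return Survival probabilities.
#' @export
gompertz_survival <- function(t, a, b) {
  stopifnot(a > 0, b >= 0)
  if (b == 0) exp(-a * t) else exp(-(a / b) * expm1(b * t))
}

# inverse-CDF sampler: solve S(t) = U for U ~ Unif(0,1)
rgompertz_icdf <- function(n, a, b) {
  u <- stats::runif(n)
  if (b == 0) -log(u) / a else log1p(-(b / a) * log(u)) / b
}

#' Generate a synthetic survival cohort
#'
#' Event times drawn by inverse-CDF from the per-genotype Gompertz survival
#' function; records past `study_end` are administratively censored there,
#' and each fly is independently lost (censored uniformly before death)
#' with probability `censor_prob`.
#'
#' @param spec A [cohort_synth_spec()].
#' @return A [survival_table()] with true parameters in attribute `truth`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_synth_spec"))
  withr::with_seed(spec$seed, {
    rows <- lapply(names(spec$groups), function(g) {
      p <- spec$groups[[g]]
      t_death <- rgompertz_icdf(spec$n_per_group, p[["a"]], p[["b"]])
      lost <- stats::runif(spec$n_per_group) < spec$censor_prob
      t_obs <- ifelse(lost, stats::runif(spec$n_per_group) * t_death, t_death)
      status <- as.integer(!lost)
      admin <- t_obs > spec$study_end
      t_obs[admin] <- spec$study_end
      status[admin] <- 0L
      tibble::tibble(
        fly_id = sprintf("%s_%04d", g, seq_len(spec$n_per_group)),
        genotype = g, condition = spec$condition,
        time = t_obs, status = status)
    })
    tab <- survival_table(do.call(rbind, rows), time_unit = spec$time_unit)
    attr(tab, "truth") <- spec$groups
    tab
  })
}

#' Generate synthetic climbing trials
#'
#' Five trials of per-fly normalized vial heights at the 4-s mark, drawn
#' Gaussian around `true_mean` and clipped to \[0, 1\].
#'
#' @param n_flies Flies per trial.
#' @param true_mean True mean normalized height, in \[0, 1\].
#' @param sd Gaussian SD before clipping, >= 0.
#' @param seed Integer seed.
#' @return A tibble of class `climbing_trials` with columns `trial`, `fly`,
#'   `height`.
#' @export
gen_climbing_trials <- function(n_flies, true_mean, sd, seed = 1L) {
  stopifnot(n_flies >= 1, true_mean >= 0, true_mean <= 1)
  if (sd < 0) stop("sd must be non-negative")
  withr::with_seed(as.integer(seed), {
    h <- pmin(1, pmax(0, stats::rnorm(5L * n_flies, true_mean, sd)))
    out <- tibble::tibble(trial = rep(1:5, each = n_flies),
                          fly = rep(seq_len(n_flies), times = 5),
                          height = h)
    class(out) <- c("climbing_trials", class(out))
    out
  })
}
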