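# End-to-end pipeline: simulate -> respirometry -> survival -> stats.
# A single resolved configuration (serialized next to every output) plus a
# seed reproduces every artifact byte for byte.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default, plus the
#' parameterization of the synthetic demo cohort. Values given in `...`
#' override the defaults (and a structured YAML file can be loaded with
#' [read_pipeline_config()]).
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `pipeline_config`.
#' @details Defaults: RQ 1, oxyjoule coefficient 21.164 J/mL, mass exponent
#'   0.856, flow 50 mL/min, 1-Hz sampling, 300-s segments, SMR window 300 s
#'   at quiescence quantile 0.2, alpha 0.05, Bonferroni correction,
#'   top-decile-mean maximum lifespan, seed 1.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    rq = 1,
    joule_coefficient = oxyjoule_coefficient(1),
    mass_exponent = 0.856,
    segment_s = 300L,
    smr_window_s = 300L,
    smr_quantile = 0.2,
    alpha = 0.05,
    correction = "bonferroni",
    max_lifespan_definition = "top_decile_mean",
    seed = 1L,
    simulate = list(
      n_flies = 4L,
      trace_groups = list(
        control = list(smr_uW = 17.637, activity_coupling_uW = 0),
        mutant = list(smr_uW = 17.637, activity_coupling_uW = 0.5)
      ),
      duration_s = 1800L,
      noise_sd_ppm = 0.5,
      cohort_groups = list(control = c(a = log(2) / 40, b = 0.05),
                           mutant = c(a = log(2) / 55, b = 0.05)),
      n_per_group = 100L,
      climbing = list(n_flies = 25L, true_mean = 0.6, sd = 0.15)
    )
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' File values override defaults; anything in `...` overrides the file
#' (precedence: call > file > defaults).
#'
#' @param path YAML file of config keys.
#' @param ... Final overrides.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, utils::modifyList(vals, list(...)))
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order:
#' * `simulate` — write synthetic traces (CSV + sidecar), a survival
#'   cohort and climbing trials under `out_dir/data/`;
#' * `respire` — segment every trace, extract SMR, and run the
#'   per-group homeostasis regression;
#' * `survive` — KM curve per group, corrected pairwise tests, lifespan
#'   summaries;
#' * `stats` — normality-gated comparison of per-fly SMR between groups
#'   and climbing scores.
#'
#' The resolved configuration is serialized to `out_dir/config.yml` and a
#' log is written to `out_dir/pipeline.log`. Identical (config, seed) give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "respire", "survive", "stats")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  for (d in c(out_dir, data_dir, res_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  atomic_write_yaml(unclass(config), file.path(out_dir, "config.yml"))
  artifacts <- list(config = file.path(out_dir, "config.yml"))
  sim <- config$simulate

  run_stage <- function(name, fun) {
    pipeline_log(log_con, "stage ", name, ": start")
    tryCatch(fun(), error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    pipeline_log(log_con, "stage ", name, ": done")
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    fly_no <- 0L
    for (g in names(sim$trace_groups)) {
      gp <- sim$trace_groups[[g]]
      for (i in seq_len(sim$n_flies)) {
        fly_no <- fly_no + 1L
        spec <- resp_synth_spec(
          duration_s = sim$duration_s,
          smr_uW = gp$smr_uW, activity_coupling_uW = gp$activity_coupling_uW,
          noise_sd_ppm = sim$noise_sd_ppm, mass_mg = 1.2,
          seed = config$seed * 1000L + fly_no,
          fly_id = sprintf("%s_%02d", g, i), genotype = g)
        write_trace(gen_resp_trace(spec),
                    file.path(data_dir, sprintf("trace_%s_%02d.csv", g, i)))
      }
    }
    cohort <- gen_cohort(cohort_synth_spec(
      groups = sim$cohort_groups, n_per_group = sim$n_per_group,
      seed = config$seed))
    write_survival_table(cohort, file.path(data_dir, "cohort.csv"))
    for (k in seq_along(names(sim$trace_groups))) {
      g <- names(sim$trace_groups)[k]
      trials <- gen_climbing_trials(sim$climbing$n_flies,
                                    sim$climbing$true_mean,
                                    sim$climbing$sd,
                                    seed = config$seed * 100L + k)
      atomic_write_csv(as.data.frame(trials),
                       file.path(data_dir, sprintf("climbing_%s.csv", g)))
    }
    artifacts$data <<- data_dir
  })

  if ("respire" %in% stages) run_stage("respire", function() {
    paths <- sort(list.files(data_dir, pattern = "^trace_.*\\.csv$",
                             full.names = TRUE))
    if (length(paths) == 0) stop("no trace CSVs under ", data_dir)
    traces <- lapply(paths, read_trace)
    segs <- do.call(rbind, lapply(traces, segment_metrics,
                                  segment_s = config$segment_s,
                                  rq = config$rq,
                                  joule_coefficient = config$joule_coefficient,
                                  mass_exponent = config$mass_exponent))
    atomic_write_csv(segs, file.path(res_dir, "segments.csv"))
    smr <- do.call(rbind, lapply(traces, function(tr) {
      s <- standard_metabolic_rate(tr, window_s = config$smr_window_s,
                                   quiescence_quantile = config$smr_quantile,
                                   rq = config$rq,
                                   joule_coefficient = config$joule_coefficient,
                                   mass_exponent = config$mass_exponent)
      tibble::tibble(fly_id = tr$fly_id, genotype = tr$genotype,
                     age_class = tr$age_class, smr = as.numeric(s),
                     smr_window_s = attr(s, "window_s"),
                     smr_quantile = attr(s, "quiescence_quantile"),
                     fallback = attr(s, "fallback"))
    }))
    atomic_write_csv(smr, file.path(res_dir, "smr.csv"))
    homeo <- do.call(rbind, lapply(unique(segs$genotype), function(g) {
      homeostasis_regression(segs, group = g, alpha = config$alpha)
    }))
    atomic_write_csv(homeo, file.path(res_dir, "homeostasis.csv"))
    artifacts$segments <<- file.path(res_dir, "segments.csv")
    artifacts$smr <<- file.path(res_dir, "smr.csv")
    artifacts$homeostasis <<- file.path(res_dir, "homeostasis.csv")
  })

  if ("survive" %in% stages) run_stage("survive", function() {
    tab <- read_survival_table(file.path(data_dir, "cohort.csv"))
    groups <- unique(tab$genotype)
    for (g in groups) {
      atomic_write_csv(km_estimate(tab, g),
                       file.path(res_dir, sprintf("km_%s.csv", g)))
    }
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    tests <- multi_compare(tab, pairs, method = config$correction)
    atomic_write_csv(tests, file.path(res_dir, "surv_tests.csv"))
    summ <- do.call(rbind, lapply(groups, function(g) {
      lifespan_summary(tab, g, definition = config$max_lifespan_definition)
    }))
    atomic_write_csv(summ, file.path(res_dir, "lifespan_summary.csv"))
    artifacts$surv_tests <<- file.path(res_dir, "surv_tests.csv")
    artifacts$lifespan_summary <<- file.path(res_dir, "lifespan_summary.csv")
  })

  if ("stats" %in% stages) run_stage("stats", function() {
    smr_path <- file.path(res_dir, "smr.csv")
    if (file.exists(smr_path)) {
      smr <- utils::read.csv(smr_path)
      ds <- dispatch_test(data.frame(group = smr$genotype, value = smr$smr),
                          alpha_norm = config$alpha)
      atomic_write_csv(
        tibble::tibble(test = ds$test, statistic = ds$statistic,
                       p_value = ds$p_value, parametric = ds$parametric),
        file.path(res_dir, "smr_dispatch.csv"))
      atomic_write_csv(ds$gate, file.path(res_dir, "smr_dispatch_gate.csv"))
      artifacts$smr_dispatch <<- file.path(res_dir, "smr_dispatch.csv")
    }
    climb_paths <- list.files(data_dir, pattern = "^climbing_.*\\.csv$",
                              full.names = TRUE)
    if (length(climb_paths)) {
      scores <- do.call(rbind, lapply(sort(climb_paths), function(p) {
        tr <- utils::read.csv(p)
        tibble::tibble(group = sub("^climbing_(.*)\\.csv$", "\\1",
                                   basename(p)),
                       score = as.numeric(climbing_score(tr)))
      }))
      atomic_write_csv(scores, file.path(res_dir, "climbing_scores.csv"))
      artifacts$climbing_scores <<- file.path(res_dir, "climbing_scores.csv")
    }
  })

  pipeline_log(log_con, "pipeline complete")
  invisible(artifacts)
}
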