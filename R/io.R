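# Delimited-text readers/writers. Traces travel as CSV (time_s, co2_ppm,
# activity, temp_C, flow_ml_min) with a YAML metadata sidecar; survival
# tables and all result tables as plain CSV. All writes are atomic
# (write to a temp file in the same directory, then rename).

atomic_write_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(df, tmp, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

atomic_write_yaml <- function(x, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  yaml::write_yaml(x, tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".yml", path)

#' Write a respirometry trace to CSV (+ YAML sidecar)
#'
#' @param trace A [resp_trace()].
#' @param path Output CSV path; the metadata sidecar goes to the same path
#'   with extension `.yml`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  df <- trace$data
  df$flow_ml_min <- trace$flow_ml_min
  atomic_write_csv(df, path)
  meta <- list(fly_id = trace$fly_id, genotype = trace$genotype,
               age_class = trace$age_class,
               live_mass_mg = trace$live_mass_mg,
               flow_ml_min = trace$flow_ml_min,
               baseline_pre = as.integer(trace$baseline_pre),
               baseline_post = as.integer(trace$baseline_post))
  if (!is.null(trace$truth)) meta$truth <- trace$truth
  atomic_write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a respirometry trace from CSV (+ YAML sidecar)
#'
#' Validates the 1-Hz sampling contract (unit time step), required columns
#' and finiteness on read.
#'
#' @param path Trace CSV with columns `time_s`, `co2_ppm`, `activity`,
#'   `temp_C` (and optionally `flow_ml_min`).
#' @param meta_path Metadata sidecar; defaults to `path` with `.yml`.
#' @return A [resp_trace()].
#' @export
read_trace <- function(path, meta_path = sidecar_path(path)) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  df <- utils::read.csv(path)
  need <- c("time_s", "co2_ppm", "activity", "temp_C")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trace ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    if (any(!is.finite(df[[col]]))) {
      stop("non-finite value in `", col, "` at row ",
           which(!is.finite(df[[col]]))[1])
    }
  }
  meta <- yaml::read_yaml(meta_path)
  flow <- if ("flow_ml_min" %in% names(df)) df$flow_ml_min[1] else
    meta$flow_ml_min
  resp_trace(time_s = df$time_s, co2_ppm = df$co2_ppm,
             activity = df$activity, temp_C = df$temp_C,
             flow_ml_min = flow,
             baseline_pre = unlist(meta$baseline_pre),
             baseline_post = unlist(meta$baseline_post),
             fly_id = meta$fly_id, genotype = meta$genotype,
             age_class = meta$age_class,
             live_mass_mg = meta$live_mass_mg,
             truth = meta$truth)
}

#' Read a survival event table from CSV
#'
#' @param path CSV with columns `fly_id`, `genotype`, `condition`, `time`,
#'   `status` (or `event` coded `death`/`censored`).
#' @param time_unit Declared time unit (`"days"` or `"hours"`); never
#'   inferred from the data.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path, time_unit = c("days", "hours")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- utils::read.csv(path)
  if (!"status" %in% names(df) && "event" %in% names(df)) {
    df$status <- as.integer(df$event == "death")
  }
  survival_table(df, time_unit = time_unit)
}

#' Write a survival event table to CSV
#'
#' @param table A [survival_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(table, path) {
  stopifnot(inherits(table, "survival_table"))
  atomic_write_csv(as.data.frame(table), path)
}
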