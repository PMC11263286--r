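# Readers and writers for the pipeline's plain-text artifacts. All files are
# UTF-8 with a header row; floats are serialized at 12 significant digits;
# a leading comment line carries provenance (config hash and seed).

# 31-polynomial rolling hash over the deparsed object, kept within 2^31
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 7
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_line <- function(seed = NA, config = NULL) {
  sprintf("# fittsnirs seed=%s config=%s", as.character(seed),
          if (is.null(config)) "NA" else config_hash(config))
}

fmt12 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  df
}

write_table_prov <- function(df, path, sep, seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed, config), con)
  utils::write.table(fmt12(df), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_table_prov <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read the pooled trial table (CSV)
#'
#' Columns: subject, block, trial, condition, D, W, ID, OT, MT, HT, success,
#' overshoot (plus generator bookkeeping columns when present).
#' @param trials trial table. @param path file path.
#' @param seed,config optional provenance.
#' @return the path (write) or the table (read).
#' @export
write_trials <- function(trials, path, seed = NA, config = NULL)
  write_table_prov(trials, path, ",", seed, config)

#' @rdname write_trials
#' @export
read_trials <- function(path) read_table_prov(path, ",")

#' Write / read a subject's block events table (TSV)
#'
#' Standard events layout: `onset`, `duration`, `condition` in seconds on
#' the recording clock.
#' @param schedule schedule/events table. @param path file path.
#' @param seed,config optional provenance.
#' @export
write_events <- function(schedule, path, seed = NA, config = NULL) {
  ev <- schedule[, intersect(c("onset", "duration", "condition", "subject",
                               "block"), names(schedule))]
  write_table_prov(ev, path, "\t", seed, config)
}

#' @rdname write_events
#' @export
read_events <- function(path) read_table_prov(path, "\t")

#' Write / read a wide multi-channel series (CSV)
#'
#' Column 1 is `time_s`, remaining columns `ch01`..`chNN`.
#' @param series a `nirs_series`. @param path file path.
#' @param seed,config optional provenance.
#' @export
write_series <- function(series, path, seed = NA, config = NULL) {
  df <- data.frame(time_s = series$time, series$data, check.names = FALSE)
  write_table_prov(df, path, ",", seed, config)
}

#' @rdname write_series
#' @param subject subject id to attach on read.
#' @export
read_series <- function(path, subject = NA) {
  df <- read_table_prov(path, ",")
  t <- df$time_s
  data <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  rate <- 1 / stats::median(diff(t))
  structure(list(subject = subject, time = t, rate = round(rate, 6),
                 data = data), class = "nirs_series")
}

#' Write / read a channel registration table (CSV)
#'
#' Columns: channel, ba_label, hemisphere, mni_x, mni_y, mni_z, probability.
#' @param reg registration table. @param path file path.
#' @param seed,config optional provenance.
#' @export
write_registration <- function(reg, path, seed = NA, config = NULL)
  write_table_prov(reg, path, ",", seed, config)

#' @rdname write_registration
#' @export
read_registration <- function(path) read_table_prov(path, ",")

#' Write / read a results list as JSON
#'
#' @param results a (possibly nested) list of numbers, strings and tables.
#' @param path file path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write / read a single-trial cursor trajectory (CSV)
#'
#' Columns `time_s`, `x_px`, `y_px`; the target and start centres are kept
#' on comment lines so a trajectory file is self-contained for
#' re-classification with [classify_trial()].
#' @param traj trajectory list (see [simulate_trajectory()]).
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# target %.12g %.12g", traj$target[1], traj$target[2]),
             con)
  writeLines(sprintf("# start %.12g %.12g", traj$start[1], traj$start[2]),
             con)
  utils::write.table(fmt12(data.frame(time_s = traj$time, x_px = traj$x,
                                      y_px = traj$y)),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 2)
  num <- function(line) as.numeric(strsplit(line, " ")[[1]][3:4])
  df <- utils::read.table(path, sep = ",", header = TRUE, comment.char = "#")
  rate <- 1 / stats::median(diff(df$time_s))
  list(time = df$time_s, x = df$x_px, y = df$y_px,
       target = num(hdr[1]), start = num(hdr[2]), rate = round(rate, 6))
}
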