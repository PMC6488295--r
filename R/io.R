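## CSV / JSON contracts. Plain text only; a column-mapping dictionary lets
## external trial-table dialects (e.g. the deposited per-trial source-data
## files) be ingested without code changes.

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    stop_clamp(sprintf(
      "output file exists and overwrite = FALSE: %s", path),
      "overwrite_error")
  }
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV file with one row per trial.
#' @param column_map optional named character vector mapping internal
#'   column names to the file's column names, e.g.
#'   `c(hand_angle = "HandAngle", participant = "SN")`.
#' @return a trial table data frame.
#' @export
read_trials <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop_clamp(sprintf("input file not found: %s", path),
               "missing_file_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      ext <- column_map[[internal]]
      if (!ext %in% names(df)) {
        stop_clamp(sprintf("mapped column '%s' (for '%s') not in %s",
                           ext, internal, path), "missing_column_error")
      }
      names(df)[names(df) == ext] <- internal
    }
  }
  check_columns(df, .trial_cols, sprintf("trial CSV %s", path))
  for (col in c("trial", "cycle", "target_deg", "hand_angle")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop_clamp(sprintf("non-numeric value in column '%s', row %d of %s",
                         col, bad[1], path), "malformed_csv_error")
    }
    df[[col]] <- v
  }
  df
}

#' Write tables and records produced by the pipeline
#'
#' @param x object to write.
#' @param path output file.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
write_cycle_series <- function(x, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
write_json_record <- function(x, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_json_record <- function(path) {
  if (!file.exists(path)) {
    stop_clamp(sprintf("input file not found: %s", path),
               "missing_file_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

fit_record <- function(fit) {
  list(model = fit$model, parameters = as.list(fit$par), sse = fit$sse,
       r_squared = fit$r_squared, aic = fit$aic, n_obs = fit$n_obs,
       k = fit$k, converged = fit$converged)
}

permtest_record <- function(pt, effect = NULL) {
  c(list(test = pt$statistic, statistic = pt$observed, p = pt$p_value,
         n_perm = pt$n_perm, seed = pt$seed, null = pt$null),
    if (!is.null(effect)) list(effect_size = effect))
}
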