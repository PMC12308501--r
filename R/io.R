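# Interchange formats: ROI time series as TSV + JSON sidecar, matrices as
# TSV, long metrics and cohorts as CSV, configs as YAML. All numeric text is
# written with 17 significant digits so float64 round-trips losslessly.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write / read an ROI recording (TSV + JSON sidecar)
#'
#' The time series is a tab-separated matrix, one column per ROI, one row per
#' sample, with ROI labels as header; the sidecar
#' `<path>.json` carries `participant_id`, `condition`, `fs_hz` and `labels`.
#'
#' @param x A `roi_recording`.
#' @param path Path of the TSV file; the sidecar is written next to it.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `roi_recording`.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "roi_recording"))
  df <- as.data.frame(t(x$data))
  names(df) <- x$labels
  readr::write_tsv(dplyr::mutate(df, dplyr::across(dplyr::everything(), fmt_num)),
                   path, col_names = TRUE)
  sidecar <- list(participant_id = x$participant_id, condition = x$condition,
                  fs_hz = x$fs_hz, labels = as.list(x$labels))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop_arg("sidecar %s not found", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("participant_id", "condition", "fs_hz", "labels")) {
    if (is.null(sc[[field]])) {
      stop_arg("sidecar %s lacks required field '%s'", sidecar_path, field)
    }
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  if (!identical(names(df), as.character(sc$labels))) {
    stop_arg("TSV header does not match sidecar labels in %s", path)
  }
  data <- t(as.matrix(df))
  dimnames(data) <- NULL
  new_roi_recording(data, fs_hz = sc$fs_hz,
                    labels = as.character(sc$labels),
                    participant_id = sc$participant_id,
                    condition = sc$condition)
}

#' Write / read a connectivity matrix as TSV
#'
#' Square tab-separated matrix with ROI labels as header; metadata
#' (participant, condition, band, epochs averaged) in a JSON sidecar.
#'
#' @param x A `connectivity_matrix`.
#' @param path TSV path.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` a `connectivity_matrix`.
#' @export
write_connectivity <- function(x, path) {
  stopifnot(inherits(x, "connectivity_matrix"))
  df <- as.data.frame(x$values)
  names(df) <- x$labels
  readr::write_tsv(dplyr::mutate(df, dplyr::across(dplyr::everything(), fmt_num)),
                   path, col_names = TRUE)
  jsonlite::write_json(
    list(participant_id = x$participant_id, condition = x$condition,
         band = x$band, n_epochs_averaged = x$n_epochs_averaged,
         labels = as.list(x$labels)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  values <- as.matrix(df)
  labels <- as.character(sc$labels)
  dimnames(values) <- list(labels, labels)
  structure(
    list(values = values, labels = labels,
         participant_id = sc$participant_id, condition = sc$condition,
         band = sc$band, n_epochs_averaged = sc$n_epochs_averaged),
    class = "connectivity_matrix"
  )
}

#' Write / read the long metrics table and the cohort table as CSV
#'
#' @param x A tibble.
#' @param path CSV path.
#' @return The path (write) or a tibble (read).
#' @export
write_metrics_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  droplevels_safe(out)
}

#' @rdname write_metrics_csv
#' @export
write_cohort_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("participant_id", "diagnosis", "age_months", "sex",
              "srs_raw_total")
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    stop_arg("cohort CSV lacks column(s): %s", paste(missing, collapse = ", "))
  }
  out$diagnosis <- factor(out$diagnosis, levels = c("TD", "ASD"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out
}
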