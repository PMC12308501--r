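# Pipeline module: one config drives cohort simulation -> epoching/QC ->
# band-pass -> PLI -> thresholded graph metrics -> the statistical analyses,
# with all interchange files and a manifest written to an output directory.

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults mirror the study
#' conditions: 23 + 31 participants, recordings of 130 s (DR) and 190 s (EO)
#' at 500 Hz, 5-s epochs with a 10-epoch QC minimum, the five canonical
#' bands, proportional density 0.20 (sweep 0.10-0.30 in steps of 0.02
#' available), 1000 rewired nulls with 5 attempted swaps per edge, and
#' Bonferroni alpha 0.05 / 5 for the omnibus and baseline models.
#'
#' @param n_asd,n_td Group sizes.
#' @param bands Character vector of band names to analyse.
#' @param duration_s Named numeric `c(DR = , EO = )` recording durations.
#' @param fs_hz Sampling rate.
#' @param epoch_len_s,min_epochs Epoching and QC parameters.
#' @param mean_epoch_loss Named numeric `c(DR = , EO = )`: Poisson means of
#'   usable-epoch loss passed to [simulate_cohort()] (emulates artifact
#'   rejection; drives QC exclusions).
#' @param kappa_default Density for the main analysis.
#' @param kappa_sweep Optional density grid for the sensitivity sweep
#'   (`NULL` to skip).
#' @param n_null,iter_per_edge Null-ensemble parameters.
#' @param coupling Either a single [coupling_spec()] applied to every
#'   group x condition, or a named list with keys `TD.DR`, `TD.EO`, `ASD.DR`,
#'   `ASD.EO` (injects group- or condition-specific network structure);
#'   `NULL` builds a default spec per band with no injected effect.
#' @param labels ROI labels (default: 68 Desikan-Killiany labels).
#' @param alpha_corrected Bonferroni-corrected alpha (default 0.05 / 5).
#' @param gate Run follow-up analyses only for cells passing the omnibus
#'   interaction gate (default `TRUE`).
#' @param robust HC1 robust SEs for the trait regressions (default `TRUE`).
#' @param master_seed Master seed; every random stage derives a child seed
#'   from it.
#' @return A `pipeline_config` (validated named list).
#' @export
#' @examples
#' cfg <- pipeline_config(n_asd = 3, n_td = 3, bands = "gamma", n_null = 20,
#'                        master_seed = 1)
pipeline_config <- function(n_asd = 23, n_td = 31,
                            bands = band_table()$name,
                            duration_s = c(DR = 130, EO = 190),
                            fs_hz = 500,
                            epoch_len_s = 5, min_epochs = 10,
                            mean_epoch_loss = c(DR = 2, EO = 16),
                            kappa_default = 0.20,
                            kappa_sweep = NULL,
                            n_null = 1000, iter_per_edge = 5,
                            coupling = NULL,
                            labels = dk_labels(),
                            alpha_corrected = 0.05 / 5,
                            gate = TRUE, robust = TRUE,
                            master_seed = 1L) {
  stopifnot(all(bands %in% band_table()$name))
  check_scalar_number(kappa_default, "kappa_default", lo = 1e-12, hi = 1)
  check_scalar_number(n_null, "n_null", lo = 1)
  check_scalar_number(min_epochs, "min_epochs", lo = 0)
  check_scalar_number(master_seed, "master_seed")
  if (!all(c("DR", "EO") %in% names(duration_s))) {
    stop_arg("`duration_s` must be named with DR and EO")
  }
  if (!is.null(kappa_sweep) && any(kappa_sweep <= 0 | kappa_sweep > 1)) {
    stop_arg("`kappa_sweep` densities must be in (0, 1]")
  }
  if (!is.null(coupling) && inherits(coupling, "coupling_spec")) {
    coupling <- list(TD.DR = coupling, TD.EO = coupling,
                     ASD.DR = coupling, ASD.EO = coupling)
  }
  if (!is.null(coupling) &&
      !all(c("TD.DR", "TD.EO", "ASD.DR", "ASD.EO") %in% names(coupling))) {
    stop_arg("`coupling` must cover TD.DR, TD.EO, ASD.DR, ASD.EO")
  }
  structure(
    list(n_asd = as.integer(n_asd), n_td = as.integer(n_td), bands = bands,
         duration_s = duration_s, fs_hz = fs_hz, epoch_len_s = epoch_len_s,
         min_epochs = as.integer(min_epochs),
         mean_epoch_loss = mean_epoch_loss, kappa_default = kappa_default,
         kappa_sweep = kappa_sweep, n_null = as.integer(n_null),
         iter_per_edge = as.integer(iter_per_edge), coupling = coupling,
         labels = labels, alpha_corrected = alpha_corrected, gate = gate,
         robust = robust, master_seed = as.integer(master_seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> %d ASD + %d TD, bands: %s, ",
                     "kappa %.2f, %d nulls, seed %d\n"),
              x$n_asd, x$n_td, paste(x$bands, collapse = "/"),
              x$kappa_default, x$n_null, x$master_seed))
  invisible(x)
}

# default coupling: a modest set of consistently lagged pairs on the first
# 2 * n_pairs ROIs, identical across groups and conditions (no injected
# effect).
default_coupling <- function(band, n_roi, n_pairs = 20, concentration = 6,
                             lag = pi / 4, background_noise_sd = 1) {
  n_pairs <- min(n_pairs, n_roi %/% 2)
  coupling_spec(
    band,
    tibble(
      roi_i = seq_len(n_pairs) * 2L - 1L,
      roi_j = seq_len(n_pairs) * 2L,
      lag_radians = lag,
      concentration = concentration
    ),
    background_noise_sd = background_noise_sd
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly: coupling specs are flattened to plain lists and
#' rebuilt on read.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$duration_s <- as.list(x$duration_s)
  x$mean_epoch_loss <- as.list(x$mean_epoch_loss)
  if (!is.null(x$coupling)) {
    x$coupling <- lapply(x$coupling, function(cs) {
      list(band = cs$band$name, pairs = lapply(as.list(as.data.frame(cs$pairs)),
                                               as.numeric),
           background_noise_sd = cs$background_noise_sd)
    })
  }
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  coupling <- NULL
  if (!is.null(x$coupling)) {
    coupling <- lapply(x$coupling, function(cs) {
      coupling_spec(cs$band, as_tibble(cs$pairs),
                    background_noise_sd = cs$background_noise_sd)
    })
  }
  pipeline_config(
    n_asd = x$n_asd, n_td = x$n_td, bands = unlist(x$bands),
    duration_s = unlist(x$duration_s), fs_hz = x$fs_hz,
    epoch_len_s = x$epoch_len_s, min_epochs = x$min_epochs,
    mean_epoch_loss = unlist(x$mean_epoch_loss),
    kappa_default = x$kappa_default, kappa_sweep = unlist(x$kappa_sweep),
    n_null = x$n_null, iter_per_edge = x$iter_per_edge, coupling = coupling,
    labels = unlist(x$labels), alpha_corrected = x$alpha_corrected,
    gate = x$gate, robust = x$robust, master_seed = x$master_seed
  )
}

stage_abort <- function(stage, participant_id, condition, err) {
  rlang::abort(
    sprintf("stage '%s' failed for %s/%s", stage, participant_id, condition),
    class = "plinet_stage_error", parent = err
  )
}

#' Run the full pipeline from one configuration
#'
#' Simulates the cohort and its recordings, epochs them (recording QC
#' exclusions instead of failing), band-passes each epoch, computes
#' epoch-averaged PLI matrices, thresholds at the default density (plus the
#' sweep if configured), normalizes graph metrics against rewired null
#' ensembles, assembles the long metrics table, and runs the statistical
#' analysis suite. All tables, diagnostics figures (PDF) and a JSON manifest
#' (seeds, config, QC exclusions, versions) are written under `out_dir`; the
#' same config and master seed reproduce every number bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_recordings Also write every simulated recording as
#'   TSV + sidecar (default `FALSE`; they are large).
#' @return Invisibly, a list: `cohort`, `metrics` (long tibble), `sweep`
#'   (tibble or `NULL`), `analysis` (see [condition_analysis()]),
#'   `qc_exclusions` (tibble), `manifest` (list), `paths`.
#' @export
run_pipeline <- function(config, out_dir, write_recordings = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$master_seed, 3)
  # usable epochs are additionally capped by the recording duration
  caps <- c(DR = floor(config$duration_s[["DR"]] / config$epoch_len_s),
            EO = floor(config$duration_s[["EO"]] / config$epoch_len_s))
  cohort <- simulate_cohort(config$n_asd, config$n_td,
                            max_epochs = caps,
                            mean_epoch_loss = config$mean_epoch_loss,
                            seed = seeds[1])
  n <- nrow(cohort)
  conditions <- c("DR", "EO")
  rec_seeds <- matrix(spawn_seeds(seeds[2], n * 2), nrow = n,
                      dimnames = list(NULL, conditions))
  null_seeds <- matrix(spawn_seeds(seeds[3], n * 2), nrow = n,
                       dimnames = list(NULL, conditions))

  coupling_for <- function(diagnosis, condition, band) {
    if (is.null(config$coupling)) {
      default_coupling(band, length(config$labels))
    } else {
      cs <- config$coupling[[paste(diagnosis, condition, sep = ".")]]
      if (cs$band$name != band) {
        # config couples one band; other bands get background noise only
        coupling_spec(band, background_noise_sd = cs$background_noise_sd)
      } else {
        cs
      }
    }
  }

  qc_exclusions <- tibble(participant_id = character(),
                          condition = character(), n_epochs = integer())
  metrics_rows <- list()
  sweep_rows <- list()

  for (i in seq_len(n)) {
    pid <- cohort$participant_id[i]
    diag_i <- as.character(cohort$diagnosis[i])
    for (cond in conditions) {
      n_keep <- if (cond == "DR") cohort$epochs_dr[i] else cohort$epochs_eo[i]
      # one recording per condition; band structure injected per band below
      for (band in config$bands) {
        spec <- coupling_for(diag_i, cond, band)
        rec <- tryCatch(
          simulate_recording(pid, cond, spec,
                             duration_s = config$duration_s[[cond]],
                             fs_hz = config$fs_hz, labels = config$labels,
                             seed = rec_seeds[i, cond]),
          error = function(e) stage_abort("simulate", pid, cond, e)
        )
        if (write_recordings) {
          write_recording(rec, file.path(out_dir,
                                         sprintf("%s_%s_%s.tsv", pid, cond, band)))
        }
        ep <- tryCatch(
          make_epochs(rec, epoch_len_s = config$epoch_len_s,
                      min_epochs = config$min_epochs, n_keep = n_keep),
          plinet_qc_error = function(e) e,
          error = function(e) stage_abort("epoching", pid, cond, e)
        )
        if (inherits(ep, "plinet_qc_error")) {
          if (band == config$bands[1]) {
            rlang::warn(conditionMessage(ep), class = "plinet_qc_warning")
            qc_exclusions <- dplyr::bind_rows(qc_exclusions, tibble(
              participant_id = pid, condition = cond,
              n_epochs = ep$n_epochs
            ))
          }
          next
        }
        W <- tryCatch({
          epb <- bandpass(ep, band)
          pli_matrix(epb)
        }, error = function(e) stage_abort("connectivity", pid, cond, e))
        rec_metrics <- tryCatch({
          G <- proportional_threshold(W, config$kappa_default)
          normalized_metrics(G, n_null = config$n_null,
                             iter_per_edge = config$iter_per_edge,
                             seed = null_seeds[i, cond])
        }, error = function(e) stage_abort("graphs", pid, cond, e))
        metrics_rows[[length(metrics_rows) + 1L]] <- rec_metrics |>
          dplyr::mutate(participant_id = pid, condition = cond, band = band,
                        n_epochs = W$n_epochs_averaged, .before = 1)
        if (!is.null(config$kappa_sweep)) {
          sw <- tryCatch(
            threshold_sweep(W, kappas = config$kappa_sweep,
                            n_null = config$n_null,
                            iter_per_edge = config$iter_per_edge,
                            seed = null_seeds[i, cond]),
            error = function(e) stage_abort("sweep", pid, cond, e)
          )
          sweep_rows[[length(sweep_rows) + 1L]] <- sw |>
            dplyr::mutate(participant_id = pid, condition = cond, band = band,
                          .before = 1)
        }
      }
    }
  }

  wide <- dplyr::bind_rows(metrics_rows)
  metrics <- wide |>
    dplyr::select("participant_id", "condition", "band", "kappa",
                  "C", "L", "SW") |>
    tidyr::pivot_longer(c("C", "L", "SW"), names_to = "metric",
                        values_to = "value") |>
    dplyr::left_join(dplyr::select(cohort, "participant_id", "diagnosis",
                                   "age_months", "sex", "srs_raw_total"),
                     by = "participant_id") |>
    dplyr::mutate(condition = factor(.data$condition, levels = c("DR", "EO"))) |>
    dplyr::select("participant_id", "diagnosis", "age_months", "sex",
                  "srs_raw_total", "condition", "band", "kappa", "metric",
                  "value")
  sweep <- if (length(sweep_rows) > 0) dplyr::bind_rows(sweep_rows) else NULL

  analysis <- tryCatch(
    condition_analysis(metrics, alpha_corrected = config$alpha_corrected,
                       gate = config$gate, robust = config$robust),
    error = function(e) stage_abort("stats", "(all)", "(all)", e)
  )

  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    metrics = file.path(out_dir, "metrics_long.csv"),
    records = file.path(out_dir, "graph_metrics_records.csv"),
    table_condition = file.path(out_dir, "table_condition_models.csv"),
    table_groupwise = file.path(out_dir, "table_groupwise_models.csv"),
    table_srs = file.path(out_dir, "table_srs_models.csv"),
    table_baseline = file.path(out_dir, "table_baseline_models.csv"),
    diagnostics = file.path(out_dir, "model_diagnostics.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_cohort_csv(cohort, paths$cohort)
  write_metrics_csv(metrics, paths$metrics)
  write_metrics_csv(wide, paths$records)
  write_metrics_csv(analysis$condition, paths$table_condition)
  if (nrow(analysis$groupwise) > 0) {
    write_metrics_csv(analysis$groupwise, paths$table_groupwise)
  } else {
    paths$table_groupwise <- NULL
  }
  if (nrow(analysis$srs) > 0) {
    write_metrics_csv(analysis$srs, paths$table_srs)
  } else {
    paths$table_srs <- NULL
  }
  write_metrics_csv(analysis$baseline, paths$table_baseline)
  if (!is.null(sweep)) {
    paths$sweep <- file.path(out_dir, "metrics_sweep.csv")
    write_metrics_csv(sweep, paths$sweep)
  }

  diag_rows <- purrr::map_dfr(analysis$fits, function(f) {
    model_diagnostics(f)$summary
  })
  write_metrics_csv(diag_rows, paths$diagnostics)
  for (id in names(analysis$fits)[seq_len(min(3, length(analysis$fits)))]) {
    dg <- model_diagnostics(analysis$fits[[id]])
    fig_path <- file.path(out_dir, paste0(
      "diagnostics_", gsub("[^A-Za-z0-9]+", "_", id), ".pdf"))
    ggplot2::ggsave(fig_path, plot_diagnostics(dg), width = 9, height = 3.2)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("plinet")),
    r_version = as.character(getRversion()),
    master_seed = config$master_seed,
    stage_seeds = list(cohort = seeds[1], recordings = seeds[2],
                       nulls = seeds[3]),
    config = {
      cfg <- unclass(config)
      cfg$duration_s <- as.list(cfg$duration_s)
      cfg$mean_epoch_loss <- as.list(cfg$mean_epoch_loss)
      cfg$coupling <- if (is.null(cfg$coupling)) NULL else "custom (see config yaml)"
      cfg
    },
    qc_exclusions = qc_exclusions,
    n_metric_rows = nrow(metrics)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))

  invisible(list(cohort = cohort, metrics = metrics, sweep = sweep,
                 analysis = analysis, qc_exclusions = qc_exclusions,
                 manifest = manifest, paths = paths))
}
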