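# Synthetic-data module: cohorts, phase-coupled ROI recordings, oracle graphs,
# and metric-level simulation with injectable effects.

#' Simulate a two-group participant cohort
#'
#' Generates a participant table shaped like a pediatric case-control MEG
#' cohort: diagnosis (ASD/TD), age in months, sex, a continuous autistic-trait
#' score (SRS raw total), and post-QC epoch counts per recording condition.
#' Defaults reproduce the study-like group structure: SRS group means
#' 69.391 (ASD) and 47.677 (TD), ASD ages 60-97 months, TD ages 44-109 months,
#' and epoch counts bounded by the recording durations (130 s DR, 190 s EO at
#' 5-s epochs).
#'
#' The SRS standard deviation defaults to 11.5 in both groups, which at
#' n = 23/31 reproduces a two-sample t statistic near -6.9 for the group
#' contrast in expectation.
#'
#' @param n_asd,n_td Number of participants per group (non-negative integers).
#' @param srs_mean,srs_sd Named numeric vectors (`ASD`, `TD`): group means and
#'   SDs of the SRS raw total. Draws are truncated at 0.
#' @param age_range Named list (`ASD`, `TD`) of integer `c(min, max)` age
#'   ranges in months.
#' @param p_male Named numeric vector (`ASD`, `TD`): probability of male sex.
#' @param max_epochs Named integer vector (`DR`, `EO`): upper bound on usable
#'   epochs, `floor(duration / epoch_len)` for each condition.
#' @param mean_epoch_loss Named numeric vector (`DR`, `EO`): Poisson mean of
#'   epochs lost to artifacts; counts are `max - loss`, floored at 0.
#' @param seed Integer seed; identical seeds give identical tables.
#'
#' @return A tibble with one row per participant: `participant_id`,
#'   `diagnosis` (factor, TD reference), `age_months`, `sex` (factor,
#'   female reference), `srs_raw_total`, `epochs_dr`, `epochs_eo`.
#' @export
#' @examples
#' simulate_cohort(3, 4, seed = 1)
simulate_cohort <- function(n_asd = 23, n_td = 31,
                            srs_mean = c(ASD = 69.391, TD = 47.677),
                            srs_sd = c(ASD = 11.5, TD = 11.5),
                            age_range = list(ASD = c(60L, 97L),
                                             TD = c(44L, 109L)),
                            p_male = c(ASD = 14 / 23, TD = 17 / 31),
                            max_epochs = c(DR = 26L, EO = 38L),
                            mean_epoch_loss = c(DR = 2, EO = 16),
                            seed = NULL) {
  if (length(n_asd) != 1L || length(n_td) != 1L ||
      !is.numeric(n_asd) || !is.numeric(n_td) ||
      is.na(n_asd) || is.na(n_td) || n_asd < 0 || n_td < 0) {
    stop_arg("`n_asd` and `n_td` must be single non-negative counts")
  }
  n_asd <- as.integer(n_asd); n_td <- as.integer(n_td)
  with_seed(seed, {
    groups <- c(rep("ASD", n_asd), rep("TD", n_td))
    n <- length(groups)
    if (n == 0L) {
      return(tibble(
        participant_id = character(), diagnosis = factor(levels = c("TD", "ASD")),
        age_months = integer(), sex = factor(levels = c("female", "male")),
        srs_raw_total = numeric(), epochs_dr = integer(), epochs_eo = integer()
      ))
    }
    age <- vapply(groups, function(g) {
      r <- age_range[[g]]
      sample(seq.int(r[1], r[2]), 1L)
    }, integer(1))
    sex <- ifelse(rbinom(n, 1L, p_male[groups]) == 1L, "male", "female")
    srs <- pmax(0, rnorm(n, srs_mean[groups], srs_sd[groups]))
    epochs_dr <- pmax(0L, as.integer(max_epochs[["DR"]] -
                                       rpois(n, mean_epoch_loss[["DR"]])))
    epochs_eo <- pmax(0L, as.integer(max_epochs[["EO"]] -
                                       rpois(n, mean_epoch_loss[["EO"]])))
    tibble(
      participant_id = sprintf("sub-%03d", seq_len(n)),
      diagnosis = factor(groups, levels = c("TD", "ASD")),
      age_months = as.integer(age),
      sex = factor(sex, levels = c("female", "male")),
      srs_raw_total = srs,
      epochs_dr = epochs_dr,
      epochs_eo = epochs_eo
    )
  })
}

#' Specify pairwise phase coupling for a simulated recording
#'
#' Describes which ROI pairs oscillate together in a frequency band and how
#' consistently. Each coupled pair shares a common band-limited phase process;
#' the second ROI lags the first by `lag_radians` plus von Mises jitter with
#' the given concentration. Concentration `Inf` means a perfectly constant
#' lag (downstream single-epoch PLI 1 for a nonzero lag); concentration 0
#' means a uniformly random phase difference (expected PLI near 0).
#'
#' @param band Band name or a one-row band definition (see [band_table()]).
#' @param pairs A data frame with columns `roi_i`, `roi_j` (1-based ROI
#'   indices), `lag_radians` in (-pi, pi], and `concentration` (>= 0, may be
#'   `Inf`). May have zero rows.
#' @param background_noise_sd Standard deviation of the white background noise
#'   added to every ROI (>= 0).
#'
#' @return An object of class `coupling_spec`.
#' @export
#' @examples
#' coupling_spec("alpha", tibble::tibble(
#'   roi_i = 1, roi_j = 2, lag_radians = pi / 4, concentration = 8
#' ))
coupling_spec <- function(band, pairs = NULL, background_noise_sd = 1) {
  band <- as_band(band)
  check_scalar_number(background_noise_sd, "background_noise_sd", lo = 0)
  if (is.null(pairs)) {
    pairs <- tibble(roi_i = integer(), roi_j = integer(),
                    lag_radians = numeric(), concentration = numeric())
  }
  pairs <- as_tibble(pairs)
  needed <- c("roi_i", "roi_j", "lag_radians", "concentration")
  if (!all(needed %in% names(pairs))) {
    stop_arg("`pairs` must have columns %s", paste(needed, collapse = ", "))
  }
  if (any(pairs$roi_i == pairs$roi_j)) {
    stop_arg("coupled pairs must join two distinct ROIs")
  }
  if (any(pairs$lag_radians <= -pi | pairs$lag_radians > pi)) {
    stop_arg("`lag_radians` must lie in (-pi, pi]")
  }
  if (any(pairs$concentration < 0)) {
    stop_arg("`concentration` must be >= 0")
  }
  structure(
    list(band = band, pairs = pairs,
         background_noise_sd = background_noise_sd),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> band %s (%g-%g Hz), %d coupled pair(s), noise sd %g\n",
              x$band$name, x$band$lo_hz, x$band$hi_hz, nrow(x$pairs),
              x$background_noise_sd))
  invisible(x)
}

# Draw n angles from a von Mises(0, kappa) distribution. kappa = 0 is the
# uniform circle; kappa = Inf is a point mass at 0. Best-of-rejection sampler
# (Best & Fisher 1979), adequate for simulation use.
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric())
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u <- runif(1)
    if (c0 * (2 - c0) - u > 0 || log(c0 / u) + 1 - c0 >= 0) {
      out[i] <- sign(runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Probability that the wrapped phase difference lag + VM(0, kappa) is positive
# (and negative); the expected long-run PLI of a coupled pair is |p+ - p-|.
# Computed by numeric integration of the von Mises density.
pli_expected <- function(lag_radians, concentration) {
  if (!is.finite(concentration)) {
    return(abs(sign(wrap_phase(lag_radians))))
  }
  if (concentration == 0) return(0)
  dens <- function(theta) {
    exp(concentration * cos(theta)) /
      (2 * pi * besselI(concentration, 0, expon.scaled = FALSE))
  }
  # sign of wrap(lag + eps) over eps in (-pi, pi]
  f_pos <- function(eps) dens(eps) * (sin(lag_radians + eps) > 0 |
                                        (sin(lag_radians + eps) == 0 &
                                           cos(lag_radians + eps) < 0))
  f_neg <- function(eps) dens(eps) * (sin(lag_radians + eps) < 0)
  p_pos <- stats::integrate(f_pos, -pi, pi, subdivisions = 2000L)$value
  p_neg <- stats::integrate(f_neg, -pi, pi, subdivisions = 2000L)$value
  abs(p_pos - p_neg)
}

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- atan2(sin(x), cos(x))
  # atan2 returns -pi for exact antiphase; map to +pi so the interval is
  # half-open on the left.
  w[w == -pi] <- pi
  w
}

#' Simulate one band-coupled ROI recording
#'
#' Builds a clean source-level ROI time-series matrix: every ROI carries white
#' background noise; each coupled pair in `spec` additionally carries a shared
#' narrowband oscillation whose phase difference is `lag_radians` plus von
#' Mises jitter, redrawn in blocks of `jitter_block_s` seconds so the phase
#' difference decorrelates at roughly the band's own rate. Signals are clean:
#' no sensor noise model, no artifacts.
#'
#' @param participant_id Participant identifier stored in the recording.
#' @param condition `"DR"` or `"EO"`.
#' @param spec A [coupling_spec()].
#' @param duration_s Recording length in seconds (default 130 for DR, 190 for
#'   EO, the study's recording durations).
#' @param fs_hz Sampling rate in Hz (default 500).
#' @param labels ROI labels; defaults to the 68 Desikan-Killiany labels.
#' @param amplitude Amplitude of each coupled oscillation (does not affect
#'   PLI, which is phase-only).
#' @param jitter_block_s Length in seconds of the blocks over which the pair
#'   jitter is held constant; `NULL` picks `1 / bandwidth`.
#' @param seed Integer seed.
#'
#' @return An object of class `roi_recording`: list with `data`
#'   (n_roi x n_samples matrix), `fs_hz`, `labels`, `participant_id`,
#'   `condition`.
#' @export
#' @examples
#' spec <- coupling_spec("alpha", tibble::tibble(
#'   roi_i = 1, roi_j = 2, lag_radians = pi / 3, concentration = Inf
#' ), background_noise_sd = 0)
#' rec <- simulate_recording("sub-001", "DR", spec, duration_s = 10, seed = 1)
#' dim(rec$data)
simulate_recording <- function(participant_id, condition, spec,
                               duration_s = c(DR = 130, EO = 190)[[condition]],
                               fs_hz = 500, labels = dk_labels(),
                               amplitude = 1, jitter_block_s = NULL,
                               seed = NULL) {
  condition <- match.arg(condition, c("DR", "EO"))
  stopifnot(inherits(spec, "coupling_spec"))
  check_scalar_number(duration_s, "duration_s", lo = 1e-9)
  check_scalar_number(fs_hz, "fs_hz", lo = 1e-9)
  n_roi <- length(labels)
  if (nrow(spec$pairs) > 0 &&
      any(spec$pairs$roi_i > n_roi | spec$pairs$roi_j > n_roi |
            spec$pairs$roi_i < 1 | spec$pairs$roi_j < 1)) {
    stop_arg("coupling pair ROI index out of range 1..%d", n_roi)
  }
  n <- round(duration_s * fs_hz)
  band <- spec$band
  if (is.null(jitter_block_s)) {
    jitter_block_s <- 1 / (band$hi_hz - band$lo_hz)
  }
  with_seed(seed, {
    x <- matrix(rnorm(n_roi * n, sd = spec$background_noise_sd),
                nrow = n_roi, ncol = n)
    if (nrow(spec$pairs) > 0) {
      t_sec <- (seq_len(n) - 1) / fs_hz
      f_c <- (band$lo_hz + band$hi_hz) / 2
      block_len <- max(1L, round(jitter_block_s * fs_hz))
      n_block <- ceiling(n / block_len)
      for (r in seq_len(nrow(spec$pairs))) {
        p <- spec$pairs[r, ]
        # shared carrier with a smooth slow FM (quasi-narrowband, not a pure
        # tone; smoothness keeps the envelope stable so phases stay clean)
        drift <- 0.5 * sin(2 * pi * runif(1, 0.05, 0.15) * t_sec +
                             runif(1, -pi, pi))
        theta <- 2 * pi * f_c * t_sec + runif(1, -pi, pi) + drift
        jit <- rvonmises(n_block, p$concentration)
        eps <- rep(jit, each = block_len)[seq_len(n)]
        x[p$roi_i, ] <- x[p$roi_i, ] + amplitude * cos(theta)
        x[p$roi_j, ] <- x[p$roi_j, ] +
          amplitude * cos(theta - p$lag_radians - eps)
      }
    }
    new_roi_recording(x, fs_hz, labels, participant_id, condition)
  })
}

new_roi_recording <- function(data, fs_hz, labels, participant_id, condition) {
  stopifnot(is.matrix(data), nrow(data) == length(labels), !anyNA(data))
  structure(
    list(data = data, fs_hz = fs_hz, labels = labels,
         participant_id = participant_id, condition = condition),
    class = "roi_recording"
  )
}

#' @export
print.roi_recording <- function(x, ...) {
  cat(sprintf("<roi_recording> %s / %s: %d ROIs x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$condition, nrow(x$data), ncol(x$data),
              x$fs_hz, ncol(x$data) / x$fs_hz))
  invisible(x)
}

#' Generate a Watts-Strogatz small-world graph
#'
#' Ring lattice on `n` nodes with each node joined to its `k` nearest
#' neighbours, then each lattice edge independently rewired with probability
#' `p_rewire` to a uniformly chosen new endpoint (avoiding self-loops and
#' duplicate edges). The edge count is exactly `n * k / 2` regardless of
#' `p_rewire`. Used as an oracle fixture with known clustering
#' (`3 (k - 2) / (4 (k - 1))` at `p_rewire = 0`) and small-world behaviour at
#' small nonzero `p_rewire`.
#'
#' @param n Number of nodes.
#' @param k Even number of nearest neighbours per node, `2 <= k < n`.
#' @param p_rewire Rewiring probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A [binary_graph] object.
#' @export
#' @examples
#' g <- simulate_small_world_graph(68, 4, 0.05, seed = 1)
#' g$n_edges
simulate_small_world_graph <- function(n, k, p_rewire, seed = NULL) {
  check_scalar_number(n, "n", lo = 3)
  check_scalar_number(k, "k", lo = 2)
  check_scalar_number(p_rewire, "p_rewire", lo = 0, hi = 1)
  n <- as.integer(n); k <- as.integer(k)
  if (k %% 2L != 0L) stop_arg("`k` must be even")
  if (k >= n) stop_arg("`k` must be smaller than `n`")
  with_seed(seed, {
    adj <- matrix(0L, n, n)
    for (d in seq_len(k %/% 2L)) {
      i <- seq_len(n)
      j <- ((i - 1L + d) %% n) + 1L
      adj[cbind(i, j)] <- 1L
      adj[cbind(j, i)] <- 1L
    }
    if (p_rewire > 0) {
      # visit lattice edges in canonical order, as in the original construction
      for (d in seq_len(k %/% 2L)) {
        for (i in seq_len(n)) {
          j <- ((i - 1L + d) %% n) + 1L
          if (adj[i, j] == 1L && runif(1) < p_rewire) {
            candidates <- which(adj[i, ] == 0L)
            candidates <- setdiff(candidates, i)
            if (length(candidates) > 0) {
              new_j <- candidates[sample.int(length(candidates), 1L)]
              adj[i, j] <- adj[j, i] <- 0L
              adj[i, new_j] <- adj[new_j, i] <- 1L
            }
          }
        }
      }
    }
    new_binary_graph(adj, kappa = (n * k / 2) / (n * (n - 1) / 2))
  })
}

#' Simulate a long-format graph-metrics table with injectable effects
#'
#' Draws per-participant, per-condition graph metrics directly from an
#' additive generative model (participant random intercept plus residual
#' noise), bypassing the signal-level pipeline. This is the workhorse for
#' statistical parameter-recovery and type-I-error simulations, where
#' thousands of cohort replicates are needed and the signal chain's only role
#' would be to add cost.
#'
#' For each metric x band cell the value is
#' `mu + b_diag * ASD + b_cond * EO + b_int * ASD * EO + u_participant + e`,
#' with `u ~ N(0, sigma_participant^2)` and `e ~ N(0, sigma_resid^2)`.
#' Effects default to zero; `effects` entries are named
#' `"<metric>.<band>"`, each a named vector with any of `diagnosis`,
#' `condition`, `interaction`.
#'
#' Optionally, `srs_assoc` rewires the cohort's SRS scores to depend on a
#' chosen cell's change score: `SRS = group_mean + slope_g * delta + noise`,
#' giving a known group-specific trait association.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param bands Character vector of band names.
#' @param metrics Character vector among `"SW"`, `"C"`, `"L"`.
#' @param kappa Density recorded in the table (default 0.20).
#' @param mu Named numeric: baseline level per metric.
#' @param effects Named list of injected effects (see Details).
#' @param sigma_participant,sigma_resid Random-intercept and residual SDs.
#' @param srs_assoc Optional list with `metric`, `band`, `slope` (named vector
#'   `c(TD = ..., ASD = ...)`) and `sd` (noise SD of the regenerated SRS).
#' @param seed Integer seed.
#' @return A metrics tibble with columns `participant_id`, `diagnosis`,
#'   `age_months`, `sex`, `srs_raw_total`, `condition`, `band`, `kappa`,
#'   `metric`, `value`.
#' @export
#' @examples
#' coh <- simulate_cohort(5, 5, seed = 1)
#' simulate_metrics(coh, bands = "beta", metrics = "SW",
#'                  effects = list(SW.beta = c(interaction = 0.08)), seed = 2)
simulate_metrics <- function(cohort,
                             bands = c("delta", "theta", "alpha", "beta", "gamma"),
                             metrics = c("SW", "C", "L"),
                             kappa = 0.2,
                             mu = c(SW = 1.0, C = 0.45, L = 2.0),
                             effects = list(),
                             sigma_participant = 0.05,
                             sigma_resid = 0.05,
                             srs_assoc = NULL,
                             seed = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  with_seed(seed, {
    n <- nrow(cohort)
    grid <- tidyr::expand_grid(
      participant_id = cohort$participant_id,
      condition = factor(c("DR", "EO"), levels = c("DR", "EO")),
      band = bands,
      metric = metrics
    )
    u <- setNames(rnorm(n, 0, sigma_participant), cohort$participant_id)
    out <- grid |>
      dplyr::left_join(cohort, by = "participant_id") |>
      dplyr::mutate(
        is_asd = as.integer(.data$diagnosis == "ASD"),
        is_eo = as.integer(.data$condition == "EO"),
        cell = paste(.data$metric, .data$band, sep = ".")
      )
    eff <- function(cell, which) {
      v <- effects[[cell]]
      if (is.null(v) || is.na(v[which])) 0 else unname(v[which])
    }
    out$value <- mu[out$metric] +
      vapply(out$cell, eff, numeric(1), which = "diagnosis") * out$is_asd +
      vapply(out$cell, eff, numeric(1), which = "condition") * out$is_eo +
      vapply(out$cell, eff, numeric(1), which = "interaction") *
        out$is_asd * out$is_eo +
      u[out$participant_id] +
      rnorm(nrow(out), 0, sigma_resid)
    out <- out |>
      dplyr::mutate(kappa = kappa) |>
      dplyr::select("participant_id", "diagnosis", "age_months", "sex",
                    "srs_raw_total", "condition", "band", "kappa", "metric",
                    "value")
    if (!is.null(srs_assoc)) {
      deltas <- out |>
        dplyr::filter(.data$metric == srs_assoc$metric,
                      .data$band == srs_assoc$band) |>
        tidyr::pivot_wider(id_cols = c("participant_id", "diagnosis"),
                           names_from = "condition",
                           values_from = "value") |>
        dplyr::mutate(delta = .data$EO - .data$DR)
      grp_mean <- c(TD = 47.677, ASD = 69.391)
      srs_new <- grp_mean[as.character(deltas$diagnosis)] +
        srs_assoc$slope[as.character(deltas$diagnosis)] * deltas$delta +
        rnorm(nrow(deltas), 0, srs_assoc$sd)
      names(srs_new) <- deltas$participant_id
      out$srs_raw_total <- pmax(0, srs_new[out$participant_id])
    }
    out
  })
}
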