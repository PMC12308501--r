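test_that("cohort generation respects sizes, ranges and seeded determinism", {
  coh <- simulate_cohort(23, 31, seed = 7)
  expect_equal(nrow(coh), 54)
  expect_equal(sum(coh$diagnosis == "ASD"), 23)
  expect_equal(sum(coh$diagnosis == "TD"), 31)
  expect_false(anyDuplicated(coh$participant_id) > 0)
  expect_true(all(coh$age_months[coh$diagnosis == "ASD"] >= 60 &
                    coh$age_months[coh$diagnosis == "ASD"] <= 97))
  expect_true(all(coh$age_months[coh$diagnosis == "TD"] >= 44 &
                    coh$age_months[coh$diagnosis == "TD"] <= 109))
  expect_true(all(coh$srs_raw_total >= 0))
  # group SRS means land near their targets at these n
  expect_lt(abs(mean(coh$srs_raw_total[coh$diagnosis == "ASD"]) - 69.391), 3)
  expect_lt(abs(mean(coh$srs_raw_total[coh$diagnosis == "TD"]) - 47.677), 3)
  # empty group
  td_only <- simulate_cohort(0, 5, seed = 1)
  expect_equal(nrow(td_only), 5)
  expect_true(all(td_only$diagnosis == "TD"))
  # determinism
  expect_identical(simulate_cohort(10, 10, seed = 3),
                   simulate_cohort(10, 10, seed = 3))
  expect_error(simulate_cohort(-1, 5), class = "plinet_argument_error")
})

test_that("epoch counts never exceed the recording-duration cap", {
  coh <- simulate_cohort(20, 20, seed = 11)
  expect_true(all(coh$epochs_dr <= 26))
  expect_true(all(coh$epochs_eo <= 38))
})

test_that("coupling_spec validates pairs", {
  expect_error(coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 1, lag_radians = 0.1, concentration = 1
  )), class = "plinet_argument_error")
  expect_error(coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 2, lag_radians = 4, concentration = 1
  )), class = "plinet_argument_error")
  expect_error(coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 2, lag_radians = 0.1, concentration = -1
  )), class = "plinet_argument_error")
  expect_error(coupling_spec("nosuchband"), class = "plinet_argument_error")
})

test_that("recording generation is seeded-deterministic and validates indices", {
  spec <- coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 2, lag_radians = pi / 4, concentration = 5
  ))
  r1 <- simulate_recording("s1", "DR", spec, duration_s = 5,
                           labels = c("a", "b", "c"), seed = 2)
  r2 <- simulate_recording("s1", "DR", spec, duration_s = 5,
                           labels = c("a", "b", "c"), seed = 2)
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data), c(3, 2500))
  expect_error(
    simulate_recording("s1", "DR", spec, duration_s = 5,
                       labels = c("a"), seed = 2),
    class = "plinet_argument_error"
  )
})

test_that("a perfectly concentrated nonzero lag yields downstream PLI of 1", {
  spec <- coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 2, lag_radians = pi / 3, concentration = Inf
  ), background_noise_sd = 0)
  rec <- simulate_recording("s1", "DR", spec, duration_s = 60,
                            labels = c("a", "b", "c"), seed = 1)
  M <- pli_matrix(bandpass(make_epochs(rec), "alpha"), trim_s = 0.1)
  expect_identical(M$values[1, 2], 1)
})

test_that("uniform phase jitter leaves mean off-diagonal PLI below 0.1", {
  # oracle expectation for iid symmetric signs at N = 2500 is
  # sqrt(2 / (pi N)) ~ 0.016; 0.1 is a generous bound on top of residual
  # autocorrelation
  spec <- coupling_spec("gamma", tibble::tibble(
    roi_i = 1:3, roi_j = 4:6, lag_radians = 0.5, concentration = 0
  ))
  rec <- simulate_recording("s1", "DR", spec, duration_s = 50,
                            labels = letters[1:6], seed = 9)
  M <- pli_matrix(make_epochs(rec))
  expect_lt(mean(M$values[upper.tri(M$values)]), 0.1)
})

test_that("expected PLI closed form |p+ - p-| matches brute-force resampling", {
  # direct resampling of the wrapped lag + jitter sign distribution
  for (case in list(c(pi / 3, 1), c(pi / 6, 4), c(-pi / 2, 2))) {
    lag <- case[1]; conc <- case[2]
    closed <- plinet:::pli_expected(lag, conc)
    set.seed(42)
    eps <- plinet:::rvonmises(2e5, conc)
    d <- plinet:::wrap_phase(lag + eps)
    brute <- abs(mean(sign(d)))
    expect_lt(abs(closed - brute), 0.01)
  }
})

test_that("downstream PLI is monotone in jitter concentration", {
  grid <- c(0, 1, 4, 16)
  plis <- vapply(grid, function(conc) {
    sp <- coupling_spec("gamma", tibble::tibble(
      roi_i = 1, roi_j = 2, lag_radians = pi / 3, concentration = conc
    ), background_noise_sd = 0.2)
    r <- simulate_recording("s1", "DR", sp, duration_s = 50,
                            labels = c("a", "b"), seed = 3)
    pli_matrix(bandpass(make_epochs(r), "gamma"), trim_s = 0.05)$values[1, 2]
  }, numeric(1))
  expect_true(all(diff(plis) > 0))
  # and the closed-form expectation is monotone on the same grid
  expected <- vapply(grid, plinet:::pli_expected, numeric(1),
                     lag_radians = pi / 3)
  expect_true(all(diff(expected) >= 0))
})

test_that("amplitude scaling leaves downstream PLI unchanged", {
  spec <- coupling_spec("alpha", tibble::tibble(
    roi_i = 1, roi_j = 2, lag_radians = pi / 4, concentration = 3
  ))
  rec <- simulate_recording("s1", "DR", spec, duration_s = 55,
                            labels = c("a", "b", "c"), seed = 4)
  scaled <- rec
  scaled$data <- 7.3 * scaled$data
  m1 <- pli_matrix(bandpass(make_epochs(rec), "alpha"))
  m2 <- pli_matrix(bandpass(make_epochs(scaled), "alpha"))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("small-world generator matches lattice formulas and is deterministic", {
  g <- simulate_small_world_graph(68, 4, 0, seed = 1)
  expect_equal(clustering_coefficient(g), 0.5)          # 3(k-2)/(4(k-1)), k=4
  expect_equal(oracle_clustering(g$adjacency), 0.5)     # brute-force triangles
  expect_equal(g$n_edges, 68 * 4 / 2)
  g6 <- simulate_small_world_graph(68, 6, 1.0, seed = 5)
  expect_equal(g6$n_edges, 204)                         # nk/2 preserved
  expect_identical(simulate_small_world_graph(10, 4, 0.1, seed = 2)$adjacency,
                   simulate_small_world_graph(10, 4, 0.1, seed = 2)$adjacency)
  expect_error(simulate_small_world_graph(10, 3, 0.1), class = "plinet_argument_error")
  expect_error(simulate_small_world_graph(4, 4, 0.1), class = "plinet_argument_error")
})

test_that("metric-level simulation injects effects where asked", {
  coh <- simulate_cohort(40, 40, seed = 2)
  m <- simulate_metrics(coh, bands = c("beta", "alpha"), metrics = "SW",
                        effects = list(SW.beta = c(interaction = 0.5)),
                        sigma_participant = 0.01, sigma_resid = 0.01,
                        seed = 3)
  expect_equal(nrow(m), 80 * 2 * 2)
  cell_mean <- function(band, diag, cond) {
    mean(m$value[m$band == band & m$diagnosis == diag & m$condition == cond])
  }
  inter_beta <- (cell_mean("beta", "ASD", "EO") - cell_mean("beta", "ASD", "DR")) -
    (cell_mean("beta", "TD", "EO") - cell_mean("beta", "TD", "DR"))
  inter_alpha <- (cell_mean("alpha", "ASD", "EO") - cell_mean("alpha", "ASD", "DR")) -
    (cell_mean("alpha", "TD", "EO") - cell_mean("alpha", "TD", "DR"))
  expect_lt(abs(inter_beta - 0.5), 0.05)
  expect_lt(abs(inter_alpha), 0.05)
  expect_identical(m, simulate_metrics(coh, bands = c("beta", "alpha"),
                                       metrics = "SW",
                                       effects = list(SW.beta = c(interaction = 0.5)),
                                       sigma_participant = 0.01,
                                       sigma_resid = 0.01, seed = 3))
})
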