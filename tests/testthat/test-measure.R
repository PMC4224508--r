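# minimal synthetic nodal_sim for map-based measurements
fake_sim <- function(act, labels, dx = 0.06) {
  g <- nodalsim:::new_geometry(labels, dx,
                               probes = tibble::tibble(name = "p", x = 1L,
                                                       y = 1L, z = 1L))
  structure(list(engine = "fhn", geometry = g, activation = act,
                 events = list(), traces = tibble::tibble()),
            class = "nodal_sim")
}

test_that("conduction velocity is plain distance over time on a uniform map", {
  labels <- array(1L, c(50, 5, 5))
  act <- array(rep(0.1125 * (0:49), 25), c(50, 5, 5))
  s <- fake_sim(act, labels)
  expect_equal(conduction_velocity(s, 10, 40), 0.06 / 0.1125) # = 0.5333 m/s
  act2 <- act; act2[40, 3, 3] <- NA
  expect_error(conduction_velocity(fake_sim(act2, labels), 10, 40),
               class = "nodalsim_propagation_failure")
  act3 <- array(5, c(50, 5, 5))
  expect_error(conduction_velocity(fake_sim(act3, labels), 10, 40),
               class = "nodalsim_measurement_error")
})

test_that("apd90 of a triangular pulse is rise time plus 90% of the fall", {
  tt <- seq(0, 150, by = 0.05)
  u <- ifelse(tt <= 1, tt, pmax(0, 1 - (tt - 1) / 100))
  expect_equal(apd90(tibble::tibble(time = tt, u = u)), 91, tolerance = 0.06)
  flat <- tibble::tibble(time = tt, u = 0 * tt)
  expect_error(apd90(flat), class = "nodalsim_measurement_error")
})

test_that("max upstroke of a linear ramp equals its slope", {
  tt <- seq(0, 10, by = 0.1)
  tr <- tibble::tibble(time = tt, u = 0.3 * tt)
  expect_equal(max_upstroke(tr)$du_dt, 0.3, tolerance = 1e-9)
  expect_equal(max_upstroke(tr, apa = 100)$dvm_dt, 30, tolerance = 1e-6)
})

test_that("upstroke measurement is sampling-rate stable", {
  g <- make_strand(tissue = "atrial")
  ups <- vapply(c(0.05, 0.025), function(rd) {
    s <- simulate_fhn(g, duration = 30, record_dt = rd,
                      stimuli = list(stimulus(region_layers(g, 1:3), 2, 1)),
                      probes = "mid")
    max_upstroke(probe_trace(s, "mid"))$du_dt
  }, numeric(1))
  expect_lt(abs(diff(ups)) / ups[1], 0.02)
})

test_that("apd90 and upstroke are invariant under the voltage display map", {
  g <- make_strand(tissue = "atrial")
  s <- simulate_fhn(g, duration = 150, record_dt = 0.05,
                    stimuli = list(stimulus(region_layers(g, 1:3), 2, 1)),
                    probes = "mid")
  tr <- probe_trace(s, "mid")
  sc <- list(Vr = -80, Vos = 20)
  tr_mv <- tibble::tibble(time = tr$time,
                          u = vm_to_u(u_to_vm(tr$u, sc), sc))
  expect_equal(apd90(tr_mv), apd90(tr), tolerance = 1e-9)
  expect_equal(max_upstroke(tr_mv)$du_dt, max_upstroke(tr)$du_dt,
               tolerance = 1e-9)
})

test_that("cycle length, rate and conduction ratios reduce correctly", {
  ev <- seq(0, 3300, by = 330)
  expect_equal(cycle_length(ev), 330)
  expect_error(cycle_length(c(1, 2)), class = "nodalsim_measurement_error")
  expect_equal(dominant_frequency(seq(0, 1000, by = 100)), 10)
  up <- seq(0, 1300, by = 100)          # 14 events
  dn <- up[seq(1, 14, by = 2)]          # every other -> 7 events
  r <- conduction_ratio(up, dn)
  expect_equal(r$text, "2:1")
  # alternating 2:1 / 3:1 pattern is reported as mixed
  dn2 <- up[c(1, 3, 6, 8, 11, 13)]
  r2 <- conduction_ratio(up, dn2)
  expect_match(r2$text, "mixed")
  expect_setequal(unique(r2$per_beat), c(2, 3))
})

test_that("refractory-period bisection matches an exhaustive 1 ms sweep", {
  # the automaton engine makes the exhaustive oracle cheap
  g <- make_strand(n_long = 30, n_cross = 3)
  pars <- ca_params(0.1)
  sweep <- vapply(70:95, function(ci) {
    s <- simulate_ca(g, duration = ci + 40, params = pars, dt = 0.1,
                     stimuli = list(ca_stimulus(region_layers(g, 1), 5),
                                    ca_stimulus(region_layers(g, 1), 5 + ci)),
                     probes = "layer_25")
    sum(s$events[["layer_25"]] > 5 + ci) > 0
  }, logical(1))
  rp_sweep <- (70:95)[which(sweep)[1]]
  rp_scan <- refractory_period(g, engine = "ca", ca_parameters = pars,
                               ci_range = c(60, 110), far_layer = 25)
  expect_equal(as.numeric(rp_scan), rp_sweep)
})

test_that("activation-map CV equals two-probe CV on a uniform strand", {
  g <- make_strand(tissue = "atrial")
  s <- simulate_fhn(g, duration = 35, record_dt = 0.5,
                    stimuli = list(stimulus(region_layers(g, 1:3), 2, 1)),
                    probes = c("layer_10", "layer_40"))
  cv_map <- conduction_velocity(s, 10, 40)
  cv_probe <- 30 * 0.06 /
    (s$events[["layer_40"]][1] - s$events[["layer_10"]][1])
  expect_lt(abs(cv_map - cv_probe) / cv_map, 0.01)
})

test_that("tidiers and plots expose the simulation surface", {
  g <- make_strand(n_long = 15, n_cross = 3)
  s <- simulate_fhn(g, duration = 15,
                    stimuli = list(stimulus(region_layers(g, 1:3), 1, 1)),
                    probes = c("layer_5", "mid"))
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("site", "t_activation", "n_events") %in% names(td)))
  gl <- glance(s)
  expect_equal(gl$engine, "fhn")
  expect_equal(gl$n_tissue, 15 * 9)
  p <- ggplot2::autoplot(s)
  expect_s3_class(p, "ggplot")
  pa <- plot_activation(s, slice = 2)
  expect_s3_class(pa, "ggplot")
})
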