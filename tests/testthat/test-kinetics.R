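atrial <- dplyr::filter(tissue_params(), tissue == "atrial")
san <- dplyr::filter(tissue_params(), tissue == "san")

test_that("rest is an equilibrium of the non-pacemaking kinetics", {
  r <- reaction_rogers(0, 0, atrial)
  expect_identical(r$du_dt, 0)
  expect_identical(r$dv_dt, 0)
  # and of every excitable tissue class
  for (tis in c("ine", "pb")) {
    p <- dplyr::filter(tissue_params(), tissue == tis)
    r <- reaction_rogers(0, 0, p)
    expect_identical(abs(r$du_dt) + abs(r$dv_dt), 0)
  }
})

test_that("sub-threshold perturbations decay back to rest", {
  eps <- seq(0.005, atrial$alpha - 0.005, length.out = 25)
  r <- reaction_rogers(eps, 0, atrial)
  expect_true(all(r$du_dt < 0))
})

test_that("non-finite states are rejected", {
  expect_error(reaction_rogers(NaN, 0, atrial), class = "nodalsim_state_error")
  expect_error(reaction_rogers(0, Inf, atrial), class = "nodalsim_state_error")
})

test_that("a suprathreshold kick yields one action potential then rest", {
  # single cell, long unstimulated follow-up: exactly one activation
  for (tis in c("atrial", "ine", "pb")) {
    g <- make_single_cell(tis)
    s <- simulate_fhn(g, duration = 5000,
                      stimuli = list(stimulus(region_layers(g, 1), at = 2,
                                              duration = 1)),
                      probes = "cell", record_dt = 1)
    expect_length(s$events[["cell"]], 1)
    expect_lt(abs(tail(probe_trace(s, "cell")$u, 1)), 1e-4)
  }
})

test_that("engine point kinetics agree with a plain-R integration", {
  # independent forward-Euler on the exported reaction functions
  g <- make_single_cell("atrial")
  s <- simulate_fhn(g, duration = 120, dt = 0.005,
                    stimuli = list(stimulus(region_layers(g, 1), at = 1,
                                            duration = 0.5, amplitude = 0.8)),
                    probes = "cell", record_dt = 0.5)
  tr <- probe_trace(s, "cell")
  orc <- cell_oracle(atrial, u0 = 0, v0 = 0, dt = 0.005, t_max = 120,
                     kick = list(at = 1, duration = 0.5, amplitude = 0.8))
  u_orc <- approx(orc$time, orc$u, xout = tr$time)$y
  expect_lt(max(abs(tr$u - u_orc)), 1e-8)
})

test_that("isolated node converges to the same limit cycle from different states", {
  g <- make_single_cell("san")
  run <- function(u0, v0) {
    s <- simulate_fhn(g, duration = 3500,
                      init = list(u = array(u0, c(1, 1, 1)),
                                  v = array(v0, c(1, 1, 1))),
                      probes = "cell", record_dt = 1)
    s$events[["cell"]]
  }
  ev1 <- run(0.05, 0); ev2 <- run(0.9, 1.2)
  p1 <- mean(diff(tail(ev1, 4))); p2 <- mean(diff(tail(ev2, 4)))
  expect_lt(abs(p1 - p2) / p1, 0.01)
})

test_that("node period is stable to <1% across many cycles", {
  g <- make_single_cell("san")
  s <- simulate_fhn(g, duration = 4600, probes = "cell", record_dt = 1)
  ev <- s$events[["cell"]]
  expect_gte(length(ev), 11)
  iv <- diff(ev)[-1]  # drop the startup interval
  expect_lt((max(iv) - min(iv)) / mean(iv), 0.01)
})

test_that("passive kinetics are pure decay", {
  expect_identical(reaction_passive(0), 0)
  expect_lt(reaction_passive(0.7, rb = 0.5), 0)
  expect_error(reaction_passive(0.5, rb = 0), class = "nodalsim_parameter_error")
  # isolated passive element: u non-increasing
  u <- 0.8
  for (i in 1:200) {
    du <- reaction_passive(u, 0.5)
    expect_lte(du, 0)
    u_new <- u + 0.01 * du
    expect_lte(u_new, u)
    u <- u_new
  }
})

test_that("periphery blend is continuous, monotone and hits its endpoints", {
  rule <- list(band_width = 4, c1S = 1, c1A_ref = 12.7)
  d <- seq(0, 6, by = 0.25)
  v <- blend_periphery(d, rule)
  expect_equal(blend_periphery(0, rule), rule$c1A_ref)
  expect_equal(blend_periphery(4, rule), rule$c1S)
  expect_equal(blend_periphery(6, rule), rule$c1S)   # interior unmodified
  expect_true(all(diff(v) <= 1e-12))                 # monotone toward the node
  expect_true(all(v >= min(rule$c1S, rule$c1A_ref) - 1e-12 &
                    v <= max(rule$c1S, rule$c1A_ref) + 1e-12))
  expect_error(blend_periphery(-1, rule), class = "nodalsim_parameter_error")
})

test_that("voltage map is affine with exact round trip", {
  sc <- list(Vr = -80, Vos = 20)
  expect_equal(u_to_vm(0, sc), -80)
  expect_equal(u_to_vm(1, sc), 20)
  u <- seq(-0.3, 1.2, by = 0.05)
  expect_equal(vm_to_u(u_to_vm(u, sc), sc), u, tolerance = 1e-12)
  expect_error(u_to_vm(0.5, list(Vr = 10, Vos = -60)),
               class = "nodalsim_parameter_error")
})

test_that("published tissue parameters are preserved verbatim", {
  tt <- tissue_params()
  expect_equal(tt$D, c(2, 7, 2, 2))
  expect_equal(tt$c1, c(1, 12.7, 1.45, 3.05))
  expect_equal(tt$c2, c(0.22, 1.84, 1, 1))
  expect_equal(tt$b, c(0.003, 0.01, 0.013, 0.0048))
  expect_equal(tt$d, c(3.5, 2.475, 2.5, 2))
})

test_that("config validation and YAML round trip", {
  cfg <- default_config()
  path <- file.path(tempdir(), "cfg.yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$tissues, cfg$tissues, tolerance = 1e-9)
  expect_equal(cfg2$diffusion_unit, cfg$diffusion_unit)
  bad <- cfg; bad$tissues$b[1] <- -1
  expect_error(validate_config(bad), class = "nodalsim_parameter_error")
})
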