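test_that("axis-aligned fiber tensor is diagonal with the right eigenvalues", {
  Dm <- build_tensor(c(1, 0, 0), D_l = 2, D_t = 0.2)
  expect_equal(Dm, diag(c(2, 0.2, 0.2)))
  expect_equal(build_tensor(c(0, 1, 0), 7, 7), 7 * diag(3))
})

test_that("random fiber tensors have eigenstructure {D_l, D_t, D_t}", {
  set.seed(42)
  for (i in 1:20) {
    f <- rnorm(3); f <- f / sqrt(sum(f^2))
    Dl <- runif(1, 1, 5); Dt <- runif(1, 0.1, Dl)
    Dm <- build_tensor(f, Dl, Dt)
    expect_equal(Dm, t(Dm))
    ev <- eigen(Dm, symmetric = TRUE)
    expect_equal(sort(ev$values), sort(c(Dl, Dt, Dt)), tolerance = 1e-10)
    # f is the eigenvector at D_l
    expect_equal(as.numeric(Dm %*% f), Dl * f, tolerance = 1e-10)
  }
  expect_error(build_tensor(c(1, 1, 0), 2, 1), class = "nodalsim_parameter_error")
  expect_error(build_tensor(c(1, 0, 0), 1, 2), class = "nodalsim_parameter_error")
})

test_that("diffusion of a uniform field is identically zero", {
  g <- make_strand(n_long = 20, n_cross = 4)
  u0 <- array(0.37, dim(g$labels))
  s <- simulate_fhn(g, duration = 1, init = list(u = u0, v = 0 * u0),
                    diffusion_only = TRUE, probes = "mid")
  expect_equal(max(abs(s$state$u - 0.37)), 0, tolerance = 1e-13)
})

test_that("no-flux diffusion conserves total u over 1000 steps", {
  # smooth random field on a geometry with holes and several tissue codes
  g <- make_idealized_right_atrium(150, 150)
  d <- dim(g$labels)
  xg <- (seq_len(d[1]) - 70) / 40; yg <- (seq_len(d[2]) - 60) / 35
  u0 <- array(outer(exp(-xg^2), exp(-yg^2)), d)
  u0[g$labels == 0L] <- 0
  s <- simulate_fhn(g, duration = 1000 * 0.002, dt = 0.002,
                    init = list(u = u0, v = 0 * u0),
                    diffusion_only = TRUE, probes = "san_centre")
  expect_lt(abs(sum(s$state$u) - sum(u0)) / sum(u0), 1e-8)
})

test_that("isotropic spread matches the heat-kernel variance growth", {
  # 1D Gaussian profile on a long strand; var grows as 2 D t
  g <- make_strand(n_long = 220, n_cross = 3, tissue = "atrial")
  cfg <- default_config()
  D <- cfg$diffusion_unit * 7          # mm^2/ms
  d <- dim(g$labels)
  x <- (seq_len(d[1]) - 110) * g$dx    # mm
  s0 <- 0.35
  u0 <- array(rep(exp(-x^2 / (2 * s0^2)), d[2] * d[3]), d)
  t_run <- 3
  s <- simulate_fhn(g, duration = t_run, dt = 0.002, config = cfg,
                    init = list(u = u0, v = 0 * u0),
                    diffusion_only = TRUE, probes = "mid")
  prof <- array(s$state$u, d)[, 2, 2]
  var_emp <- sum(prof * x^2) / sum(prof)
  var_th <- s0^2 + 2 * D * t_run
  expect_lt(abs(var_emp - var_th) / var_th, 0.01)
})

test_that("conduction is isotropic along the three lattice axes", {
  cfg <- default_config()
  cvs <- vapply(1:3, function(ax) {
    dims <- c(12, 12, 12); dims[ax] <- 40
    g <- make_strand(n_long = 3, n_cross = 3)   # template, rebuilt below
    labels <- array(1L, dims)
    g <- nodalsim:::new_geometry(labels, 0.06, probes = tibble::tibble(
      name = c("a", "b"),
      x = if (ax == 1) c(10, 30) else 6, y = if (ax == 2) c(10, 30) else 6,
      z = if (ax == 3) c(10, 30) else 6))
    s <- simulate_fhn(g, duration = 40, config = cfg,
                      stimuli = list(stimulus(region_layers(g, 1:3, axis = ax),
                                              at = 1, duration = 1)),
                      probes = c("a", "b"), record_dt = 0.5)
    20 * 0.06 / (s$events[["b"]][1] - s$events[["a"]][1])
  }, numeric(1))
  expect_lt(max(cvs) / min(cvs), 1.02)
})

test_that("conduction velocity scales as the square root of diffusion", {
  g <- make_strand(tissue = "atrial")
  cv_for <- function(mult) {
    cfg <- default_config()
    cfg$tissues$D[cfg$tissues$tissue == "atrial"] <- 7 * mult
    s <- simulate_fhn(g, duration = 40, config = cfg,
                      stimuli = list(stimulus(region_layers(g, 1:3), 2, 1)),
                      probes = "mid", record_dt = 1)
    conduction_velocity(s, 10, 40)
  }
  expect_equal(cv_for(2) / cv_for(1), sqrt(2), tolerance = 0.03)
})

test_that("instability is detected and reported with the offending dt", {
  g <- make_strand(n_long = 10, n_cross = 3, tissue = "atrial")
  expect_error(
    simulate_fhn(g, duration = 5, dt = 0.05,   # far beyond the bound
                 stimuli = list(stimulus(region_layers(g, 1:2), 1, 1)),
                 probes = "mid"),
    class = "nodalsim_stability_error")
})

test_that("halving dt changes strand conduction velocity by <1%", {
  g <- make_strand(tissue = "atrial")
  cv_at <- function(dt) {
    s <- simulate_fhn(g, duration = 35, dt = dt,
                      stimuli = list(stimulus(region_layers(g, 1:3), 2, 1)),
                      probes = "mid", record_dt = 1)
    conduction_velocity(s, 10, 40)
  }
  expect_lt(abs(cv_at(0.005) - cv_at(0.0025)) / cv_at(0.005), 0.01)
})

test_that("stimulus contracts: empty region, zero duration, idempotence", {
  g <- make_strand(n_long = 12, n_cross = 3)
  empty <- array(FALSE, dim(g$labels))
  expect_error(simulate_fhn(g, 2, stimuli = list(stimulus(empty, 1)),
                            probes = "mid"),
               class = "nodalsim_parameter_error")
  # zero-duration set-u stimulus leaves the state unchanged
  s0 <- simulate_fhn(g, duration = 3, probes = "mid")
  s1 <- simulate_fhn(g, duration = 3, probes = "mid",
                     stimuli = list(stimulus(region_layers(g, 1), at = 1,
                                             duration = 0)))
  expect_equal(s1$state$u, s0$state$u)
  # re-applying a clamp during its window is a no-op (idempotent)
  st <- list(u = array(0, dim(g$labels)), v = array(0, dim(g$labels)))
  st1 <- apply_stimulus(st, g, region_layers(g, 1), amplitude = 1)
  st2 <- apply_stimulus(st1, g, region_layers(g, 1), amplitude = 1)
  expect_identical(st1, st2)
})

test_that("a premature stimulus inside the refractory period does not propagate", {
  g <- make_strand(tissue = "atrial")
  s <- simulate_fhn(g, duration = 100,
                    stimuli = list(stimulus(region_layers(g, 1:3), 2, 1),
                                   stimulus(region_layers(g, 1:3), 42, 1)),
                    probes = "layer_40", record_dt = 1)
  ev <- s$events[["layer_40"]]
  expect_length(ev, 1)   # only the conditioning wave arrives
})

test_that("snapshots and VTK export round the field through disk", {
  g <- make_strand(n_long = 15, n_cross = 3)
  s <- simulate_fhn(g, duration = 10, snapshot_dt = 2,
                    stimuli = list(stimulus(region_layers(g, 1:3), 1, 1)),
                    probes = "mid")
  expect_gt(length(s$frames$t), 3)
  path <- file.path(tempdir(), "act.vtk")
  write_vtk(s, path, "activation")
  txt <- readLines(path)
  expect_true(any(grepl("STRUCTURED_POINTS", txt)))
  expect_true(any(grepl("DIMENSIONS 15 3 3", txt)))
})
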