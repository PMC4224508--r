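# parameterized equivalence against the brute-force reference automaton:
# random heterogeneous 20x20 lattices (three tissue classes plus holes),
# compared state by state over 120 synchronous steps
test_that("automaton is state-identical to the brute-force reference", {
  set.seed(7)
  for (case in 1:3) {
    nr <- 20; nc <- 20
    codes <- c(0L, 1L, 2L, 9L)   # hole, atrial, nodal extension, transitional
    labels2d <- matrix(sample(codes, nr * nc, TRUE,
                              prob = c(0.08, 0.5, 0.21, 0.21)), nr, nc)
    pars <- tibble::tibble(
      tissue = c("atrial", "ine", "tz"),
      theta = sample(1:4, 3, TRUE), gain = 1,
      E = sample(6:12, 3, TRUE), R = sample(10:40, 3, TRUE))
    # per-cell parameter matrices for the reference implementation
    ca_name <- c("1" = "atrial", "2" = "ine", "9" = "tz")
    idx <- match(ca_name[as.character(labels2d)], pars$tissue)
    to_mat <- function(v, default) {
      m <- matrix(default, nr, nc); m[!is.na(idx)] <- v[idx[!is.na(idx)]]; m
    }
    active <- matrix(!is.na(idx), nr, nc)
    theta <- to_mat(pars$theta, 1); E <- to_mat(pars$E, 1)
    R <- to_mat(pars$R, 0); gain <- matrix(1, nr, nc)
    stim_cells <- cbind(sample(nr, 6), sample(nc, 6))
    stimuli <- list(list(step = 0, cells = stim_cells),
                    list(step = 60, cells = stim_cells))
    n_steps <- 120
    ref <- ca_oracle(active, theta, gain, E, R, n_steps, stimuli,
                     neighborhood = 4)

    labels <- array(labels2d, c(nr, nc, 1))
    g <- nodalsim:::new_geometry(labels, 0.06,
                                 probes = tibble::tibble(name = "p", x = 1L,
                                                         y = 1L, z = 1L))
    stim_idx <- function(cells) {
      reg <- array(FALSE, c(nr, nc, 1))
      reg[cbind(cells, 1)] <- TRUE
      reg
    }
    state <- list(state = integer(nr * nc), phase = integer(nr * nc),
                  e = numeric(nr * nc), step = 0L)
    for (step in seq_len(n_steps)) {
      stims <- list()
      for (sv in stimuli) if (sv$step == step - 1)
        stims <- c(stims, list(ca_stimulus(stim_idx(sv$cells),
                                           at = (step - 1) * 0.1)))
      s <- simulate_ca(g, duration = 0.1, params = pars, dt = 0.1,
                       stimuli = stims, probes = "p", init = state)
      state <- s$state
      hist <- ref$history[[step]]
      expect_identical(matrix(state$state, nr, nc)[active],
                       hist$state[active],
                       label = sprintf("case %d step %d state", case, step))
      expect_equal(matrix(state$e, nr, nc)[active], hist$e[active],
                   label = sprintf("case %d step %d counter", case, step))
    }
  }
})

test_that("wavefront speed on a uniform fiber is constant after a transient", {
  g <- make_strand(n_long = 60, n_cross = 3)
  pars <- ca_params(0.1)
  s <- simulate_ca(g, duration = 60, params = pars, dt = 0.1,
                   stimuli = list(ca_stimulus(region_layers(g, 1), 0)))
  act <- s$activation[, 2, 2]
  steps <- diff(act[6:55])
  expect_equal(length(unique(round(steps, 6))), 1)  # constant nodes/step
  expect_equal(unique(round(steps, 6)),
               pars$theta[pars$tissue == "atrial"] * 0.1)
})

test_that("a node cannot re-fire during its refractory phase", {
  g <- make_single_cell("atrial")
  reg <- array(TRUE, c(1, 1, 1))
  pars <- ca_params(0.1)
  s <- simulate_ca(g, duration = 120, params = pars, dt = 0.1,
                   stimuli = list(ca_stimulus(reg, 1), ca_stimulus(reg, 40),
                                  ca_stimulus(reg, 100)))
  ev <- s$events[["cell"]]
  # the 40 ms stimulus falls inside the 81 ms refractory period
  expect_equal(length(ev), 2)
  expect_gte(diff(ev), ca_refractory_period(
    dplyr::filter(pars, tissue == "atrial"), 0.1))
})

test_that("effective refractory period equals (E+R)*dt and the S1-S2 scan", {
  pars <- ca_params(0.1)
  for (tis in c("atrial", "tz")) {
    row <- dplyr::filter(pars, tissue == tis)
    rp_nominal <- ca_refractory_period(row, 0.1)
    # S1-S2 on a fiber: exhaustive 1 ms sweep around the nominal value
    g <- make_strand(n_long = 30, n_cross = 3)
    fiber_pars <- dplyr::mutate(row, tissue = "atrial")
    conducts <- vapply(seq(rp_nominal - 4, rp_nominal + 4), function(ci) {
      s <- simulate_ca(g, duration = ci + 40, params = fiber_pars, dt = 0.1,
                       stimuli = list(ca_stimulus(region_layers(g, 1), 2),
                                      ca_stimulus(region_layers(g, 1), 2 + ci)),
                       probes = "layer_25")
      sum(s$events[["layer_25"]] > 2 + ci) > 0
    }, logical(1))
    rp_meas <- seq(rp_nominal - 4, rp_nominal + 4)[which(conducts)[1]]
    expect_equal(rp_meas, rp_nominal, tolerance = 1e-9)
  }
  # degenerate case: R = 0 -> refractoriness is just the excited period
  expect_equal(ca_refractory_period(list(E = 30, R = 0), 0.1), 3)
})

test_that("published automaton refractory periods are encoded", {
  pars <- ca_params(0.1)
  rp <- vapply(c("atrial", "ine", "tz", "pb"), function(t)
    ca_refractory_period(dplyr::filter(pars, tissue == t), 0.1), numeric(1))
  expect_equal(unname(rp), c(81, 94, 134, 154))
})

test_that("conduction-velocity tuning hits its targets and flags bad ones", {
  for (tgt in c(0.104, 0.154)) {
    p <- ca_tune_cv(tgt, dx = 0.06, dt = 0.1)
    expect_lt(abs(attr(p, "cv_measured") - tgt) / tgt, 0.10)
  }
  # one node per step is the automaton's maximum speed
  p <- ca_tune_cv(0.6, dx = 0.06, dt = 0.1)
  expect_equal(p$theta, 1)
  expect_error(ca_tune_cv(5, dx = 0.06, dt = 0.1),
               class = "nodalsim_range_error")
  expect_error(ca_tune_cv(0.135, dx = 0.06, dt = 0.1),
               class = "nodalsim_range_error")  # between representable speeds
})

test_that("a premature wave is blocked exactly below the refractory period", {
  g <- make_strand(n_long = 30, n_cross = 3)
  pars <- ca_params(0.1)
  row <- dplyr::filter(pars, tissue == "atrial")
  for (ci in c(79, 80, 81, 82)) {
    s <- simulate_ca(g, duration = ci + 40, params = pars, dt = 0.1,
                     stimuli = list(ca_stimulus(region_layers(g, 1), 2),
                                    ca_stimulus(region_layers(g, 1), 2 + ci)),
                     probes = "layer_25")
    got <- sum(s$events[["layer_25"]] > 2 + ci) > 0
    expect_identical(got, ci >= ca_refractory_period(row, 0.1),
                     label = sprintf("ci=%d", ci))
  }
})
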