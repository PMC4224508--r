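#' Cellular-automaton tissue parameters
#'
#' Per-tissue parameters of the three-state automaton: excitation threshold
#' `theta` (counter units), counter gain per excited neighbour per step,
#' excited period `E` and refractory period `R` (steps), at the automaton
#' time step `dt` (ms).  A resting node adjacent to a single excited
#' neighbour fires after `ceiling(theta/gain)` steps, so with unit gain
#' `theta` is the conduction delay per node; the effective refractory
#' period is `(E + R) * dt`.
#'
#' Defaults encode the published automaton behaviour at `dt = 0.1` ms on
#' the 60 um lattice: conduction velocities 0.30 (atrial), 0.10 (inferior
#' nodal extension), 0.15 (transitional zone), 0.10 (penetrating bundle)
#' m/s and refractory periods 81, 94, 134, 154 ms; the node row is an
#' extension carrying the long nodal refractory period (283 ms) used by the
#' fibrillation scenario.
#'
#' @param dt Automaton time step in ms.
#' @return Tibble with columns `tissue`, `theta`, `gain`, `E`, `R`.
#' @export
#' @examples
#' ca_params()
ca_params <- function(dt = 0.1) {
  rp_steps <- function(rp_ms) round(rp_ms / dt)
  base <- tibble::tribble(
    ~tissue,  ~theta, ~rp_ms,
    "atrial",   2,      81,
    "ine",      6,      94,
    "tz",       4,     134,
    "pb",       6,     154,
    "san",      9,     283
  )
  # the excited (neighbour-exciting) phase is kept short -- just beyond the
  # slowest accumulation delay -- and the refractory phase carries the rest
  # of the refractory period; long excited phases would re-fire short-RP
  # nodes across heterogeneous tissue borders
  dplyr::transmute(base,
    tissue = .data$tissue,
    theta = .data$theta,
    gain = 1,
    E = pmax(.data$theta + 2, round(1.5 / dt)),
    R = rp_steps(.data$rp_ms) - pmax(.data$theta + 2, round(1.5 / dt))
  )
}

#' Effective automaton refractory period
#'
#' The shortest interval after firing at which a node can fire again:
#' `(E + R) * dt` ms.  With `R = 0` it degenerates to the excited period.
#'
#' @param params One row of [ca_params()] (or named list with `E`, `R`).
#' @param dt Automaton step (ms).
#' @return Refractory period in ms.
#' @export
ca_refractory_period <- function(params, dt = 0.1) {
  p <- as.list(params)
  (p$E + p$R) * dt
}

#' Tune automaton parameters to a conduction-velocity target
#'
#' Solves for the per-node firing delay `k = ceiling(theta/gain)` such that
#' the 1D wavefront speed `dx/(k dt)` is within 10 percent of the target,
#' then verifies the choice by simulating a fiber.  Slow conduction is
#' implemented by multi-step counter accumulation (larger `theta`).
#'
#' @param target_cv Target conduction velocity (m/s).
#' @param dx Lattice spacing (mm).
#' @param dt Automaton step (ms).
#' @param rp_ms Refractory period the returned parameter set should carry.
#' @return One-row tibble like [ca_params()], with attribute `cv_measured`.
#' @export
#' @examples
#' ca_tune_cv(0.104, dx = 0.06, dt = 0.1)
ca_tune_cv <- function(target_cv, dx = 0.06, dt = 0.1, rp_ms = 100) {
  cv_max <- dx / dt            # one node per step, mm/ms = m/s
  k <- round(cv_max / target_cv)
  if (k < 1 || target_cv > cv_max * 1.1 || k > 200)
    abort(sprintf(
      "target %.3g m/s unreachable: achievable range %.3g..%.3g m/s",
      target_cv, cv_max / 200, cv_max), class = "nodalsim_range_error")
  achieved <- cv_max / k
  if (abs(achieved - target_cv) / target_cv > 0.10) {
    abort(sprintf(
      "target %.3g m/s not representable within 10%% (nearest %.3g m/s)",
      target_cv, achieved), class = "nodalsim_range_error")
  }
  E <- max(k + 2, round(1.5 / dt))
  p <- tibble(tissue = "custom", theta = k, gain = 1, E = E,
              R = round(rp_ms / dt) - E)
  # verify on a fiber
  cv <- ca_fiber_cv(p, n = 60, dx = dx, dt = dt)
  attr(p, "cv_measured") <- cv
  p
}

# measured 1D automaton conduction velocity (m/s) for a parameter row
ca_fiber_cv <- function(p, n = 60, dx = 0.06, dt = 0.1) {
  g <- make_strand(n_long = n, n_cross = 3, tissue = "atrial", dx = dx)
  pars <- dplyr::mutate(p, tissue = "atrial")
  s <- simulate_ca(g, duration = n * p$theta * dt * 1.5 + 20, params = pars,
                   dt = dt, stimuli = list(ca_stimulus(region_layers(g, 1), at = 0)))
  amap <- s$activation
  t10 <- mean(amap[10, , ], na.rm = TRUE); t40 <- mean(amap[min(40, n - 5), , ], na.rm = TRUE)
  (min(40, n - 5) - 10) * dx / (t40 - t10)
}

#' Automaton stimulus event
#'
#' Fires every resting node of the region at time `at`; refractory or
#' excited nodes are unaffected (a premature stimulus into refractory
#' tissue does nothing, as in the automaton's refractory branch).
#'
#' @inheritParams stimulus
#' @export
ca_stimulus <- function(region, at) {
  structure(list(region = region, at = at), class = "nodal_ca_stimulus")
}

# per-voxel automaton parameter vectors
build_ca_kinetics <- function(g, params) {
  labs <- as.vector(g$labels)
  codes <- g$codes
  kin <- codes$kinetics[match(labs, codes$code)]
  # automaton tissue naming: transitional zone has its own row; block zone
  # is inexcitable; the node uses its extension row
  ca_name <- kin
  ca_name[labs == 9L] <- "tz"
  ca_name[kin %in% "passive"] <- NA
  i <- match(ca_name, params$tissue)
  active <- as.integer(!is.na(i) & labs != 0L)
  grab <- function(f, default = 0) {
    v <- params[[f]][i]; v[is.na(v)] <- default; v
  }
  list(active = active, theta = grab("theta", 1), gain = grab("gain", 1),
       E = as.integer(grab("E", 1)), R = as.integer(grab("R", 0)))
}

#' Run the cellular-automaton engine
#'
#' Synchronous update of the three-state automaton (resting, excited,
#' refractory with per-node excitation counters) over a labelled geometry.
#' Produces the same activation-map / probe-event surface as
#' [simulate_fhn()], so every measurement applies to both engines.
#'
#' @param g A `nodal_geometry`.
#' @param duration Simulated time (ms).
#' @param params Parameter table from [ca_params()]; rows are matched to the
#'   geometry's kinetic classes (`atrial`, `ine`, `pb`, `san`, plus the
#'   transitional-zone code).
#' @param dt Automaton step (ms).
#' @param stimuli List of [ca_stimulus()] events.
#' @param probes Probe names to record (default all).
#' @param init Optional state to continue (list `state`, `phase`, `e`,
#'   `step`).
#' @param neighborhood 6 or 26 (3D connectivity; 4 or 8 in a single-slice
#'   geometry).
#' @return A `nodal_sim` with `engine = "ca"`.
#' @export
#' @examples
#' g <- make_strand(n_long = 30, n_cross = 3)
#' s <- simulate_ca(g, 40, stimuli = list(ca_stimulus(region_layers(g, 1), 0)))
#' conduction_velocity(s, from_layer = 10, to_layer = 25)
simulate_ca <- function(g, duration, params = ca_params(dt), dt = 0.1,
                        stimuli = list(), probes = NULL, init = NULL,
                        neighborhood = 6) {
  if (!neighborhood %in% c(6, 26))
    abort("neighborhood must be 6 or 26", class = "nodalsim_parameter_error")
  kin <- build_ca_kinetics(g, params)
  N <- length(g$labels)
  if (is.null(init))
    init <- list(state = integer(N), phase = integer(N), e = numeric(N),
                 step = 0L)
  n_steps <- max(1L, round(duration / dt))
  if (is.null(probes)) probes <- g$probes$name
  pidx <- probe_flat_index(g, probes)
  stim_list <- lapply(stimuli, function(s)
    list(step = as.integer(round(s$at / dt)),
         idx = region_to_index(s$region, g)))

  res <- .ca_run_cpp(init$state, init$phase, init$e, dim(g$labels),
                     kin$active, kin$theta, kin$gain, kin$E, kin$R,
                     n_steps, init$step, as.integer(neighborhood),
                     pidx, stim_list)

  events <- stats::setNames(
    lapply(res$fire_steps, function(st) as.numeric(st) * dt), probes)
  act <- array(as.numeric(res$activation_step) * dt, dim(g$labels))

  structure(list(
    engine = "ca", geometry = g, config = list(dt = dt, threshold = 0.5),
    dt = dt, duration = n_steps * dt, t0 = init$step * dt,
    t_end = res$step_end * dt,
    params = params,
    traces = tibble(time = numeric(), site = character(), u = numeric()),
    events = events, activation = act,
    state = list(state = res$state, phase = res$phase, e = res$e,
                 step = res$step_end),
    stimuli = stimuli
  ), class = "nodal_sim")
}
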