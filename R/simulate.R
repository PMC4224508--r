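#' Stimulus events
#'
#' Builds one stimulus event for [simulate_fhn()].  `mode = "set"` clamps
#' the excitation variable to `amplitude` over the region for the stated
#' duration (idempotent: re-applying it changes nothing); `mode = "add"`
#' injects a constant current (adds `amplitude` to du/dt).
#'
#' @param region Integer matrix/data frame of voxel coordinates (columns
#'   x, y, z, 1-based), or a logical array congruent with the lattice.
#' @param at Onset time (ms).
#' @param duration Duration (ms); zero-duration stimuli are legal no-ops.
#' @param amplitude Clamp level or current density.
#' @param mode `"set"` or `"add"`.
#' @return A `nodal_stimulus` list.
#' @export
stimulus <- function(region, at, duration = 1, amplitude = 1, mode = "set") {
  mode <- match.arg(mode, c("set", "add"))
  structure(list(region = region, at = at, duration = duration,
                 amplitude = amplitude, mode = mode),
            class = "nodal_stimulus")
}

#' First-layers stimulus region of a strand or slab
#'
#' @param g A `nodal_geometry`.
#' @param layers Layer indices along `axis` (default the first three).
#' @param axis Lattice axis (1 = x).
#' @return A logical array marking the region.
#' @export
region_layers <- function(g, layers = 1:3, axis = 1) {
  d <- dim(g$labels)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- layers
  out[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  out & g$labels != 0L
}

region_to_index <- function(region, g) {
  d <- dim(g$labels)
  if (is.array(region) && is.logical(region)) {
    if (!identical(dim(region), d))
      abort("stimulus region array must match the lattice",
            class = "nodalsim_parameter_error")
    idx <- which(region) - 1L
  } else {
    region <- as.matrix(as.data.frame(region))
    idx <- (region[, 1] - 1L) + d[1] * (region[, 2] - 1L) +
      d[1] * d[2] * (region[, 3] - 1L)
  }
  idx <- idx[as.vector(g$labels)[idx + 1L] != 0L]
  if (length(idx) == 0)
    abort("stimulus region is empty (no tissue voxels)",
          class = "nodalsim_parameter_error")
  as.integer(idx)
}

# per-voxel kinetic parameter vectors, with the SAN periphery blend applied
build_kinetics <- function(g, config) {
  labs <- as.vector(g$labels)
  N <- length(labs)
  codes <- g$codes
  kin <- codes$kinetics[match(labs, codes$code)]

  model <- integer(N)   # 0 hole, 1 Rogers, 2 passive, 3 pacemaking (additive)
  model[!is.na(kin) & kin != "passive" & labs != 0L] <- 1L
  model[!is.na(kin) & kin == "passive"] <- 2L
  model[!is.na(kin) & kin == "san"] <- 3L

  par_of <- function(field) {
    v <- config$tissues[[field]][match(kin, config$tissues$tissue)]
    v[is.na(v)] <- 0
    v
  }
  c1 <- par_of("c1"); c2 <- par_of("c2"); b <- par_of("b")
  d_ <- par_of("d"); alpha <- par_of("alpha")
  j0 <- if ("j" %in% names(config$tissues)) par_of("j") else numeric(N)
  rb <- rep(config$block$rb, N)

  # SAN periphery: grade c1 (and the threshold with it) linearly over the
  # border band toward the atrial values, by lattice distance to the
  # nearest atrial-kinetics voxel
  san_mask <- array(kin %in% "san", dim(g$labels))
  atr_mask <- array(kin %in% "atrial", dim(g$labels))
  if (any(san_mask) && any(atr_mask)) {
    bw <- config$periphery$band_width
    dist <- lattice_distance(atr_mask, bw + 1L)
    ds <- pmin(as.vector(dist)[san_mask], bw + 1)
    in_band <- ds <= bw
    if (any(in_band)) {
      san_row <- tissue_row(config, "san")
      atr_row <- tissue_row(config, "atrial")
      rule <- list(band_width = bw, c1S = san_row$c1, c1A_ref = atr_row$c1)
      idx <- which(san_mask)[in_band]
      c1[idx] <- blend_periphery(ds[in_band], rule)
      # the border loses automaticity toward the atrium (pacemaker current
      # fades, threshold rises to a small positive value) but keeps a low
      # threshold relative to atrial muscle: an excitable amplifier that
      # carries the nodal impulse out against the atrial current sink
      frac <- pmin(ds[in_band], bw) / bw
      a_edge <- config$periphery$alpha_edge
      alpha[idx] <- a_edge + (san_row$alpha - a_edge) * frac
      j0[idx] <- j0[idx] * frac
    }
  }
  list(model = model, c1 = c1, c2 = c2, b = b, d = d_, alpha = alpha,
       j0 = j0, rb = rb)
}

default_init <- function(g, config, kin) {
  N <- length(g$labels)
  u <- numeric(N); v <- numeric(N)
  # pacemaking voxels start with a small diastolic depolarization so the
  # node starts beating immediately instead of creeping off u = 0
  u[kin$model == 3L] <- config$san_init_u
  list(u = u, v = v)
}

#' Run the reaction-diffusion engine
#'
#' Explicit forward-Euler integration of the modified FitzHugh-Nagumo system
#' over a labelled voxel geometry: per-voxel kinetics by tissue class
#' (pacemaking node, excitable muscle/nodal tissue, passive block zone, SAN
#' periphery blend), conservative anisotropic diffusion with no-flux
#' boundaries, stimulus events, probe traces, threshold-crossing event
#' detection and a first-activation map.
#'
#' @param g A `nodal_geometry`.
#' @param duration Simulated time (ms).
#' @param config A [default_config()] list.
#' @param stimuli List of [stimulus()] events.
#' @param dt Time step (ms); defaults to `config$dt`, reduced automatically
#'   if the diffusion stability bound requires it.
#' @param init Optional list `u`, `v` (flat or arrays) to continue a run.
#' @param probes Character vector of probe names to record (default all).
#' @param record_dt Trace sampling interval (ms).
#' @param snapshot_dt If set, store full-field snapshots at this interval.
#' @param diffusion_only Disable the reaction terms (used by conservation
#'   and heat-kernel checks).
#' @return A `nodal_sim` object: probe traces (tibble), per-probe activation
#'   event times, activation map, final state and run metadata.
#' @export
#' @examples
#' g <- make_strand(n_long = 20, tissue = "atrial")
#' s <- simulate_fhn(g, duration = 30,
#'                   stimuli = list(stimulus(region_layers(g), at = 1)))
#' dplyr::filter(tidy(s), !is.na(t_activation))[1:3, ]
simulate_fhn <- function(g, duration, config = default_config(),
                         stimuli = list(), dt = NULL, init = NULL,
                         probes = NULL, record_dt = 0.1, snapshot_dt = NULL,
                         diffusion_only = FALSE) {
  kin <- build_kinetics(g, config)
  tf <- build_tensor_field(g, config)
  dt_max <- stable_dt(tf)
  if (is.null(dt)) {
    # default step, reduced automatically to the diffusion stability bound
    dt <- config$dt
    if (dt > 0.95 * dt_max) dt <- 0.95 * dt_max
  }
  n_steps <- max(1L, ceiling(duration / dt))

  if (is.null(init)) init <- default_init(g, config, kin)
  u0 <- as.vector(init$u); v0 <- as.vector(init$v)
  t0 <- init$t %||% 0

  if (is.null(probes)) probes <- g$probes$name
  pidx <- probe_flat_index(g, probes)

  stim_list <- lapply(stimuli, function(s) {
    list(t_on = s$at, t_off = s$at + s$duration, amplitude = s$amplitude,
         mode = if (s$mode == "set") 0L else 1L,
         idx = region_to_index(s$region, g))
  })

  record_every <- max(1L, round(record_dt / dt))
  snapshot_every <- if (is.null(snapshot_dt)) 0L else
    max(1L, round(snapshot_dt / dt))

  res <- .fhn_run_cpp(u0, v0, dim(g$labels), kin$model,
                      kin$c1, kin$c2, kin$b, kin$d, kin$alpha, kin$rb,
                      kin$j0, tf, dt, n_steps, t0, pidx, record_every,
                      stim_list, config$threshold,
                      snapshot_every, diffusion_only)
  if (res$status != 0)
    abort(sprintf(paste0("numerical instability at t = %.3f ms ",
                         "(dt = %g ms); reduce dt"), res$bad_t, dt),
          class = "nodalsim_stability_error")

  traces <- tibble(time = rep(res$trace_t, length(probes)),
                   site = rep(probes, each = length(res$trace_t)),
                   u = as.vector(res$trace_u),
                   v = as.vector(res$trace_v))
  events <- stats::setNames(lapply(res$events, as.numeric), probes)

  structure(list(
    engine = "fhn", geometry = g, config = config, dt = dt,
    duration = n_steps * dt, t0 = t0, t_end = res$t_end,
    traces = traces, events = events,
    activation = array(res$activation, dim(g$labels)),
    state = list(u = res$u, v = res$v, t = res$t_end),
    frames = if (snapshot_every > 0 && res$n_frames > 0)
      list(u = res$frames[, seq_len(res$n_frames), drop = FALSE],
           t = res$frame_t[seq_len(res$n_frames)]),
    stimuli = stimuli
  ), class = c("nodal_sim"))
}

#' Apply a stimulus to a stored state
#'
#' Convenience wrapper used by protocol code: clamps or kicks `u` inside a
#' region of an existing state without running the integrator.
#'
#' @param state List with `u` (flat or array).
#' @param g Geometry the state lives on.
#' @param region As in [stimulus()].
#' @param amplitude Clamp level (`mode = "set"`) or increment (`"add"`).
#' @param mode `"set"` or `"add"`.
#' @return The modified state.
#' @export
apply_stimulus <- function(state, g, region, amplitude = 1, mode = "set") {
  idx <- region_to_index(region, g) + 1L
  if (mode == "set") state$u[idx] <- amplitude
  else state$u[idx] <- state$u[idx] + amplitude
  state
}

#' @export
print.nodal_sim <- function(x, ...) {
  cat(sprintf("<nodal_sim: %s engine> %.1f ms on %s lattice, dt = %g ms\n",
              x$engine, x$duration, paste(dim(x$geometry$labels),
                                          collapse = " x "), x$dt))
  n_act <- sum(!is.na(x$activation))
  cat(sprintf("  %d/%d voxels activated; %d probes recorded\n",
              n_act, sum(x$geometry$labels != 0), length(x$events)))
  invisible(x)
}

#' Probe trace as a tibble
#'
#' @param sim A `nodal_sim`.
#' @param site Probe name.
#' @return Tibble with `time`, `u` (and `v` for the reaction-diffusion
#'   engine).
#' @export
probe_trace <- function(sim, site) {
  tr <- dplyr::filter(sim$traces, .data$site == !!site)
  if (nrow(tr) == 0)
    abort(sprintf("no trace recorded at '%s'", site),
          class = "nodalsim_parameter_error")
  tr
}
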