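#' Activation map as a tibble
#'
#' Per-voxel first crossing of the activation threshold (upward), in ms;
#' unactivated tissue voxels carry `NA`.
#'
#' @param sim A `nodal_sim`.
#' @return Tibble with `x`, `y`, `z`, `code`, `t_activation`.
#' @export
activation_map <- function(sim) {
  d <- dim(sim$geometry$labels)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  out <- tibble::as_tibble(grid)
  out$code <- as.vector(sim$geometry$labels)
  out$t_activation <- as.vector(sim$activation)
  dplyr::filter(out, .data$code != 0L)
}

#' Conduction velocity between two element layers
#'
#' Mean first-activation time of all tissue voxels in each layer
#' (perpendicular to `axis`); velocity is the layer-centroid distance over
#' the mean time difference, in m/s.  By convention strand velocity is read
#' from layer 10 to layer 40.
#'
#' @param sim A `nodal_sim` (either engine).
#' @param from_layer,to_layer Layer indices along `axis`.
#' @param axis Lattice axis the wave travels along (1 = x).
#' @param window Optional `c(t0, t1)`: use only activations inside the
#'   window (for beats later than the first, supply per-probe events
#'   instead).
#' @return Conduction velocity (m/s).  If either layer contains an
#'   unactivated voxel a `nodalsim_propagation_failure` error is raised --
#'   the refractory-period scan relies on that signal.
#' @export
conduction_velocity <- function(sim, from_layer = 10, to_layer = 40,
                                axis = 1, window = NULL) {
  g <- sim$geometry
  act <- sim$activation
  if (!is.null(window)) act[act < window[1] | act > window[2]] <- NA
  d <- dim(act)
  layer_time <- function(layer) {
    idx <- lapply(d, seq_len); idx[[axis]] <- layer
    a <- act[idx[[1]], idx[[2]], idx[[3]]]
    tissue <- g$labels[idx[[1]], idx[[2]], idx[[3]]] != 0L
    if (any(is.na(a[tissue])))
      abort(sprintf("layer %d not (fully) activated", layer),
            class = "nodalsim_propagation_failure")
    mean(a[tissue])
  }
  t1 <- layer_time(from_layer); t2 <- layer_time(to_layer)
  if (t2 == t1)
    abort("zero activation-time difference between layers",
          class = "nodalsim_measurement_error")
  dist_mm <- abs(to_layer - from_layer) * g$dx
  dist_mm / (t2 - t1)   # mm/ms == m/s
}

first_crossing <- function(time, u, thresh) {
  up <- which(u[-1] >= thresh & u[-length(u)] < thresh)
  if (length(up) == 0) return(NA_real_)
  i <- up[1]
  time[i] + (time[i + 1] - time[i]) * (thresh - u[i]) / (u[i + 1] - u[i])
}

#' Action potential duration at 90 percent repolarization
#'
#' Measured on a sampled trace: onset is the foot of the upstroke (last
#' sample before the activation-threshold crossing at which the potential
#' is within 5 percent of the pre-upstroke baseline), and the end is the
#' first later time at which the potential has returned 90 percent of the
#' way from the peak to that baseline, linearly interpolated between
#' samples.
#'
#' @param trace Tibble with `time` and `u` (one site), e.g.
#'   [probe_trace()].
#' @param threshold Activation detection threshold (normalized units).
#' @param window Optional `c(t0, t1)` restricting the measurement to one
#'   beat.
#' @return APD90 in ms.
#' @export
apd90 <- function(trace, threshold = 0.5, window = NULL) {
  tr <- trace[order(trace$time), ]
  if (!is.null(window)) tr <- tr[tr$time >= window[1] & tr$time <= window[2], ]
  tt <- tr$time; uu <- tr$u
  t_up <- first_crossing(tt, uu, threshold)
  if (is.na(t_up))
    abort("trace contains no activation", class = "nodalsim_measurement_error")
  pre <- uu[tt < t_up]
  baseline <- if (length(pre) > 0) min(pre) else uu[1]
  after <- tt >= t_up
  peak_i <- which.max(ifelse(after, uu, -Inf))
  peak <- uu[peak_i]
  amp <- peak - baseline
  if (amp <= 0)
    abort("no action potential amplitude", class = "nodalsim_measurement_error")
  # onset: last pre-crossing sample still near baseline
  onset_candidates <- which(tt < t_up & uu <= baseline + 0.05 * amp)
  t_onset <- if (length(onset_candidates) > 0) tt[max(onset_candidates)] else t_up
  # end: 90 % repolarized after the peak
  target <- peak - 0.9 * amp
  ii <- which(seq_along(uu) > peak_i & uu <= target)
  if (length(ii) == 0)
    abort("trace ends before 90% repolarization",
          class = "nodalsim_measurement_error")
  j <- ii[1]
  t_end <- if (uu[j - 1] > target)
    tt[j - 1] + (tt[j] - tt[j - 1]) * (uu[j - 1] - target) / (uu[j - 1] - uu[j])
  else tt[j]
  t_end - t_onset
}

#' Maximum upstroke velocity
#'
#' Maximum discrete du/dt over the (first) upstroke, in 1/ms for the
#' normalized potential; supplying the action-potential amplitude `apa`
#' (mV) also returns the conventional mV/ms value.
#'
#' @param trace Tibble with `time`, `u`.
#' @param apa Optional action-potential amplitude in mV.
#' @param window Optional time window.
#' @return Named list `du_dt` (1/ms) and, if `apa` given, `dvm_dt` (mV/ms).
#' @export
max_upstroke <- function(trace, apa = NULL, window = NULL) {
  tr <- trace[order(trace$time), ]
  if (!is.null(window)) tr <- tr[tr$time >= window[1] & tr$time <= window[2], ]
  if (nrow(tr) < 3)
    abort("trace too short", class = "nodalsim_measurement_error")
  slope <- diff(tr$u) / diff(tr$time)
  out <- list(du_dt = max(slope))
  if (!is.null(apa)) out$dvm_dt <- out$du_dt * apa
  out
}

#' Cycle length, rate and conduction ratio of event trains
#'
#' `cycle_length()` is the mean inter-activation interval of a probe's
#' event train (at least three activations required).
#' `dominant_frequency()` counts activations per unit time (robust on the
#' short records desk-scale runs produce).  `conduction_ratio()` reduces
#' the upstream:downstream activation counts inside a window to an integer
#' ratio and, per downstream beat, lists how many upstream events it
#' swallowed -- a mixed pattern (e.g. alternating 2:1/3:1) is reported as
#' such.
#'
#' @param events Numeric vector of activation times (ms), e.g. one element
#'   of `sim$events`.
#' @param discard_first Number of initial (transient) intervals to drop.
#' @return `cycle_length()`: ms. `dominant_frequency()`: Hz.
#' @export
cycle_length <- function(events, discard_first = 1) {
  if (length(events) < 3)
    abort("need at least 3 activations", class = "nodalsim_measurement_error")
  iv <- diff(events)
  if (discard_first > 0 && length(iv) > discard_first)
    iv <- iv[-seq_len(discard_first)]
  mean(iv)
}

#' @rdname cycle_length
#' @param window `c(t0, t1)` ms.
#' @export
dominant_frequency <- function(events, window = range(events)) {
  ev <- events[events >= window[1] & events <= window[2]]
  if (length(ev) < 2)
    abort("need at least 2 activations in window",
          class = "nodalsim_measurement_error")
  1000 * (length(ev) - 1) / (max(ev) - min(ev))
}

#' @rdname cycle_length
#' @param upstream,downstream Event trains (ms) of the driving and driven
#'   sites.
#' @export
conduction_ratio <- function(upstream, downstream, window = NULL) {
  if (!is.null(window)) {
    upstream <- upstream[upstream >= window[1] & upstream <= window[2]]
    downstream <- downstream[downstream >= window[1] & downstream <= window[2]]
  }
  n_up <- length(upstream); n_dn <- length(downstream)
  if (n_dn == 0)
    return(structure(list(up = n_up, down = 0L, text = sprintf("%d:0", n_up),
                          per_beat = integer()), class = "nodal_ratio"))
  g <- gcd2(n_up, n_dn)
  # events swallowed per conducted beat
  per_beat <- if (n_dn >= 2) {
    vapply(seq_len(n_dn - 1), function(i)
      sum(upstream >= downstream[i] & upstream < downstream[i + 1]),
      integer(1))
  } else integer()
  txt <- sprintf("%d:%d", n_up / g, n_dn / g)
  if (length(unique(per_beat)) > 1)
    txt <- paste0(txt, " (mixed: ",
                  paste(sort(unique(per_beat)), collapse = ":1, "), ":1)")
  structure(list(up = as.integer(n_up), down = as.integer(n_dn),
                 ratio = n_up / n_dn, text = txt, per_beat = per_beat),
            class = "nodal_ratio")
}

gcd2 <- function(a, b) if (b == 0) max(a, 1L) else gcd2(b, a %% b)

#' @export
print.nodal_ratio <- function(x, ...) {
  cat(sprintf("conduction ratio %s (%d upstream : %d downstream)\n",
              x$text, x$up, x$down))
  invisible(x)
}

#' Refractory period by the S1-S2 protocol
#'
#' Runs the engine on a strand-style geometry: a conditioning S1 stimulus
#' at the proximal end, then a premature S2 at the same site, and reports
#' the shortest S1-to-S2 coupling interval (onset to onset) at which the S2
#' wave still propagates to the far probe.  The coupling interval is found
#' by bisection refined to `resolution` (default 1 ms); the result is
#' identical to an exhaustive scan at that resolution because propagation
#' success is monotone in the interval.
#'
#' For the pacemaking node the conditioning beat is the strand's own
#' spontaneous activation (S1 stimulation is skipped) and coupling is
#' measured from that beat.
#'
#' @param g Strand geometry from [make_strand()].
#' @param config For the reaction-diffusion engine: a [default_config()].
#' @param engine `"fhn"` or `"ca"`.
#' @param ca_parameters [ca_params()] table when `engine = "ca"`.
#' @param resolution Scan resolution (ms).
#' @param ci_range Coupling intervals (ms) bracketing the refractory
#'   period.
#' @param far_layer Propagation success probe layer (default 40).
#' @return Refractory period in ms, with attribute `detail` (tibble of the
#'   intervals probed and outcomes).
#' @export
refractory_period <- function(g, config = default_config(), engine = "fhn",
                              ca_parameters = NULL, resolution = 1,
                              ci_range = c(20, 400), far_layer = 40) {
  trial <- s1s2_trial_fn(g, config, engine, ca_parameters, far_layer)
  if (!trial(ci_range[2]))
    abort("S2 fails even at the longest coupling interval tested",
          class = "nodalsim_protocol_error")
  lo <- ci_range[1]; hi <- ci_range[2]
  if (trial(lo)) return(structure(lo, detail = "propagates at lower bound"))
  tried <- list()
  while (hi - lo > resolution) {
    mid <- lo + floor((hi - lo) / 2 / resolution) * resolution
    if (mid <= lo) mid <- lo + resolution
    ok <- trial(mid)
    tried[[length(tried) + 1]] <- tibble(ci = mid, propagated = ok)
    if (ok) hi <- mid else lo <- mid
  }
  structure(hi, detail = dplyr::bind_rows(tried))
}

# returns function(ci) -> TRUE if S2 at coupling interval ci propagates to
# the far probe
s1s2_trial_fn <- function(g, config, engine, ca_parameters, far_layer) {
  stim_region <- region_layers(g, g$meta$stim_layers %||% 1:3)
  far_probe <- paste0("layer_", far_layer)
  if (engine == "ca") {
    dt <- 0.1
    pars <- ca_parameters %||% ca_params(dt)
    function(ci) {
      s1_at <- 5
      s <- simulate_ca(g, duration = s1_at + ci + 120, params = pars, dt = dt,
                       stimuli = list(ca_stimulus(stim_region, s1_at),
                                      ca_stimulus(stim_region, s1_at + ci)),
                       probes = far_probe)
      ev <- s$events[[far_probe]]
      any(ev > s1_at + ci)
    }
  } else {
    kinetics <- g$meta$tissue %||% "atrial"
    pacemaking <- identical(tissue_codes()$kinetics[
      match(code_for(kinetics), tissue_codes()$code)], "san")
    if (pacemaking) {
      # the conditioning beat is the strand's own (near-synchronous)
      # spontaneous activation; S2 is coupled to it.  Success is a
      # propagated premature wave at a mid-distal probe arriving within its
      # transit time and clearly before the next spontaneous cycle.
      base <- simulate_fhn(g, duration = 900, config = config,
                           probes = "mid", record_dt = 0.5)
      s1_ev <- base$events[["mid"]]
      if (length(s1_ev) < 3)
        abort("no spontaneous nodal activation", class = "nodalsim_protocol_error")
      t_beat <- s1_ev[2]     # steady beat, past the startup transient
      cyc <- s1_ev[3] - s1_ev[2]
      det_probe <- "layer_30"
      function(ci) {
        s <- simulate_fhn(g, duration = t_beat + ci + 60, config = config,
                          stimuli = list(
                            stimulus(stim_region, at = t_beat + ci,
                                     duration = 1)),
                          probes = det_probe, record_dt = 2)
        ev <- s$events[[det_probe]]
        any(ev > t_beat + ci + 1 & ev < t_beat + ci + 55 &
              ev < t_beat + cyc - 12)
      }
    } else {
      function(ci) {
        s1_at <- 2
        s <- simulate_fhn(g, duration = s1_at + ci + 160, config = config,
                          stimuli = list(
                            stimulus(stim_region, at = s1_at, duration = 1),
                            stimulus(stim_region, at = s1_at + ci, duration = 1)),
                          probes = far_probe, record_dt = 2)
        ev <- s$events[[far_probe]]
        if (length(ev) == 0)
          abort("S1 failed to propagate", class = "nodalsim_protocol_error")
        # the first far-probe event is the S1 passage; success requires a
        # distinct later activation after the premature stimulus
        any(ev > ev[1] + 1 & ev > s1_at + ci)
      }
    }
  }
}

#' Full strand characterization of one tissue class
#'
#' Builds the 50 x 5 x 5 strand, stimulates the first three element layers
#' and reports the four published measurements: conduction velocity (layers
#' 10 to 40), APD90 and maximum upstroke at mid-strand, and the S1-S2
#' refractory period.  For the pacemaking node the strand's spontaneous
#' beat conditions the measurement (see [refractory_period()]) and the
#' spontaneous cycle length is reported as well.
#'
#' @param tissue `"san"`, `"atrial"`, `"ine"` or `"pb"`.
#' @param config A [default_config()].
#' @param rp Also run the S1-S2 refractory scan (slower).
#' @return One-row tibble: `tissue`, `cv_m_s`, `apd90_ms`,
#'   `upstroke_per_ms`, `rp_ms` (and `cycle_ms` for the node).
#' @export
#' @examples
#' \donttest{strand_measurements("atrial", rp = FALSE)}
strand_measurements <- function(tissue, config = default_config(), rp = TRUE) {
  g <- make_strand(tissue = tissue)
  stim <- region_layers(g, 1:3)
  pacemaking <- identical(tissue, "san")

  if (!pacemaking) {
    s <- simulate_fhn(g, duration = 220, config = config,
                      stimuli = list(stimulus(stim, at = 2, duration = 1)),
                      probes = c(paste0("layer_", c(10, 40)), "mid"),
                      record_dt = 0.05)
    cv <- conduction_velocity(s, 10, 40)
    tr <- probe_trace(s, "mid")
    apd <- apd90(tr, threshold = config$threshold)
    ups <- max_upstroke(tr)$du_dt
    cyc <- NA_real_
  } else {
    # Free-running node strand.  The strand beats spontaneously and almost
    # synchronously (a phase wave, not true conduction), so: cycle length,
    # APD90 and upstroke come from a steady spontaneous beat at mid-strand,
    # while conduction velocity and the refractory period come from a
    # premature (S1-S2) wave -- the only genuinely propagating wave a
    # pacemaking strand supports.  CV is read at the shortest fully
    # propagating coupling interval (the refractory period itself), layers
    # 10 to 40, from per-layer probe events.
    s <- simulate_fhn(g, duration = 1300, config = config, probes = "mid",
                      record_dt = 0.05)
    beats <- s$events[["mid"]]
    if (length(beats) < 4)
      abort("node strand failed to beat", class = "nodalsim_protocol_error")
    cyc <- cycle_length(beats)
    tr <- probe_trace(s, "mid")
    win <- c(beats[3] - 30, min(beats[3] + cyc - 20, max(tr$time)))
    apd <- apd90(tr, threshold = config$threshold, window = win)
    ups <- max_upstroke(tr, window = c(beats[3] - 10, beats[3] + 30))$du_dt
    rp_scan <- refractory_period(g, config = config, ci_range = c(150, 315))
    cv <- san_premature_cv(g, config, ci = as.numeric(rp_scan) + 2)
    rp_ms <- if (rp) as.numeric(rp_scan) else NA_real_
    return(tibble(tissue = tissue, cv_m_s = cv, apd90_ms = apd,
                  upstroke_per_ms = ups, rp_ms = rp_ms, cycle_ms = cyc))
  }
  rp_ms <- if (rp) {
    as.numeric(refractory_period(g, config = config, ci_range = c(10, 380)))
  } else NA_real_
  tibble(tissue = tissue, cv_m_s = cv, apd90_ms = apd,
         upstroke_per_ms = ups, rp_ms = rp_ms, cycle_ms = NA_real_)
}

# conduction velocity of a premature wave on the pacemaking strand at
# coupling interval ci after a steady spontaneous beat
san_premature_cv <- function(g, config, ci) {
  stim <- region_layers(g, g$meta$stim_layers %||% 1:3)
  base <- simulate_fhn(g, duration = 800, config = config, probes = "mid",
                       record_dt = 0.5)
  beats <- base$events[["mid"]]
  t_beat <- beats[2]
  s <- simulate_fhn(g, duration = t_beat + ci + 80, config = config,
                    stimuli = list(stimulus(stim, at = t_beat + ci,
                                            duration = 1)),
                    probes = c("layer_10", "layer_40"))
  inwin <- function(e) e[e > t_beat + ci & e < t_beat + ci + 75]
  a10 <- inwin(s$events[["layer_10"]])
  a40 <- inwin(s$events[["layer_40"]])
  if (length(a10) == 0 || length(a40) == 0)
    abort("premature wave did not traverse layers 10-40",
          class = "nodalsim_propagation_failure")
  30 * g$dx / (a40[1] - a10[1])
}
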