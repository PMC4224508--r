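#' Sinus-rhythm scenario
#'
#' Free-running simulation of the idealized atrium with the
#' reaction-diffusion engine: no external stimulus, activation initiated by
#' the sinoatrial node itself (the node centre carries the diastolic seed,
#' so the leading pacemaker site is central and the periphery is entrained).
#' Returns the full `nodal_sim` with activation map and probe traces.
#'
#' @param g Geometry from [make_idealized_right_atrium()].
#' @param duration Simulated time (ms); default long enough for one beat to
#'   cover the sheet.
#' @param config A [default_config()].
#' @param probes Probe names (default all).
#' @param dt Override time step (ms).
#' @return A `nodal_sim`.
#' @export
run_sinus <- function(g, duration = 220, config = default_config(),
                      probes = NULL, dt = NULL) {
  if (!any(g$labels == 3L))
    abort("geometry contains no sinoatrial node",
          class = "nodalsim_protocol_error")
  init <- sinus_init(g, config)
  sim <- simulate_fhn(g, duration = duration, config = config, init = init,
                      probes = probes, dt = dt)
  if (sum(!is.na(sim$activation)) < 0.05 * sum(g$labels != 0L))
    abort("no spontaneous activation spread within the run",
          class = "nodalsim_protocol_error")
  sim
}

# diastolic seed in the central third of the node -> central leading
# pacemaker site
sinus_init <- function(g, config) {
  d <- dim(g$labels)
  u <- array(0, d); v <- array(0, d)
  san <- which(g$labels == 3L, arr.ind = TRUE)
  ctr <- colMeans(san)
  r2 <- (san[, 1] - ctr[1])^2 + (san[, 2] - ctr[2])^2 + (san[, 3] - ctr[3])^2
  core <- san[r2 <= stats::quantile(r2, 0.3), , drop = FALSE]
  u[core] <- config$san_init_u
  list(u = u, v = v)
}

#' Fibrillation-like scenario
#'
#' S1 is a sinus beat initiated by the node; the arrhythmia is then driven
#' from the caval region and the node-centre and atrionodal probe lines
#' record how the sinoatrial node and the atrioventricular pathway filter
#' the high atrial rate.
#'
#' Two induction modes:
#' \describe{
#'   \item{`"burst"` (default)}{after the premature beat, a rapid train of
#'   planar stimuli at the caval band (interval just above the atrial
#'   refractory period) sustains the fibrillation-like atrial rate.  On a
#'   desk-scale sheet with a single uniform atrial refractory period a
#'   lone premature wave cannot break and re-enter -- the recovery front
#'   it chases moves exactly at wave speed, so its two arms always
#'   annihilate after one lap around the orifice; the refractory
#'   dispersion of the full anatomy is what sustains true reentry.  The
#'   burst driver reproduces the same high-rate atrial input to the nodes
#'   without that dispersion (see the methods vignette).}
#'   \item{`"s2"`}{the single premature planar stimulus alone; whether
#'   reentry was induced is reported as an outcome, not an error.}
#' }
#'
#' The cellular-automaton engine is the default here: its wavelength
#' (refractory period times conduction velocity) fits the desk-scale
#' sheet, while the reaction-diffusion atrial wavelength (about 44 mm)
#' does not.
#'
#' @param g Geometry from [make_idealized_right_atrium()] (the enlarged
#'   variant, e.g. `make_idealized_right_atrium(300, 300, svc_radius =
#'   100)`, leaves room for the caval circuit).
#' @param s2_time Premature-stimulus onset (ms); default 150.
#' @param induce `"burst"` or `"s2"`.
#' @param burst_interval Pacing interval of the burst train (ms); default
#'   95, just above the atrial refractory period.
#' @param n_burst Number of burst beats after the premature one.
#' @param duration Total simulated time (ms).
#' @param engine `"ca"` or `"fhn"`.
#' @param config [default_config()] (reaction-diffusion engine).
#' @param ca_parameters [ca_params()] table (automaton engine).
#' @param dt Automaton step (ms) when `engine = "ca"`.
#' @return List: `sim` (`nodal_sim`), `reentry` (logical: self-sustained
#'   activity beyond the stimuli), `san_ratio` and `avn_ratio`
#'   (`conduction_ratio` over the driven window), `atrial_events`,
#'   `san_events`, `pb_events`, `window`.
#' @export
run_af <- function(g, s2_time = NULL, induce = c("burst", "s2"),
                   burst_interval = 95, n_burst = 7, duration = 1100,
                   engine = c("ca", "fhn"),
                   config = default_config(), ca_parameters = NULL,
                   dt = 0.1) {
  engine <- match.arg(engine)
  induce <- match.arg(induce)
  svc <- g$meta$svc
  d <- dim(g$labels)
  # planar stimulus across the caval region: a cranial band at the
  # latitude of the orifice shoulder (only recovered tissue fires)
  band_y <- min(round(svc$cy + svc$r * 0.55), d[2] - 2)
  planar <- array(FALSE, d)
  planar[, band_y:min(band_y + 3, d[2]), ] <- TRUE
  planar <- planar & g$labels != 0L

  probes <- intersect(c("san_centre", "line_1", "line_5", "crista", "septum",
                        "avn_4", "avn_11", "pb_distal", "svc_rim"),
                      g$probes$name)

  s2_time <- s2_time %||% 150
  drive_times <- if (induce == "burst")
    s2_time + burst_interval * (0:n_burst) else s2_time
  last_drive <- max(drive_times)

  if (engine == "ca") {
    pars <- ca_parameters %||% ca_params(dt)
    stims <- c(list(ca_stimulus(san_core_region(g), at = 5)),
               lapply(drive_times, function(t) ca_stimulus(planar, at = t)))
    sim <- simulate_ca(g, duration = duration, params = pars, dt = dt,
                       probes = probes, stimuli = stims)
  } else {
    init <- sinus_init(g, config)
    stims <- lapply(drive_times, function(t)
      stimulus(planar, at = t, duration = 1))
    sim <- simulate_fhn(g, duration = duration, config = config, init = init,
                        probes = probes, stimuli = stims)
  }
  # atrial reference rate is read on the caval rim, next to the driver;
  # distant sheet probes can undercount during fibrillation-like activity
  atrial_site <- if ("svc_rim" %in% probes) "svc_rim" else "crista"
  ev_at <- sim$events[[atrial_site]]
  ev_san <- sim$events[["san_centre"]]
  ev_pb <- sim$events[["pb_distal"]]
  win <- c(s2_time, last_drive + burst_interval)
  # self-sustained activity = atrial events well after the last stimulus
  reentry <- any(ev_at > last_drive + 150)
  list(sim = sim, reentry = reentry, s2_time = s2_time, window = win,
       san_ratio = conduction_ratio(ev_at, ev_san, window = win),
       avn_ratio = conduction_ratio(ev_at, ev_pb, window = win),
       atrial_events = ev_at, san_events = ev_san, pb_events = ev_pb)
}

san_core_region <- function(g) {
  d <- dim(g$labels)
  out <- array(FALSE, d)
  san <- which(g$labels == 3L, arr.ind = TRUE)
  ctr <- colMeans(san)
  r2 <- (san[, 1] - ctr[1])^2 + (san[, 2] - ctr[2])^2 + (san[, 3] - ctr[3])^2
  out[san[r2 <= stats::quantile(r2, 0.3), , drop = FALSE]] <- TRUE
  out
}

#' Ventricular echo-beat scenario on the dual-pathway ring
#'
#' Cellular-automaton S1-S2 protocol at the penetrating-bundle stub of
#' [make_dual_pathway_ring()].  S1 conducts retrogradely up both limbs;
#' a premature S2 in the echo window is blocked in the fast limb
#' (transitional zone, long refractory period), conducts retrogradely up
#' the slow limb (inferior nodal extension), crosses the atrial bar, and
#' reenters the recovered fast limb anterogradely back to the bundle: a
#' single echo activation.
#'
#' The published penetrating-bundle refractory period (154 ms) exceeds the
#' whole echo window, so the stimulus stub uses a shorter recovery (60 ms)
#' -- otherwise no premature beat could re-enter the node at all; the limbs
#' carry the published values (134 / 94 ms).
#'
#' @param g Ring geometry.
#' @param s1_s2_interval Coupling interval (ms).
#' @param s1_at S1 time (ms).
#' @param ca_parameters Base parameter table, [ca_params()].
#' @param dt Automaton step (ms).
#' @return List with `echo` (logical), `events` (tibble log of probe
#'   activations with limb and direction), `sim`.
#' @export
run_echo <- function(g, s1_s2_interval, s1_at = 10,
                     ca_parameters = NULL, dt = 0.1) {
  pars <- ca_parameters %||% ca_params(dt)
  # fast-recovering stimulus stub (see above)
  pars$R[pars$tissue == "pb"] <-
    round(60 / dt) - pars$E[pars$tissue == "pb"]
  stim <- array(FALSE, dim(g$labels))
  p <- g$probes[g$probes$name == "pb_distal", ]
  stim[p$x, p$y, p$z] <- TRUE
  s2_at <- s1_at + s1_s2_interval
  probes <- c("pb_distal", "junction", "tz_mid", "tz_top", "bar_mid",
              "ine_top", "ine_mid")
  sim <- simulate_ca(g, duration = s2_at + 260, params = pars, dt = dt,
                     probes = probes,
                     stimuli = list(ca_stimulus(stim, s1_at),
                                    ca_stimulus(stim, s2_at)))
  ev <- tidyr::unnest(
    tibble(site = names(sim$events),
           t = purrr::map(sim$events, identity)), "t")
  # direction per limb traversal: compare mid-limb vs limb-end times
  log <- dplyr::arrange(ev, .data$t)
  pb_ev <- sim$events[["pb_distal"]]
  # echo = a bundle activation after S2 that is not the S2 stimulus itself
  echo <- any(pb_ev > s2_at + 5 * dt)
  tz_after <- sim$events[["tz_mid"]][sim$events[["tz_mid"]] > s2_at]
  ine_after <- sim$events[["ine_mid"]][sim$events[["ine_mid"]] > s2_at]
  list(echo = echo, s2_at = s2_at,
       fast_path_blocked = length(tz_after) == 0 ||
         min(tz_after) > s2_at + 40,
       slow_path_conducted = length(ine_after) > 0 &&
         min(ine_after) < s2_at + 40,
       events = log, sim = sim)
}

#' Scan the echo window
#'
#' Runs [run_echo()] over a grid of S1-S2 coupling intervals and reports
#' for each whether a single reentrant echo occurred.
#'
#' @param g Ring geometry.
#' @param intervals Coupling intervals to test (ms).
#' @param ... Passed to [run_echo()].
#' @return Tibble `interval`, `echo`, `fast_path_blocked`,
#'   `slow_path_conducted`.
#' @export
echo_window <- function(g, intervals = seq(70, 160, by = 5), ...) {
  purrr::map_dfr(intervals, function(ci) {
    r <- run_echo(g, ci, ...)
    tibble(interval = ci, echo = r$echo,
           fast_path_blocked = r$fast_path_blocked,
           slow_path_conducted = r$slow_path_conducted)
  })
}
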