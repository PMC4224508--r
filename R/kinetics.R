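#' Point reaction kinetics: Rogers-type modified FitzHugh-Nagumo
#'
#' Reaction (non-diffusive) rates of the two-variable excitation/recovery
#' system used for every active tissue class:
#' \deqn{du/dt = c_1 u (u - \alpha)(1 - u) - c_2 u v}
#' \deqn{dv/dt = b (d u - v)}
#' With a positive threshold `alpha` the rest state (0, 0) is stable and the
#' cell is an ordinary excitable element (atrial muscle, inferior nodal
#' extension, penetrating bundle).  [reaction_san()] is the pacemaking
#' variant, built on the original (additive) recovery coupling
#' \deqn{du/dt = c_1 u (u - \alpha)(1 - u) - c_2 v}
#' with the threshold shifted negative: rest is destabilized and the cell
#' settles on a stable limit cycle (spontaneous sinoatrial depolarization,
#' with a finite diastolic depolarization rate because the trajectory
#' rebounds through a brief hyperpolarization instead of decaying to zero).
#'
#' @param u Excitation variable (normalized voltage), finite numeric.
#' @param v Recovery variable, finite numeric.
#' @param params A one-row data frame (or named list) with `c1`, `c2`, `b`,
#'   `d`, `alpha`, e.g. a row of [tissue_params()].
#' @return A tibble with columns `du_dt`, `dv_dt` (vectorized over `u`, `v`).
#' @export
#' @examples
#' p <- dplyr::filter(tissue_params(), tissue == "atrial")
#' reaction_rogers(0, 0, p)         # rest is an equilibrium
#' reaction_rogers(0.6, 0.05, p)    # regenerative upstroke
reaction_rogers <- function(u, v, params) {
  if (!all(is.finite(u)) || !all(is.finite(v)))
    abort("u and v must be finite", class = "nodalsim_state_error")
  p <- as.list(params)
  stopifnot(p$c1 > 0, p$b > 0, p$d > 0)
  tibble(
    du_dt = p$c1 * u * (u - p$alpha) * (1 - u) - p$c2 * u * v,
    dv_dt = p$b * (p$d * u - v)
  )
}

#' @rdname reaction_rogers
#' @export
reaction_san <- function(u, v, params) {
  p <- as.list(params)
  if (p$alpha >= 0 && (p$j %||% 0) <= 0)
    abort(paste("SAN kinetics require a destabilized rest state:",
                "alpha < 0 or pacemaker current j > 0"),
          class = "nodalsim_parameter_error")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    abort("u and v must be finite", class = "nodalsim_state_error")
  stopifnot(p$c1 > 0, p$b > 0, p$d > 0)
  j <- p$j %||% 0
  tibble(
    du_dt = p$c1 * u * (u - p$alpha) * (1 - u) - p$c2 * v + j,
    dv_dt = p$b * (p$d * u - v)
  )
}

#' Passive block-zone kinetics
#'
#' The conduction block zone is passive tissue: no regenerative term, only
#' linear decay toward rest scaled by the resistivity, \eqn{du/dt = -u/R_b}.
#' Coupled with diffusion this is sufficient to extinguish an incoming
#' action potential.
#'
#' @param u Excitation variable.
#' @param rb Resistivity (dimensionless, default 0.5).
#' @return `du_dt`, same length as `u`.
#' @export
#' @examples
#' reaction_passive(0.8)   # pure decay, always <= 0 for u >= 0
reaction_passive <- function(u, rb = 0.5) {
  if (!is.numeric(rb) || rb <= 0)
    abort("block-zone resistivity rb must be positive",
          class = "nodalsim_parameter_error")
  if (!all(is.finite(u)))
    abort("u must be finite", class = "nodalsim_state_error")
  -u / rb
}

#' SAN periphery blend
#'
#' The sinoatrial node border (default 4 elements, 0.24 mm) grades its
#' excitability toward the surrounding atrium.  A SAN element at lattice
#' distance `dis_sa` from the nearest atrial element gets
#' \deqn{c_{1P} = c_{1A} + (c_{1S} - c_{1A}) \min(dis_{SA}, w)/w}
#' with `w` the band width: linear in distance, continuous across the band,
#' equal to the SAN core value at and beyond the band edge and to the
#' atrial-side endpoint at distance zero.
#'
#' @param dis_sa Minimum lattice distance (elements) from a SAN element to
#'   the nearest atrial element; non-negative.
#' @param rule A list with `band_width`, `c1S`, `c1A_ref` (see
#'   [default_config()]`$periphery`).
#' @return Blended `c1P`, same length as `dis_sa`.
#' @export
#' @examples
#' rule <- list(band_width = 4, c1S = 1, c1A_ref = 12.7)
#' blend_periphery(0:5, rule)
blend_periphery <- function(dis_sa, rule) {
  if (any(dis_sa < 0))
    abort("dis_sa must be non-negative", class = "nodalsim_parameter_error")
  w <- rule$band_width
  stopifnot(w >= 1)
  frac <- pmin(dis_sa, w) / w
  rule$c1A_ref + (rule$c1S - rule$c1A_ref) * frac
}

#' Map normalized voltage to millivolts and back
#'
#' Affine display map: `u = 0` is the resting potential `Vr`, `u = 1` the
#' overshoot potential `Vos`.  The simulation itself runs entirely in
#' normalized units; the map affects no dynamics.
#'
#' @param u Normalized voltage.
#' @param vm Membrane potential in mV.
#' @param scale List with `Vr` and `Vos` (mV), `Vos > Vr`.
#' @return `u_to_vm()` returns mV; `vm_to_u()` returns normalized units.
#' @export
#' @examples
#' s <- list(Vr = -80, Vos = 20)
#' u_to_vm(c(0, 1), s)
#' vm_to_u(u_to_vm(0.37, s), s)
u_to_vm <- function(u, scale) {
  if (scale$Vos <= scale$Vr)
    abort("requires Vos > Vr", class = "nodalsim_parameter_error")
  scale$Vr + u * (scale$Vos - scale$Vr)
}

#' @rdname u_to_vm
#' @export
vm_to_u <- function(vm, scale) {
  if (scale$Vos <= scale$Vr)
    abort("requires Vos > Vr", class = "nodalsim_parameter_error")
  (vm - scale$Vr) / (scale$Vos - scale$Vr)
}
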