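#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation: per-probe activation events
#'
#' One row per probe with its first activation time and event count; use
#' `sim$events` for the full trains and [activation_map()] for the field.
#'
#' @param x A `nodal_sim`.
#' @param ... Unused.
#' @return Tibble `site`, `t_activation`, `n_events`.
#' @export
tidy.nodal_sim <- function(x, ...) {
  tibble(
    site = names(x$events),
    t_activation = purrr::map_dbl(x$events, ~ if (length(.x)) .x[1] else NA_real_),
    n_events = purrr::map_int(x$events, length)
  )
}

#' Glance at a simulation
#'
#' @param x A `nodal_sim`.
#' @param ... Unused.
#' @return One-row tibble: engine, lattice size, duration, dt, voxels
#'   activated.
#' @export
glance.nodal_sim <- function(x, ...) {
  d <- dim(x$geometry$labels)
  tibble(engine = x$engine, nx = d[1], ny = d[2], nz = d[3],
         dx_mm = x$geometry$dx, dt_ms = x$dt, duration_ms = x$duration,
         n_tissue = sum(x$geometry$labels != 0L),
         n_activated = sum(!is.na(x$activation)))
}

#' Plot probe traces
#'
#' Action-potential traces of the recorded probe sites, stacked.
#'
#' @param object A `nodal_sim` (reaction-diffusion engine; the automaton
#'   records events, not traces).
#' @param sites Probe subset (default all recorded).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nodal_sim <- function(object, sites = NULL, ...) {
  tr <- object$traces
  if (nrow(tr) == 0)
    abort("no traces recorded (automaton runs store events only)",
          class = "nodalsim_parameter_error")
  if (!is.null(sites)) tr <- dplyr::filter(tr, .data$site %in% sites)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$u)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "time (ms)", y = "u (normalized)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot an activation map
#'
#' First-activation isochrone raster of a (single-slice) geometry.
#'
#' @param sim A `nodal_sim`.
#' @param slice z index to plot.
#' @return A ggplot.
#' @export
plot_activation <- function(sim, slice = 1) {
  m <- activation_map(sim)
  m <- dplyr::filter(m, .data$z == slice)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$t_activation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "activation (ms)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Export a field as legacy VTK structured points
#'
#' Writes the activation map (ms) or the final excitation field as an ASCII
#' VTK file loadable by standard visualization tools.
#'
#' @param sim A `nodal_sim`.
#' @param path Output `.vtk` path.
#' @param what `"activation"` or `"u"`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(sim, path, what = c("activation", "u")) {
  what <- match.arg(what)
  g <- sim$geometry
  d <- dim(g$labels)
  vals <- switch(what,
                 activation = as.vector(sim$activation),
                 u = as.vector(sim$state$u))
  vals[is.na(vals)] <- -1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("nodalsim %s field", what),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", g$dx, g$dx, g$dx),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", what),
               "LOOKUP_TABLE default"), con)
  writeLines(paste(format(vals, trim = TRUE, digits = 7), collapse = " "), con)
  invisible(path)
}
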