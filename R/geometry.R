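#' Tissue code table
#'
#' Integer coding of the voxel label volumes.  Codes 1-8 follow the published
#' supplementary simulation-array coding (atrial wall, inferior nodal
#' extension, sinoatrial node, crista terminalis, roof bundle, main branch,
#' block zone, penetrating bundle).  Code 9 (transitional zone, the fast AVN
#' pathway) is a package extension used by the cellular-automaton scenarios.
#'
#' `kinetics` names the FitzHugh-Nagumo parameter class each code maps to
#' (the three anisotropic muscle bundles share atrial kinetics; the
#' transitional zone is treated as atrial tissue by the reaction-diffusion
#' engine and has its own cellular-automaton parameters).
#'
#' @return A tibble with columns `code`, `tissue`, `kinetics`, `anisotropic`.
#' @export
tissue_codes <- function() {
  tibble::tribble(
    ~code, ~tissue,                    ~kinetics, ~anisotropic,
    1L,    "atrial wall",              "atrial",  FALSE,
    2L,    "inferior nodal extension", "ine",     FALSE,
    3L,    "sinoatrial node",          "san",     TRUE,
    4L,    "crista terminalis",        "atrial",  TRUE,
    5L,    "roof bundle",              "atrial",  TRUE,
    6L,    "main branch",              "atrial",  TRUE,
    7L,    "block zone",               "passive", FALSE,
    8L,    "penetrating bundle",       "pb",      FALSE,
    9L,    "transitional zone",        "atrial",  FALSE
  )
}

new_geometry <- function(labels, dx, fibers = NULL, probes = NULL,
                         meta = list()) {
  stopifnot(length(dim(labels)) == 3, dx > 0)
  storage.mode(labels) <- "integer"
  g <- structure(list(
    labels = labels, dx = dx,
    codes = tissue_codes(),
    fibers = fibers,
    probes = probes %||% tibble(name = character(), x = integer(),
                                y = integer(), z = integer()),
    meta = meta
  ), class = "nodal_geometry")
  validate_geometry(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a geometry
#'
#' Checks that every non-zero label appears in the code table, that fiber
#' vectors are unit length wherever the label is anisotropic, and that probe
#' coordinates fall on tissue.  Invoked by every generator and by
#' [read_label_volume()].
#'
#' @param g A `nodal_geometry`.
#' @return `g`, invisibly usable; errors (class
#'   `nodalsim_validation_error`) describe offending codes.
#' @export
validate_geometry <- function(g) {
  labs <- unique(as.vector(g$labels))
  labs <- labs[labs != 0L]
  if (length(labs) == 0)
    abort("label volume contains no tissue voxels",
          class = "nodalsim_validation_error")
  bad <- setdiff(labs, g$codes$code)
  if (length(bad) > 0)
    abort(sprintf("unknown tissue codes in volume: %s",
                  paste(sort(bad), collapse = ", ")),
          class = "nodalsim_validation_error")
  if (!is.null(g$fibers)) {
    aniso <- g$labels %in% g$codes$code[g$codes$anisotropic]
    n2 <- g$fibers$l^2 + g$fibers$m^2 + g$fibers$n^2
    if (any(abs(n2[aniso] - 1) > 1e-8))
      abort("fiber vectors must be unit length on anisotropic tissue",
            class = "nodalsim_validation_error")
  } else if (any(g$labels %in% g$codes$code[g$codes$anisotropic])) {
    abort("geometry contains anisotropic tissue but no fiber field",
          class = "nodalsim_validation_error")
  }
  if (nrow(g$probes) > 0) {
    d <- dim(g$labels)
    ok <- g$probes$x >= 1 & g$probes$x <= d[1] &
      g$probes$y >= 1 & g$probes$y <= d[2] &
      g$probes$z >= 1 & g$probes$z <= d[3]
    if (!all(ok))
      abort("probe sites outside the lattice",
            class = "nodalsim_validation_error")
  }
  g
}

#' @export
print.nodal_geometry <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<nodal_geometry> %d x %d x %d voxels, dx = %g mm\n",
              d[1], d[2], d[3], x$dx))
  counts <- table(factor(as.vector(x$labels), levels = x$codes$code))
  present <- counts[counts > 0]
  for (cd in names(present)) {
    nm <- x$codes$tissue[x$codes$code == as.integer(cd)]
    cat(sprintf("  code %s (%s): %d voxels\n", cd, nm, present[[cd]]))
  }
  if (nrow(x$probes) > 0)
    cat(sprintf("  probes: %s\n", paste(head(x$probes$name, 8), collapse = ", ")),
        if (nrow(x$probes) > 8) sprintf("  ... %d total\n", nrow(x$probes)) else "")
  invisible(x)
}

#' Voxel counts per tissue code
#'
#' @param g A `nodal_geometry`.
#' @return Tibble with `code`, `tissue`, `n_voxels`.
#' @export
geometry_census <- function(g) {
  counts <- table(factor(as.vector(g$labels), levels = g$codes$code))
  dplyr::mutate(g$codes[, c("code", "tissue")],
                n_voxels = as.integer(counts))
}

code_for <- function(tissue) {
  map <- c(atrial = 1L, ine = 2L, san = 3L, pb = 8L, tz = 9L,
           crista = 4L, block = 7L)
  if (!tissue %in% names(map))
    abort(sprintf("unknown tissue '%s'", tissue),
          class = "nodalsim_parameter_error")
  map[[tissue]]
}

constant_fibers <- function(dims, f) {
  f <- f / sqrt(sum(f^2))
  list(l = array(f[1], dims), m = array(f[2], dims), n = array(f[3], dims))
}

#' Uniform strand geometry
#'
#' The 50 x 5 x 5 element strand used to characterize each tissue class.
#' The stimulus region is the first three element layers; probe sites sit on
#' the strand axis at every layer (named `layer_1` ... `layer_<n>`), with
#' conduction velocity conventionally read between layers 10 and 40
#' (1.8 mm apart at the 60 um lattice).  Strand tissue is modelled
#' isotropic: the tissue-level anisotropy ratio is applied in anatomical
#' geometries via the fiber field, not in the characterization strand.
#'
#' @param n_long Number of element layers along the strand (default 50).
#' @param n_cross Cross-section edge in elements (default 5).
#' @param tissue One of `"san"`, `"atrial"`, `"ine"`, `"pb"`.
#' @param dx Voxel edge in mm.
#' @return A `nodal_geometry` with `meta$stim_layers = 1:3`.
#' @export
#' @examples
#' g <- make_strand(tissue = "atrial")
#' geometry_census(g)
make_strand <- function(n_long = 50, n_cross = 5, tissue = "atrial",
                        dx = 0.06) {
  if (n_long < 3 || n_cross < 3)
    abort("strand dimensions must be at least 3 in each axis",
          class = "nodalsim_parameter_error")
  code <- code_for(tissue)
  labels <- array(code, c(n_long, n_cross, n_cross))
  mid <- ceiling(n_cross / 2)
  probes <- tibble(
    name = paste0("layer_", seq_len(n_long)),
    x = seq_len(n_long), y = mid, z = mid
  )
  probes <- dplyr::bind_rows(
    probes,
    tibble(name = "mid", x = ceiling(n_long / 2), y = mid, z = mid)
  )
  fibers <- if (code %in% tissue_codes()$code[tissue_codes()$anisotropic]) {
    # characterization strands are isotropic; mark fibers along the axis but
    # the strand helpers below build an isotropic tensor (see strand_tensor)
    constant_fibers(c(n_long, n_cross, n_cross), c(1, 0, 0))
  } else NULL
  new_geometry(labels, dx, fibers = fibers, probes = probes,
               meta = list(kind = "strand", tissue = tissue,
                           stim_layers = 1:3, isotropic = TRUE))
}

#' Single-cell geometry
#'
#' One isolated voxel of the given tissue (diffusion has no effect), with a
#' probe named `"cell"`: the cheapest way to study point kinetics with the
#' full engine (spontaneous cycle length, single-cell APD, limit-cycle
#' convergence).
#'
#' @param tissue Tissue class.
#' @param dx Voxel edge in mm.
#' @return A `nodal_geometry` of dimensions 1 x 1 x 1.
#' @export
make_single_cell <- function(tissue = "san", dx = 0.06) {
  labels <- array(code_for(tissue), c(1, 1, 1))
  new_geometry(labels, dx,
               fibers = if (code_for(tissue) %in%
                            tissue_codes()$code[tissue_codes()$anisotropic])
                 constant_fibers(c(1, 1, 1), c(1, 0, 0)),
               probes = tibble(name = "cell", x = 1L, y = 1L, z = 1L),
               meta = list(kind = "cell", tissue = tissue, isotropic = TRUE,
                           stim_layers = 1L))
}

#' Uniform anisotropic slab
#'
#' A single-tissue slab with a constant fiber field, used to verify that the
#' conduction-velocity anisotropy follows the square root of the diffusion
#' anisotropy ratio (ratio 10 yields a conduction-velocity ratio of about
#' 3.2).
#'
#' @param dims Length-3 integer vector of voxel dimensions.
#' @param tissue Tissue class; must be one of the anisotropic codes.  The
#'   default, `"crista"` (crista terminalis), is the canonical anisotropic
#'   muscle bundle and -- unlike the self-depolarizing node -- supports a
#'   clean conducted test wave.
#' @param fiber_axis `"x"`, `"y"`, `"z"` or a length-3 vector (normalized).
#' @param dx Voxel edge in mm.
#' @return A `nodal_geometry`.
#' @export
make_anisotropic_slab <- function(dims = c(60, 21, 3), tissue = "crista",
                                  fiber_axis = "x", dx = 0.06) {
  f <- if (is.character(fiber_axis)) {
    switch(fiber_axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           abort("fiber_axis must be x, y, z or a unit vector",
                 class = "nodalsim_parameter_error"))
  } else as.numeric(fiber_axis)
  code <- code_for(tissue)
  codes <- tissue_codes()
  if (!codes$anisotropic[codes$code == code])
    abort(sprintf("'%s' is not an anisotropic tissue class", tissue),
          class = "nodalsim_parameter_error")
  labels <- array(code, dims)
  mid <- ceiling(dims / 2)
  probes <- dplyr::bind_rows(
    tibble(name = paste0("x_", seq_len(dims[1])),
           x = seq_len(dims[1]), y = mid[2], z = mid[3]),
    tibble(name = paste0("y_", seq_len(dims[2])),
           x = mid[1], y = seq_len(dims[2]), z = mid[3])
  )
  new_geometry(labels, dx, fibers = constant_fibers(dims, f), probes = probes,
               meta = list(kind = "slab", tissue = tissue, fiber = f,
                           stim_layers = 1:3))
}

# Manhattan distance (in elements) from every voxel to the nearest voxel of
# `target_mask`, capped at `max_dist`; plain iterative dilation.
lattice_distance <- function(target_mask, max_dist) {
  d <- dim(target_mask)
  dist <- array(Inf, d)
  dist[target_mask] <- 0
  shift_min <- function(a, ax, by) {
    out <- array(Inf, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq(1 + by, d[ax]); idx_src[[ax]] <- seq(1, d[ax] - by) }
    else { idx_dst[[ax]] <- seq(1, d[ax] + by); idx_src[[ax]] <- seq(1 - by, d[ax]) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (i in seq_len(max_dist)) {
    nb <- dist
    for (ax in 1:3) {
      if (d[ax] > 1) {
        nb <- pmin(nb, shift_min(dist, ax, 1) + 1, shift_min(dist, ax, -1) + 1)
      }
    }
    if (all(nb[is.finite(nb)] == dist[is.finite(nb)], na.rm = TRUE) &&
        identical(is.finite(nb), is.finite(dist))) break
    dist <- nb
  }
  dist
}

#' Idealized two-dimensional right atrium
#'
#' A synthetic desk-scale sheet that preserves the topology of the real
#' chamber: a caval orifice (hole), the sinoatrial node (with its graded
#' periphery band) lying against the crista terminalis, a passive block zone
#' interposed between the node and the septal side, fast atrial wall, and an
#' atrioventricular chain -- inferior nodal extension (slow pathway),
#' transitional zone (fast pathway, reached from the septal side) and
#' penetrating bundle, joined at a compact-node junction that the atrium can
#' only reach through one of the two pathways.
#'
#' Probe lines: `line_1` ... `line_19` run perpendicular to the crista
#' through the node (atrial muscle at site 1, node centre at site 15, block
#' zone then septum beyond), and `avn_1` ... `avn_21` run along the
#' atrionodal axis (atrium, then inferior nodal extension, then penetrating
#' bundle).  Named landmarks: `san_centre`, `crista`, `septum`,
#' `fast_entry`, `slow_entry`, `junction`, `pb_distal`.
#'
#' The default sheet is about 9 mm across, enough for sinus-rhythm
#' scenarios.  Fibrillation-like reentry needs the reentrant path around the
#' caval orifice to exceed the tissue wavelength (refractory period times
#' conduction velocity); `make_idealized_right_atrium(260, 260,
#' svc_radius = 70)` provides that variant.
#'
#' @param nx,ny Sheet dimensions in voxels (minimum 120).
#' @param svc_radius Radius (voxels) of the caval orifice; default scales
#'   with the sheet.
#' @param dx Voxel edge in mm.
#' @return A `nodal_geometry` (single-voxel-thick in z).
#' @export
make_idealized_right_atrium <- function(nx = 150, ny = 150,
                                        svc_radius = NULL, dx = 0.06) {
  if (nx < 120 || ny < 120)
    abort("idealized atrium needs at least 120 x 120 voxels",
          class = "nodalsim_parameter_error")
  svc_radius <- svc_radius %||% round(0.12 * min(nx, ny))
  lab <- matrix(1L, nx, ny)   # atrial wall everywhere, carve the rest

  ix <- matrix(seq_len(nx), nx, ny)
  iy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)

  # caval orifice (hole)
  cx <- round(0.50 * nx); cy <- min(round(0.62 * ny), ny - svc_radius - 4)
  hole <- (ix - cx)^2 + (iy - cy)^2 <= svc_radius^2
  lab[hole] <- 0L
  # intercaval line of block: a thin passive spoke from the cranial pole of
  # the orifice into the roof -- the fixed discontinuity premature caval
  # waves pivot around (see run_af)
  # the line leaves a narrow conducting isthmus under the roof: the pivot
  # channel reentrant caval waves turn through
  spoke <- abs(ix - cx) <= 1 &
    iy >= cy + svc_radius - 2 & iy <= ny - 9 & !hole
  lab[spoke] <- 7L

  # sinoatrial node: ellipse right of the orifice, long axis vertical
  san_cx <- min(cx + svc_radius + 14, nx - 30)
  san_cy <- cy
  sa <- max(7, round(0.05 * nx)); sb <- max(16, round(0.11 * ny))
  san <- ((ix - san_cx) / sa)^2 + ((iy - san_cy) / sb)^2 <= 1 & !hole
  lab[san] <- 3L
  # insulating collar: connective tissue (excluded from the domain) wraps
  # the node except a crista-facing exit window, so the weak nodal source
  # drives the atrial sink only through a limited contact area -- without
  # it the 2D sheet's diffusive load pins the node below threshold after
  # its first beat
  collar <- ((ix - san_cx) / (sa + 3))^2 + ((iy - san_cy) / (sb + 3))^2 <= 1 &
    !san & !hole
  window <- ix > san_cx & abs(iy - san_cy) <= ceiling(sb / 2)
  lab[collar & !window & lab == 1L] <- 0L

  # crista terminalis: vertical strip right of the node, fibers along y
  ct_lo <- min(san_cx + sa + 2, nx - 10); ct_hi <- min(ct_lo + 7, nx - 4)
  ct <- ix >= ct_lo & ix <= ct_hi &
    iy >= round(0.10 * ny) & iy <= round(0.92 * ny) & !hole
  lab[ct & lab != 3L] <- 4L

  # block zone: from the left edge of the node toward the septum, taller
  # than the node, so the straight node->septum path crosses only passive
  # tissue and excitation must detour around it
  sep_x <- max(4, round(0.08 * nx))
  bz <- ix >= sep_x & ix <= san_cx - sa - 1 &
    abs(iy - san_cy) <= sb + 10 & !hole
  lab[bz & lab == 1L] <- 7L

  # atrioventricular chain at the caudal border --------------------------
  jx <- round(0.34 * nx); jy <- 12          # compact-node junction
  # inferior nodal extension: horizontal slow-pathway strip from below the
  # crista leftward into the junction
  ine <- iy >= jy - 1 & iy <= jy + 1 & ix >= jx & ix <= ct_hi
  lab[ine & !hole] <- 2L
  # transitional zone: short fast-pathway strip dropping from the septal
  # atrium onto the junction
  tz <- ix >= jx - 1 & ix <= jx + 1 & iy >= jy + 2 & iy <= jy + 14
  lab[tz & !hole] <- 9L
  # penetrating bundle: continues leftward from the junction, insulated
  # from the atrium except at the junction
  pb <- iy >= jy - 1 & iy <= jy + 1 & ix >= max(3, jx - 26) & ix < jx
  lab[pb & !hole] <- 8L
  lab[(jx - 1):(jx + 1), (jy - 1):(jy + 1)] <- 8L  # junction itself
  # insulating sheath around the bundle (label 0), junction column open
  sheath_x <- max(2, jx - 27):(jx - 2)
  lab[sheath_x, jy + 2] <- 0L
  lab[sheath_x, jy - 2] <- 0L
  lab[max(2, jx - 27), (jy - 1):(jy + 1)] <- 0L
  # keep the caudal strip below the chain out of the domain so the bundle
  # end is a true dead end
  lab[, seq_len(max(1, jy - 3))] <- 0L

  labels <- array(lab, c(nx, ny, 1))

  # fibers: along y on node + crista (the only anisotropic codes present)
  fib <- constant_fibers(c(nx, ny, 1), c(0, 1, 0))

  # probe lines ----------------------------------------------------------
  # sites 1..15: atrial muscle right of the crista, across the crista and
  # node periphery, to the node centre (site 15); sites 16..17 block zone
  # (electrotonic only), 18..19 septum beyond it
  line_x <- c(round(seq(min(ct_hi + 6, nx - 2), san_cx, length.out = 15)),
              round(seq(san_cx - sa - 2, sep_x + 1, length.out = 2)),
              round(seq(sep_x - 2, max(3, sep_x - 8), length.out = 2)))
  line <- tibble(name = paste0("line_", 1:19), x = line_x, y = san_cy, z = 1)
  avn_x <- round(seq(ct_hi, max(3, jx - 24), length.out = 21))
  avn <- tibble(name = paste0("avn_", 1:21), x = avn_x, y = jy, z = 1)
  marks <- tibble(
    name = c("san_centre", "crista", "septum", "fast_entry", "slow_entry",
             "junction", "pb_distal", "svc_rim"),
    x = c(san_cx, ct_lo + 3, max(3, sep_x - 4), jx, min(ct_hi, nx - 4),
          jx, max(3, jx - 24), cx + 8),
    y = c(san_cy, san_cy, san_cy, jy + 13, jy, jy, jy,
          min(cy + svc_radius + 3, ny - 1)),
    z = 1
  )
  probes <- dplyr::bind_rows(marks, line, avn)
  # nudge probes off holes / sheath if construction left them on label 0
  flat <- function(x, y) x + nx * (y - 1)
  for (i in seq_len(nrow(probes))) {
    if (lab[probes$x[i], probes$y[i]] == 0L) {
      for (s in 1:6) {
        cand <- c(flat(probes$x[i] + s, probes$y[i]),
                  flat(probes$x[i] - s, probes$y[i]),
                  flat(probes$x[i], probes$y[i] + s),
                  flat(probes$x[i], probes$y[i] - s))
        cand <- cand[cand >= 1 & cand <= length(lab)]
        hit <- cand[lab[cand] != 0L]
        if (length(hit) > 0) {
          probes$x[i] <- ((hit[1] - 1) %% nx) + 1
          probes$y[i] <- ((hit[1] - 1) %/% nx) + 1
          break
        }
      }
    }
  }

  new_geometry(labels, dx, fibers = fib, probes = probes,
               meta = list(kind = "atrium2d",
                           svc = list(cx = cx, cy = cy, r = svc_radius),
                           san = list(cx = san_cx, cy = san_cy, a = sa, b = sb),
                           junction = c(jx, jy), septum_x = sep_x,
                           crista_x = c(ct_lo, ct_hi)))
}

#' Dual-pathway ring for atrioventricular echo beats
#'
#' A ring formed by two limbs with distinct refractory properties -- the
#' fast pathway (transitional zone) and the slow pathway (inferior nodal
#' extension) -- joined caudally at a compact-node junction that continues
#' into a penetrating-bundle stub (the S1/S2 stimulus site) and cranially by
#' an atrial bar.  The slow limb is deliberately the longer path, so that a
#' premature beat blocked in the fast limb and conducted retrogradely up the
#' slow limb finds the fast limb recovered when it returns: the substrate
#' for a single reentrant echo.
#'
#' @param tz_len Fast-limb length in voxels (default 30).
#' @param bar_len Atrial bar length (default 60); the slow limb returns
#'   under the bar, so a longer bar lengthens the slow path.
#' @param pb_len Penetrating-bundle stub length (default 20).
#' @param dx Voxel edge in mm.
#' @return A `nodal_geometry` with probes `pb_distal`, `junction`,
#'   `tz_mid`, `ine_mid`, `bar_mid`, `tz_top`, `ine_top`.
#' @export
make_dual_pathway_ring <- function(tz_len = 30, bar_len = 60,
                                   pb_len = 20, dx = 0.06) {
  w <- 3L                      # limb width
  # layout: junction at left-bottom; TZ limb rises from the junction;
  # the atrial bar runs right from the TZ top; the INE limb descends from
  # the bar's right end, runs left along the bottom back to the junction.
  # The PB stub hangs below the junction.
  nx <- bar_len + 2 * w + 8
  ny <- tz_len + pb_len + 2 * w + 10
  lab <- matrix(0L, nx, ny)
  x0 <- 4L; y_j <- pb_len + 4L            # junction lower-left corner
  # junction block (penetrating bundle code)
  lab[x0:(x0 + w - 1), y_j:(y_j + w - 1)] <- 8L
  # PB stub downward
  lab[x0:(x0 + w - 1), (y_j - pb_len):(y_j - 1)] <- 8L
  # TZ limb upward
  tz_y <- (y_j + w):(y_j + w + tz_len - 1)
  lab[x0:(x0 + w - 1), tz_y] <- 9L
  # atrial bar rightward from the TZ top
  bar_y <- max(tz_y) + 1
  lab[x0:(x0 + bar_len + w - 1), bar_y:(bar_y + w - 1)] <- 1L
  # INE limb: down the right side, then left along the bottom to the junction
  xr <- x0 + bar_len + w - 1
  seg_down <- (y_j):(bar_y - 1)
  lab[(xr - w + 1):xr, seg_down] <- 2L
  lab[(x0 + w):(xr - w), y_j:(y_j + w - 1)] <- 2L
  labels <- array(lab, c(nx, ny, 1))

  mx <- x0 + 1L
  probes <- tibble(
    name = c("pb_distal", "junction", "tz_mid", "tz_top", "bar_mid",
             "ine_top", "ine_mid"),
    x = c(mx, mx, mx, mx, x0 + round(bar_len / 2), xr - 1L,
          x0 + round((bar_len + w) / 2)),
    y = c(y_j - pb_len, y_j + 1L, y_j + w + round(tz_len / 2), max(tz_y),
          bar_y + 1L, bar_y - 2L, y_j + 1L),
    z = 1L
  )
  new_geometry(labels, dx, probes = probes,
               meta = list(kind = "ring", tz_len = tz_len,
                           bar_len = bar_len, pb_len = pb_len))
}

#' Write / read a label volume container
#'
#' Portable gzip-compressed JSON container holding dimensions, voxel
#' spacing, the code table, the flattened integer labels, optional fiber
#' direction cosines and probe sites.  Round-trips losslessly; the reader
#' re-validates codes and fiber norms and reports per-code voxel counts via
#' [geometry_census()].
#'
#' @param g A `nodal_geometry`.
#' @param path Output path (conventionally `.json.gz`).
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns a validated `nodal_geometry`.
#' @export
write_label_volume <- function(g, path) {
  validate_geometry(g)
  payload <- list(
    format = "nodalsim-label-volume", version = 1L,
    dims = dim(g$labels), dx = g$dx,
    codes = g$codes,
    labels = as.vector(g$labels),
    fibers = if (!is.null(g$fibers))
      list(l = as.vector(g$fibers$l), m = as.vector(g$fibers$m),
           n = as.vector(g$fibers$n)),
    probes = g$probes,
    meta = g$meta
  )
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, null = "null",
                              auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), class = "nodalsim_io_error")
  raw <- jsonlite::fromJSON(paste(readLines(gzfile(path)), collapse = "\n"))
  if (is.null(raw$format) || raw$format != "nodalsim-label-volume")
    abort("not a nodalsim label-volume container",
          class = "nodalsim_validation_error")
  dims <- as.integer(raw$dims)
  labels <- array(as.integer(raw$labels), dims)
  fibers <- if (!is.null(raw$fibers) && length(raw$fibers) > 0)
    list(l = array(raw$fibers$l, dims), m = array(raw$fibers$m, dims),
         n = array(raw$fibers$n, dims))
  probes <- if (!is.null(raw$probes) && length(raw$probes) > 0)
    tibble::as_tibble(raw$probes)
  meta <- raw$meta %||% list()
  # meta arrives as lists of scalars; keep as-is
  new_geometry(labels, as.numeric(raw$dx), fibers = fibers, probes = probes,
               meta = meta)
}

# flattened 0-based voxel index for the C++ engines
probe_flat_index <- function(g, names) {
  d <- dim(g$labels)
  i <- match(names, g$probes$name)
  if (anyNA(i))
    abort(sprintf("unknown probe(s): %s",
                  paste(names[is.na(i)], collapse = ", ")),
          class = "nodalsim_parameter_error")
  (g$probes$x[i] - 1L) + d[1] * (g$probes$y[i] - 1L) +
    d[1] * d[2] * (g$probes$z[i] - 1L)
}
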