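#' Fiber-based anisotropic diffusion tensor
#'
#' Builds the symmetric 3x3 diffusion tensor for a voxel with unit fiber
#' direction `f`: diffusion `D_l` along the fiber and `D_t` across it,
#' \deqn{D = D_t I_3 + (D_l - D_t) f f^T.}
#' `f` is the eigenvector at eigenvalue `D_l`; the orthogonal plane carries
#' `D_t`.
#'
#' @param f Length-3 fiber direction (must be unit length to 1e-6).
#' @param D_l Longitudinal diffusion (same units as the isotropic D).
#' @param D_t Transverse diffusion, `0 < D_t <= D_l`.
#' @return A 3x3 numeric matrix.
#' @export
#' @examples
#' build_tensor(c(1, 0, 0), D_l = 2, D_t = 0.2)
build_tensor <- function(f, D_l, D_t) {
  f <- as.numeric(f)
  if (length(f) != 3 || abs(sqrt(sum(f^2)) - 1) > 1e-6)
    abort("fiber direction must be a unit 3-vector",
          class = "nodalsim_parameter_error")
  if (!(D_l >= D_t && D_t > 0))
    abort("requires D_l >= D_t > 0", class = "nodalsim_parameter_error")
  D_t * diag(3) + (D_l - D_t) * tcrossprod(f)
}

# Per-voxel tensor components (N x 6: xx yy zz xy xz yz) in lattice units
# (1/ms), i.e. already divided by dx^2.  Isotropic voxels get D*I; voxels of
# anisotropic tissue classes get the fiber tensor with the configured
# anisotropy ratio applied geometric-mean-preserving:
#   D_l = D * sqrt(ratio),  D_t = D / sqrt(ratio).
# Characterization strands set meta$isotropic and stay isotropic.
build_tensor_field <- function(g, config) {
  labs <- as.vector(g$labels)
  N <- length(labs)
  codes <- g$codes
  kin <- codes$kinetics[match(labs, codes$code)]
  aniso <- codes$anisotropic[match(labs, codes$code)] &
    !isTRUE(g$meta$isotropic)

  Dtab <- config$tissues$D[match(kin, config$tissues$tissue)]
  Dtab[kin %in% "passive"] <- config$block$D
  Dphys <- Dtab * config$diffusion_unit / config$dx^2  # 1/ms lattice rate

  out <- matrix(0, N, 6)
  iso <- !is.na(Dphys) & !(aniso %in% TRUE)
  out[iso, 1] <- out[iso, 2] <- out[iso, 3] <- Dphys[iso]

  ai <- which(aniso %in% TRUE & !is.na(Dphys))
  if (length(ai) > 0) {
    if (is.null(g$fibers))
      abort("anisotropic tissue requires a fiber field",
            class = "nodalsim_validation_error")
    r <- sqrt(config$anisotropy_ratio)
    Dl <- Dphys[ai] * r; Dt <- Dphys[ai] / r
    l <- as.vector(g$fibers$l)[ai]
    m <- as.vector(g$fibers$m)[ai]
    n <- as.vector(g$fibers$n)[ai]
    dd <- Dl - Dt
    out[ai, 1] <- Dt + dd * l * l
    out[ai, 2] <- Dt + dd * m * m
    out[ai, 3] <- Dt + dd * n * n
    out[ai, 4] <- dd * l * m
    out[ai, 5] <- dd * l * n
    out[ai, 6] <- dd * m * n
  }
  out[labs == 0L, ] <- 0
  out
}

# explicit-Euler stability bound for the assembled tensor field (ms)
stable_dt <- function(tensor_field) {
  rate <- 2 * max(rowSums(tensor_field[, 1:3, drop = FALSE]))
  if (rate <= 0) Inf else 1 / rate
}
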