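# Tumour phantom generation: lobulated ellipsoids with a Gaussian-random-field
# texture, standing in for delineated tumours on pretreatment chest CT.

#' Phantom specification
#'
#' Describes one synthetic tumour: an axis-aligned ellipsoid whose radial
#' surface is perturbed by a random low-order direction polynomial (smoothly
#' tunable lobulation) and whose interior intensity is a Gaussian random field
#' with a controllable correlation length, placed over a noisy background.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3, voxel size in mm.
#' @param semi_axes_mm ellipsoid semi-axes (mm) along x, y, z.
#' @param lobulation_amp surface perturbation amplitude as a fraction of the
#'   local radius (>= 0; values up to ~0.3 keep the mask star-shaped and
#'   therefore connected).
#' @param texture_corr_mm correlation length (Gaussian kernel sigma, mm) of
#'   the interior intensity field; 0 gives voxel-wise white noise.
#' @param intensity_mean,intensity_sd HU-like moments of the in-mask field.
#' @param background_mean,background_sd moments of the background noise.
#' @param seed RNG seed; identical specs give identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         semi_axes_mm = c(10, 10, 10),
                         lobulation_amp = 0,
                         texture_corr_mm = 2,
                         intensity_mean = 60, intensity_sd = 12,
                         background_mean = -50, background_sd = 15,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(semi_axes_mm) == 3L, all(semi_axes_mm > 0),
            lobulation_amp >= 0, texture_corr_mm >= 0,
            intensity_sd >= 0, background_sd >= 0)
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               semi_axes_mm = as.numeric(semi_axes_mm),
               lobulation_amp = lobulation_amp,
               texture_corr_mm = texture_corr_mm,
               intensity_mean = intensity_mean, intensity_sd = intensity_sd,
               background_mean = background_mean, background_sd = background_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  # containment: perturbed ellipsoid plus 2-voxel margin must fit in the grid
  need <- ceiling(2 * (semi_axes_mm * (1 + lobulation_amp) / spacing_mm + 2))
  if (any(need > grid_shape)) {
    stop(sprintf(
      "phantom does not fit: grid_shape must be at least (%s) voxels",
      paste(need, collapse = ", ")), call. = FALSE)
  }
  spec
}

# random direction polynomial of total degree <= 4 (equivalent in span to a
# spherical-harmonic expansion of degree <= 4), centred and scaled so that
# max |P| = 1 over the sphere
.lobulation_field <- function(dirs, coefs) {
  expo <- .lobulation_exponents()
  mono <- vapply(seq_len(nrow(expo)), function(r) {
    dirs[, 1]^expo[r, 1] * dirs[, 2]^expo[r, 2] * dirs[, 3]^expo[r, 3]
  }, numeric(nrow(dirs)))
  drop(mono %*% coefs)
}

.lobulation_exponents <- function() {
  ex <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
  ex <- ex[rowSums(ex) >= 1 & rowSums(ex) <= 4, , drop = FALSE]
  as.matrix(ex)
}

#' Generate a tumour phantom
#'
#' Builds the binary tumour mask (perturbed ellipsoid) and the intensity
#' volume (smoothed Gaussian random field inside the mask over a noisy
#' background) described by a [phantom_spec()].
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `volume` and `mask`, both 3D arrays with a
#'   `spacing` attribute; the mask is 0/1 integer-valued.
#' @examples
#' ph <- generate_phantom(phantom_spec(semi_axes_mm = c(10, 10, 10)))
#' sum(ph$mask)  # ~ (4/3) * pi * 10^3 voxels at 1 mm
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  withr::with_seed(spec$seed, {
    cx <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp[1]
    cy <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp[2]
    cz <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp[3]
    X <- array(cx, dm)
    Y <- array(rep(cy, each = dm[1]), dm)
    Z <- array(rep(cz, each = dm[1] * dm[2]), dm)

    # radial coordinate in ellipsoid units
    U <- sqrt((X / spec$semi_axes_mm[1])^2 +
              (Y / spec$semi_axes_mm[2])^2 +
              (Z / spec$semi_axes_mm[3])^2)

    if (spec$lobulation_amp > 0) {
      expo <- .lobulation_exponents()
      coefs <- rnorm(nrow(expo))
      # normalise the perturbation on a fixed direction sample
      th <- runif(2048, 0, 2 * pi); ph <- acos(runif(2048, -1, 1))
      sdir <- cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
      pref <- .lobulation_field(sdir, coefs)
      coefs <- coefs / max(abs(pref - mean(pref)))
      ctr <- mean(pref) / max(abs(pref - mean(pref)))

      R <- sqrt(X^2 + Y^2 + Z^2)
      R[R == 0] <- 1
      dirs <- cbind(as.vector(X / R), as.vector(Y / R), as.vector(Z / R))
      P <- .lobulation_field(dirs, coefs) - ctr
      P <- pmin(pmax(P, -1), 1)
      mask <- (as.vector(U) <= 1 + spec$lobulation_amp * P)
      mask <- array(as.integer(mask), dm)
    } else {
      mask <- array(as.integer(U <= 1), dm)
    }

    # interior texture: white noise smoothed by a Gaussian kernel
    noise <- array(rnorm(prod(dm)), dm)
    if (spec$texture_corr_mm > 0.01) {
      g <- noise
      for (ax in 0:2) {
        sig <- spec$texture_corr_mm / sp[ax + 1]
        rad <- max(1L, ceiling(3 * sig))
        ker <- exp(-((-rad):rad)^2 / (2 * sig^2))
        ker <- ker / sum(ker)
        g <- cpp_conv1d_axis(g, dm, ker, ax, rad)
      }
    } else {
      g <- noise
    }
    inm <- mask == 1L
    gv <- g[inm]
    s <- sd(gv)
    if (!is.finite(s) || s < 1e-12) {
      tex <- rep(spec$intensity_mean, sum(inm))
    } else {
      tex <- (gv - mean(gv)) / s * spec$intensity_sd + spec$intensity_mean
    }
    vol <- array(rnorm(prod(dm), spec$background_mean, spec$background_sd), dm)
    vol[inm] <- tex
  })
  list(volume = as_volume(vol, sp), mask = as_volume(mask, sp))
}
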