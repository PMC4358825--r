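#' Voxel grid geometry
#'
#' Defines the discrete image grid: integer dimensions and physical voxel
#' size. World coordinates are in mm; the centre of voxel \code{(i, j, k)}
#' (1-based R indices) sits at \code{(i - 0.5) * voxel_size_mm[1]} etc., so
#' the grid occupies \code{[0, dims * voxel_size_mm]} in each axis.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3, voxel edge
#'   lengths in mm. Default \code{c(1, 1, 2)}, the fluorine acquisition
#'   resolution the simulator emulates.
#' @return An object of class \code{voxel_grid}.
#' @examples
#' g <- voxel_grid(c(32, 32, 16))
#' voxel_volume_uL(g)  # 2 microlitres
#' @export
voxel_grid <- function(dims, voxel_size_mm = c(1, 1, 2)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three positive numbers")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid a \code{voxel_grid}.
#' @export
voxel_volume_uL <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  # 1 mm^3 == 1 uL
  prod(grid$voxel_size_mm)
}

#' @rdname voxel_grid
#' @export
grid_extent_mm <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$dims * grid$voxel_size_mm
}

# Per-axis world coordinates of voxel centres.
axis_centers_mm <- function(grid, axis) {
  (seq_len(grid$dims[axis]) - 0.5) * grid$voxel_size_mm[axis]
}

#' 3D magnitude image
#'
#' A nonnegative voxel array tied to a [voxel_grid()]. Magnitude-reconstructed
#' MR images are nonnegative by construction; the constructor enforces this.
#'
#' @param grid a \code{voxel_grid}.
#' @param values numeric array with \code{dim(values) == grid$dims}, all
#'   values >= 0.
#' @return An object of class \code{image3d} with elements \code{grid} and
#'   \code{values}.
#' @export
image3d <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$dims)))
    stop("'values' dimensions do not match the grid")
  if (any(!is.finite(values)) || any(values < 0))
    stop("magnitude image values must be finite and nonnegative")
  structure(list(grid = grid, values = values), class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat("image3d:", paste(x$grid$dims, collapse = " x "), "voxels,",
      paste(x$grid$voxel_size_mm, collapse = " x "), "mm; range [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Voxelize a sphere onto a grid
#'
#' A voxel belongs to the mask iff its centre lies within \code{radius_mm} of
#' \code{center_mm} (centre-inclusion; no partial volume). This keeps the
#' noise-free quantification oracle exact: every spin assigned to a
#' compartment lands in exactly one voxel of its mask.
#'
#' @param grid a [voxel_grid()].
#' @param center_mm sphere centre, mm (length 3).
#' @param radius_mm sphere radius, mm (> 0).
#' @return Logical array of \code{dim = grid$dims}. Errors if no voxel centre
#'   falls inside the sphere (geometry outside the grid or radius too small).
#' @export
voxelize_sphere <- function(grid, center_mm, radius_mm) {
  stopifnot(inherits(grid, "voxel_grid"), length(center_mm) == 3,
            is.finite(radius_mm), radius_mm > 0)
  dx2 <- (axis_centers_mm(grid, 1) - center_mm[1])^2
  dy2 <- (axis_centers_mm(grid, 2) - center_mm[2])^2
  dz2 <- (axis_centers_mm(grid, 3) - center_mm[3])^2
  mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_mm^2
  if (!any(mask))
    stop("sphere covers no voxel centre: check geometry against the grid")
  mask
}

#' Voxelize an axis-aligned cylinder (reference tube geometry)
#'
#' Centre-inclusion voxelization of a cylinder whose axis is parallel to a
#' grid axis (default z, the usual orientation of a reference tube lying
#' along the bore).
#'
#' @inheritParams voxelize_sphere
#' @param length_mm cylinder length along its axis, mm.
#' @param axis 1, 2 or 3: grid axis the cylinder is parallel to.
#' @return Logical array of \code{dim = grid$dims}; errors if empty.
#' @export
voxelize_cylinder <- function(grid, center_mm, radius_mm, length_mm,
                              axis = 3L) {
  stopifnot(inherits(grid, "voxel_grid"), length(center_mm) == 3,
            radius_mm > 0, length_mm > 0, axis %in% 1:3)
  radial <- setdiff(1:3, axis)
  d1 <- (axis_centers_mm(grid, radial[1]) - center_mm[radial[1]])^2
  d2 <- (axis_centers_mm(grid, radial[2]) - center_mm[radial[2]])^2
  da <- abs(axis_centers_mm(grid, axis) - center_mm[axis]) <= length_mm / 2
  r2 <- outer(d1, d2, "+") <= radius_mm^2
  mask <- array(FALSE, grid$dims)
  # place the radial disc at every axial slice inside the tube length
  perm <- order(c(radial, axis))
  mask3 <- outer(r2, da, "&")          # dims: radial1, radial2, axis
  mask <- aperm(mask3, perm)
  if (!any(mask))
    stop("cylinder covers no voxel centre: check geometry against the grid")
  mask
}

#' Cell pellet specification
#'
#' A spherical pellet of labeled cells with known cell number and per-cell
#' \eqn{^{19}}F loading (spins per cell, the generator-side Y). Total pellet
#' spins \code{n_cells * spins_per_cell} are distributed uniformly over the
#' pellet's voxels.
#'
#' @param center_mm,radius_mm sphere geometry, mm.
#' @param n_cells nonnegative integer number of labeled cells.
#' @param spins_per_cell positive number of \eqn{^{19}}F spins per cell.
#'   Measured loadings for perfluoropolyether-labeled MSC fall in roughly
#'   8.2e10 to 2.4e11 spins/cell.
#' @return Object of class \code{pellet_spec}.
#' @export
pellet_spec <- function(center_mm, radius_mm, n_cells, spins_per_cell) {
  stopifnot(length(center_mm) == 3, radius_mm > 0,
            is.finite(n_cells), n_cells >= 0,
            is.finite(spins_per_cell), spins_per_cell > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 n_cells = as.numeric(n_cells),
                 spins_per_cell = as.numeric(spins_per_cell)),
            class = "pellet_spec")
}

#' Reference tube specification
#'
#' A cylinder of known, homogeneous \eqn{^{19}}F spin concentration
#' \code{concentration_spins_per_uL} (C_ref) imaged alongside the sample.
#' Each tube voxel carries \code{C_ref * voxel_volume_uL} spins; this is the
#' external standard that converts image signal to absolute spins.
#'
#' @param center_mm,radius_mm,length_mm tube geometry, mm (axis-aligned,
#'   along z).
#' @param concentration_spins_per_uL positive spin concentration, spins/uL.
#'   Default 2.6e16.
#' @return Object of class \code{reference_tube_spec}.
#' @export
reference_tube_spec <- function(center_mm, radius_mm, length_mm,
                                concentration_spins_per_uL = 2.6e16) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, length_mm > 0,
            is.finite(concentration_spins_per_uL),
            concentration_spins_per_uL > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 length_mm = as.numeric(length_mm),
                 concentration_spins_per_uL =
                   as.numeric(concentration_spins_per_uL)),
            class = "reference_tube_spec")
}

#' Off-resonance compartment (isoflurane artifact stand-in)
#'
#' A spherical compartment of \eqn{^{19}}F spins resonating at a chemical-
#' shift offset from the label, standing in for isoflurane accumulated in
#' fat. Its signal is scaled by the excitation profile of the RF pulse at
#' that offset, so a narrow-bandwidth pulse suppresses it while a broad one
#' excites it.
#'
#' @param center_mm,radius_mm sphere geometry, mm.
#' @param offset_khz chemical-shift offset of the compartment, kHz.
#'   Default 1.2, chosen so a ~1.5 kHz pulse excludes it while a ~3 kHz
#'   pulse excites it.
#' @param spin_density_spins_per_uL positive spin density, spins/uL.
#' @return Object of class \code{off_resonance_compartment}.
#' @export
off_resonance_compartment <- function(center_mm, radius_mm,
                                      offset_khz = 1.2,
                                      spin_density_spins_per_uL = 1e15) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, is.finite(offset_khz),
            is.finite(spin_density_spins_per_uL),
            spin_density_spins_per_uL > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 offset_khz = as.numeric(offset_khz),
                 spin_density_spins_per_uL =
                   as.numeric(spin_density_spins_per_uL)),
            class = "off_resonance_compartment")
}

#' Phantom scene specification
#'
#' The ground-truth scene an image is generated from: one or more cell
#' pellets, optionally a reference tube and an off-resonance compartment,
#' on a common [voxel_grid()]. All compartments must fit inside the grid
#' and be pairwise disjoint after voxelization (checked at generation).
#'
#' @param grid a [voxel_grid()].
#' @param pellets a [pellet_spec()] or list of them.
#' @param reference a [reference_tube_spec()] or NULL.
#' @param off_resonance an [off_resonance_compartment()] or NULL.
#' @param body optional list \code{(center_mm, semiaxes_mm, intensity)}
#'   describing the proton-visible "tissue" ellipsoid; defaults to an
#'   ellipsoid filling 80% of the grid at unit intensity.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid, pellets, reference = NULL,
                         off_resonance = NULL, body = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (inherits(pellets, "pellet_spec")) pellets <- list(pellets)
  stopifnot(all(vapply(pellets, inherits, logical(1), "pellet_spec")))
  if (!is.null(reference))
    stopifnot(inherits(reference, "reference_tube_spec"))
  if (!is.null(off_resonance))
    stopifnot(inherits(off_resonance, "off_resonance_compartment"))
  if (is.null(body)) {
    ext <- grid_extent_mm(grid)
    body <- list(center_mm = ext / 2, semiaxes_mm = 0.4 * ext,
                 intensity = 1)
  }
  structure(list(grid = grid, pellets = pellets, reference = reference,
                 off_resonance = off_resonance, body = body),
            class = "phantom_spec")
}

#' RF excitation pulse model
#'
#' A time-domain pulse of full-width-at-half-maximum \code{time_fwhm_ms}
#' whose excitation bandwidth follows the time-bandwidth relation
#' \code{bandwidth_khz = 2 / time_fwhm_ms}. Two shapes are modelled:
#' \describe{
#'   \item{\code{plain_sinc}}{an unfiltered sinc, whose frequency response
#'     is close to a rectangle of full width \code{bandwidth_khz} with a
#'     smooth roll-off; off-resonance species beyond half the bandwidth are
#'     strongly suppressed.}
#'   \item{\code{filtered_sinc}}{a Gaussian-filtered sinc, shorter in time
#'     and hence broader in frequency; its response is modelled as a
#'     Gaussian with FWHM \code{bandwidth_khz}.}
#' }
#' With this relation a 1.32 ms plain sinc maps to ~1.5 kHz and a 0.66 ms
#' filtered sinc to ~3.0 kHz, the narrow/broad pair used for artifact
#' suppression versus excitation.
#'
#' @param shape \code{"plain_sinc"} or \code{"filtered_sinc"}.
#' @param time_fwhm_ms positive pulse width (FWHM) in ms.
#' @return Object of class \code{excitation_pulse} with derived field
#'   \code{bandwidth_khz}.
#' @examples
#' excitation_pulse("plain_sinc", 1.32)$bandwidth_khz   # ~1.52 kHz
#' excitation_pulse("filtered_sinc", 0.66)$bandwidth_khz # ~3.03 kHz
#' @export
excitation_pulse <- function(shape = c("plain_sinc", "filtered_sinc"),
                             time_fwhm_ms = 1.32) {
  shape <- match.arg(shape)
  stopifnot(is.finite(time_fwhm_ms), time_fwhm_ms > 0)
  structure(list(shape = shape,
                 time_fwhm_ms = as.numeric(time_fwhm_ms),
                 bandwidth_khz = 2 / as.numeric(time_fwhm_ms)),
            class = "excitation_pulse")
}

#' Excitation profile at a chemical-shift offset
#'
#' Normalized magnitude response of the pulse at a frequency offset: 1 at
#' resonance, falling to 0.5 at half the bandwidth. The plain sinc uses a
#' flat-top response \eqn{1 / (1 + (2 f / B)^{12})} (rectangular passband
#' with smooth roll-off), the filtered sinc a Gaussian
#' \eqn{\exp(-4 \ln 2 \, f^2 / B^2)} with FWHM equal to the bandwidth.
#'
#' @param pulse an [excitation_pulse()].
#' @param offset_khz numeric offset(s) in kHz.
#' @return Response in \code{[0, 1]}, vectorized over \code{offset_khz}.
#' @examples
#' narrow <- excitation_pulse("plain_sinc", 1.32)
#' broad <- excitation_pulse("filtered_sinc", 0.66)
#' excitation_response(narrow, 1.2)  # < 0.1: isoflurane suppressed
#' excitation_response(broad, 1.2)   # > 0.5: isoflurane excited
#' @export
excitation_response <- function(pulse, offset_khz) {
  stopifnot(inherits(pulse, "excitation_pulse"), all(is.finite(offset_khz)))
  B <- pulse$bandwidth_khz
  f <- abs(offset_khz)
  switch(pulse$shape,
         plain_sinc = 1 / (1 + (2 * f / B)^12),
         filtered_sinc = exp(-4 * log(2) * (f / B)^2))
}

#' Acquisition parameters
#'
#' Noise level, signal gain, RNG seed and the excitation pulse, plus
#' sequence metadata (TR, TE, flip angle, averages) that is recorded but
#' not simulated. \code{gain} is the image signal per \eqn{^{19}}F spin per
#' voxel and is identical for every compartment -- the assumption that makes
#' reference normalization valid. \code{noise_sd} is the per-channel SD of
#' the complex Gaussian noise before magnitude reconstruction (so signal-free
#' voxels are Rayleigh with mode \code{noise_sd}).
#'
#' @param noise_sd nonnegative per-channel noise SD, image units. The
#'   default 125 puts the smallest default pellet (2e5 cells) at an ROI SNR
#'   of about 10 under the default gain and geometry.
#' @param gain positive signal per spin per voxel. Default 1e-12.
#' @param seed integer RNG seed; identical \code{(spec, acq)} give
#'   bit-identical images.
#' @param pulse an [excitation_pulse()].
#' @param tr_ms,te_ms,flip_deg,averages recorded metadata only.
#' @return Object of class \code{acquisition_params}.
#' @export
acquisition_params <- function(noise_sd = 125, gain = 1e-12, seed = 1L,
                               pulse = excitation_pulse("plain_sinc", 1.32),
                               tr_ms = 3.5, te_ms = 1.8, flip_deg = 70,
                               averages = 250) {
  stopifnot(is.finite(noise_sd), is.finite(gain), gain > 0,
            inherits(pulse, "excitation_pulse"))
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  structure(list(noise_sd = as.numeric(noise_sd), gain = as.numeric(gain),
                 seed = as.integer(seed), pulse = pulse,
                 tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 averages = averages),
            class = "acquisition_params")
}

# Voxelize every compartment of a phantom; error on overlap or bad fit.
phantom_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- list()
  for (i in seq_along(spec$pellets)) {
    p <- spec$pellets[[i]]
    masks[[sprintf("pellet_%d", i)]] <-
      voxelize_sphere(spec$grid, p$center_mm, p$radius_mm)
  }
  if (!is.null(spec$reference))
    masks$reference <- voxelize_cylinder(spec$grid, spec$reference$center_mm,
                                         spec$reference$radius_mm,
                                         spec$reference$length_mm)
  if (!is.null(spec$off_resonance))
    masks$off_resonance <- voxelize_sphere(spec$grid,
                                           spec$off_resonance$center_mm,
                                           spec$off_resonance$radius_mm)
  if (length(masks) > 1) {
    total <- Reduce(`+`, masks)
    if (any(total > 1))
      stop("phantom compartments overlap after voxelization")
  }
  masks
}

# Magnitude of (signal + complex Gaussian noise), per-channel SD sigma.
rician_magnitude <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Generate a synthetic fluorine-19 magnitude image
#'
#' Builds the noiseless signal -- each compartment's total spins spread over
#' its voxels, scaled by \code{gain} and by the excitation response at the
#' compartment's chemical-shift offset (pellets and reference tube are
#' on-resonance) -- then applies Rician noise: the magnitude of the signal
#' plus complex Gaussian noise with per-channel SD \code{noise_sd}. At
#' \code{noise_sd = 0} the sum of pellet-voxel values equals
#' \code{gain * n_cells * spins_per_cell} exactly (spin conservation).
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acquisition_params()].
#' @return A list of class \code{phantom_image}: \code{image} (an
#'   [image3d()]), \code{masks} (named list of ground-truth logical masks:
#'   \code{pellet_1}, ..., \code{reference}, \code{off_resonance}),
#'   \code{spec} and \code{acq}.
#' @export
generate_fluorine_image <- function(spec, acq) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(acq, "acquisition_params"))
  masks <- phantom_masks(spec)
  signal <- array(0, spec$grid$dims)
  vol <- voxel_volume_uL(spec$grid)
  for (i in seq_along(spec$pellets)) {
    p <- spec$pellets[[i]]
    m <- masks[[sprintf("pellet_%d", i)]]
    total <- p$n_cells * p$spins_per_cell
    signal[m] <- signal[m] + acq$gain * total / sum(m)
  }
  if (!is.null(spec$reference)) {
    m <- masks$reference
    signal[m] <- signal[m] +
      acq$gain * spec$reference$concentration_spins_per_uL * vol
  }
  if (!is.null(spec$off_resonance)) {
    m <- masks$off_resonance
    resp <- excitation_response(acq$pulse, spec$off_resonance$offset_khz)
    signal[m] <- signal[m] +
      acq$gain * spec$off_resonance$spin_density_spins_per_uL * vol * resp
  }
  values <- withr::with_seed(acq$seed, {
    array(rician_magnitude(as.vector(signal), acq$noise_sd), spec$grid$dims)
  })
  structure(list(image = image3d(spec$grid, values), masks = masks,
                 spec = spec, acq = acq),
            class = "phantom_image")
}

#' Generate the companion proton (anatomical) image
#'
#' A uniform "tissue" intensity inside the phantom's body ellipsoid, zero
#' outside, with the same Rician noise model. Used only as an overlay
#' background; no proton physics is simulated.
#'
#' @inheritParams generate_fluorine_image
#' @return A \code{phantom_image} list with a single \code{body} mask.
#' @export
generate_proton_image <- function(spec, acq) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(acq, "acquisition_params"))
  b <- spec$body
  d1 <- ((axis_centers_mm(spec$grid, 1) - b$center_mm[1]) / b$semiaxes_mm[1])^2
  d2 <- ((axis_centers_mm(spec$grid, 2) - b$center_mm[2]) / b$semiaxes_mm[2])^2
  d3 <- ((axis_centers_mm(spec$grid, 3) - b$center_mm[3]) / b$semiaxes_mm[3])^2
  body <- outer(outer(d1, d2, "+"), d3, "+") <= 1
  if (!any(body)) stop("body ellipsoid covers no voxel centre")
  signal <- array(0, spec$grid$dims)
  signal[body] <- b$intensity
  values <- withr::with_seed(acq$seed, {
    array(rician_magnitude(as.vector(signal), acq$noise_sd), spec$grid$dims)
  })
  structure(list(image = image3d(spec$grid, values),
                 masks = list(body = body), spec = spec, acq = acq),
            class = "phantom_image")
}

#' Build the cell-pellet dilution series
#'
#' One phantom per cell count, all sharing the same pellet geometry,
#' reference tube and (optionally) off-resonance compartment -- the layout
#' of the in-vitro linearity experiment, where pellets of 2e5 to 2e6
#' labeled cells are imaged alongside a reference tube.
#'
#' @param cell_counts positive cell numbers, one phantom each. Default
#'   \code{c(2e5, 4e5, 6e5, 8e5, 1e6, 2e6)}.
#' @param spins_per_cell per-cell loading Y applied to every pellet.
#' @param grid a [voxel_grid()]; default 32 x 32 x 16 voxels of 1 x 1 x 2 mm.
#' @param pellet_center_mm,pellet_radius_mm shared pellet geometry.
#' @param reference a [reference_tube_spec()]; a default tube is placed away
#'   from the pellet if omitted.
#' @param off_resonance optional [off_resonance_compartment()] shared by all
#'   phantoms.
#' @return List of [phantom_spec()] objects, one per count, in order.
#' @export
build_pellet_series <- function(cell_counts = c(2e5, 4e5, 6e5, 8e5, 1e6, 2e6),
                                spins_per_cell = 1.5e11,
                                grid = voxel_grid(c(32, 32, 16)),
                                pellet_center_mm = c(10, 16, 16),
                                pellet_radius_mm = 2,
                                reference = NULL,
                                off_resonance = NULL) {
  stopifnot(length(cell_counts) >= 1, all(is.finite(cell_counts)),
            all(cell_counts > 0))
  if (is.null(reference))
    reference <- reference_tube_spec(center_mm = c(24, 16, 16),
                                     radius_mm = 1.5, length_mm = 24)
  lapply(cell_counts, function(n) {
    phantom_spec(grid,
                 pellet_spec(pellet_center_mm, pellet_radius_mm,
                             n_cells = n, spins_per_cell = spins_per_cell),
                 reference = reference, off_resonance = off_resonance)
  })
}

#' Sample a per-cell loading from the observed range
#'
#' Cellular \eqn{^{19}}F loading varies between experiments and cell types;
#' measured values span about 8.2e10 to 2.4e11 spins per cell. Each
#' simulated experiment draws one loading uniformly from that range, just as
#' each real transplant is paired with its own NMR-measured loading.
#'
#' @param n number of draws.
#' @param range length-2 numeric, spins/cell.
#' @return Numeric vector of loadings.
#' @export
sample_loading <- function(n = 1, range = c(8.2e10, 2.4e11)) {
  stopifnot(length(range) == 2, range[1] > 0, range[2] > range[1])
  runif(n, range[1], range[2])
}
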