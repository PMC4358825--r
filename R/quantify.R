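#' Background (constant) correction
#'
#' Subtracts the dataset-wide minimum voxel value x from every voxel, so the
#' corrected image's minimum is exactly 0. The minimum is taken over the
#' entire volume, reference tube included. On noise-floored magnitude data
#' the minimum is close to 0 and the correction is a small left-shift of
#' the intensity distribution; the operation is idempotent.
#'
#' @param img an [image3d()].
#' @return List with \code{image} (corrected [image3d()]) and
#'   \code{background_x} (the subtracted constant).
#' @examples
#' g <- voxel_grid(c(2, 2, 1), c(1, 1, 1))
#' background_correct(image3d(g, array(c(5, 7, 9, 6), c(2, 2, 1))))$background_x
#' @export
background_correct <- function(img) {
  stopifnot(inherits(img, "image3d"))
  x <- min(img$values)
  list(image = image3d(img$grid, img$values - x), background_x = x)
}

check_mask <- function(img, mask, what = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), dim(img$values)))
    stop(sprintf("'%s' must be a logical array on the image grid", what))
  if (!any(mask)) stop(sprintf("'%s' is empty", what))
  invisible(TRUE)
}

#' Summed signal within an ROI
#'
#' @param img a (background-corrected) [image3d()].
#' @param roi logical mask on the same grid, at least one voxel.
#' @return Sum of voxel values over the mask.
#' @export
roi_total_signal <- function(img, roi) {
  stopifnot(inherits(img, "image3d"))
  check_mask(img, roi, "roi")
  sum(img$values[roi])
}

#' Mean reference-tube signal per voxel
#'
#' @param img a (background-corrected) [image3d()].
#' @param ref logical mask over the reference tube.
#' @return Arithmetic mean of voxel values over the mask.
#' @export
reference_mean <- function(img, ref) {
  stopifnot(inherits(img, "image3d"))
  check_mask(img, ref, "ref")
  mean(img$values[ref])
}

#' Total spins in an ROI by reference normalization
#'
#' Expresses the ROI signal in reference-voxel equivalents and converts to
#' absolute spins: each reference voxel carries \code{c_ref *
#' voxel_volume_uL} spins, so
#' \deqn{X = \frac{\mathrm{ROI\ sum}}{\mathrm{ref\ mean}} \times C_{ref}
#'   \times V_{voxel}.}
#' Any global signal gain cancels in the ratio -- the property that makes
#' external-reference quantification gain-invariant.
#'
#' @param roi_sum summed corrected ROI signal (>= 0).
#' @param ref_mean mean corrected reference signal per voxel (> 0).
#' @param c_ref reference spin concentration, spins/uL (> 0). The
#'   quantification default is 2.6e16.
#' @param voxel_volume_uL voxel volume, uL (> 0); 2 uL at 1 x 1 x 2 mm.
#' @return Total \eqn{^{19}}F spins X in the ROI.
#' @export
estimate_total_spins <- function(roi_sum, ref_mean, c_ref = 2.6e16,
                                 voxel_volume_uL = 2) {
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("'ref_mean' must be positive: no reference signal")
  stopifnot(is.finite(roi_sum), c_ref > 0, voxel_volume_uL > 0)
  (roi_sum / ref_mean) * c_ref * voxel_volume_uL
}

#' Apparent cell number
#'
#' Divides the total ROI spins X by the per-cell loading Y. Reported as a
#' continuous (not rounded) nonnegative value: the quantity is an apparent
#' cell number, plotted on a continuous axis.
#'
#' @param total_spins X, total \eqn{^{19}}F spins in the ROI (>= 0).
#' @param spins_per_cell Y, spins per cell from NMR calibration (> 0).
#' @return X / Y.
#' @export
estimate_cell_number <- function(total_spins, spins_per_cell) {
  if (!is.finite(spins_per_cell) || spins_per_cell <= 0)
    stop("'spins_per_cell' must be positive")
  stopifnot(is.finite(total_spins), total_spins >= 0)
  total_spins / spins_per_cell
}

#' Estimate the noise level from a signal-free region
#'
#' In magnitude images, signal-free voxels are Rayleigh distributed with
#' scale equal to the per-channel Gaussian SD sigma; the maximum-likelihood
#' estimate is \code{sqrt(mean(v^2) / 2)}.
#'
#' @param img an [image3d()].
#' @param background logical mask over signal-free voxels.
#' @return Estimated per-channel noise SD.
#' @export
estimate_noise_sd <- function(img, background) {
  stopifnot(inherits(img, "image3d"))
  check_mask(img, background, "background")
  sqrt(mean(img$values[background]^2) / 2)
}

#' Detectability classification (Rose criterion)
#'
#' SNR is the mean corrected ROI signal divided by the noise SD, estimated
#' from a signal-free background mask unless given directly. An ROI is
#' called detectable when SNR >= \code{threshold} (default 5, the Rose
#' criterion; the boundary is inclusive). A zero noise estimate yields
#' \code{snr = Inf} for any positive ROI signal.
#'
#' @param img a (background-corrected) [image3d()].
#' @param roi logical ROI mask.
#' @param background logical mask of signal-free voxels (required unless
#'   \code{noise_sd_estimate} is given).
#' @param noise_sd_estimate optional known noise SD, bypassing estimation.
#' @param threshold SNR threshold, default 5.
#' @return List with \code{detectable} (logical) and \code{snr}.
#' @export
classify_detectable <- function(img, roi, background = NULL,
                                noise_sd_estimate = NULL, threshold = 5) {
  stopifnot(inherits(img, "image3d"))
  check_mask(img, roi, "roi")
  if (is.null(noise_sd_estimate)) {
    if (is.null(background)) stop("'background' mask required")
    noise_sd_estimate <- estimate_noise_sd(img, background)
  }
  stopifnot(is.finite(noise_sd_estimate), noise_sd_estimate >= 0)
  m <- mean(img$values[roi])
  snr <- if (noise_sd_estimate == 0) {
    if (m > 0) Inf else 0
  } else m / noise_sd_estimate
  list(detectable = snr >= threshold, snr = snr)
}

#' Automatic ROI from intensity threshold
#'
#' Convenience ROI for simulations (real ROIs are hand-drawn): voxels above
#' \code{k} times the background noise SD, restricted to the largest
#' 6-connected component. Exposed alongside the mask-file path so both
#' hand-drawn-equivalent and automatic ROIs can be used.
#'
#' @param img a background-corrected [image3d()].
#' @param noise_sd background noise SD (e.g. [estimate_noise_sd()]).
#' @param k threshold multiplier, default 3.
#' @param exclude optional logical mask to remove before labelling (e.g.
#'   the reference tube).
#' @return Logical ROI mask; errors if nothing exceeds the threshold.
#' @export
auto_roi <- function(img, noise_sd, k = 3, exclude = NULL) {
  stopifnot(inherits(img, "image3d"), is.finite(noise_sd), noise_sd >= 0)
  above <- img$values > k * noise_sd
  if (!is.null(exclude)) above <- above & !exclude
  if (!any(above)) stop("no voxel exceeds the threshold")
  lab <- label_components(above)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# 6-connected component labelling by iterative flood fill.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, d)
      for (o in seq_len(nrow(offsets))) {
        nb <- ai + offsets[o, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' Full image-side quantification chain
#'
#' Runs background correction, ROI summation, reference normalization and
#' cell-number estimation in one call, plus the Rose-criterion
#' detectability check when a background mask is available.
#'
#' @param img an uncorrected [image3d()].
#' @param roi logical ROI mask.
#' @param ref logical reference-tube mask.
#' @param spins_per_cell per-cell loading Y (> 0), e.g. from
#'   [calibrate_loading()].
#' @param c_ref reference spin concentration, spins/uL.
#' @param background optional signal-free mask for SNR estimation; when
#'   omitted, voxels outside \code{roi} and \code{ref} are used.
#' @param snr_threshold detectability threshold, default 5.
#' @return Object of class \code{quant_result}: \code{background_x},
#'   \code{roi_sum}, \code{ref_mean_per_voxel}, \code{total_spins},
#'   \code{cell_count}, \code{detectable}, \code{snr}.
#' @export
quantify_cells <- function(img, roi, ref, spins_per_cell, c_ref = 2.6e16,
                           background = NULL, snr_threshold = 5) {
  stopifnot(inherits(img, "image3d"))
  check_mask(img, roi, "roi")
  check_mask(img, ref, "ref")
  bc <- background_correct(img)
  roi_sum <- roi_total_signal(bc$image, roi)
  ref_mean <- reference_mean(bc$image, ref)
  X <- estimate_total_spins(roi_sum, ref_mean, c_ref = c_ref,
                            voxel_volume_uL = voxel_volume_uL(img$grid))
  n_hat <- estimate_cell_number(X, spins_per_cell)
  if (is.null(background)) background <- !(roi | ref)
  det <- classify_detectable(bc$image, roi, background = background,
                             threshold = snr_threshold)
  structure(list(background_x = bc$background_x, roi_sum = roi_sum,
                 ref_mean_per_voxel = ref_mean, total_spins = X,
                 cell_count = n_hat, detectable = det$detectable,
                 snr = det$snr),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "19F quantification: N = %.4g cells (X = %.4g spins; SNR %.2f, %s)\n",
    x$cell_count, x$total_spins, x$snr,
    if (x$detectable) "detectable" else "not detectable"))
  invisible(x)
}
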