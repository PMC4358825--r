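#' Configuration for the in-vitro linearity study
#'
#' Study conditions for the pellet validation experiment: a dilution series
#' of labeled-cell pellets imaged alongside the reference tube, repeated on
#' several "occasions" that differ only in their noise realization (same
#' geometry, new seed), then quantified against the ground-truth ROI.
#'
#' @param cell_counts pellet series; default \code{c(2e5, 4e5, 6e5, 8e5,
#'   1e6, 2e6)} cells.
#' @param spins_per_cell per-cell loading Y; \code{NULL} (default) draws one
#'   loading per study from the observed 8.2e10-2.4e11 spins/cell range.
#' @param c_ref reference concentration, spins/uL (default 2.6e16).
#' @param grid,pellet_center_mm,pellet_radius_mm,reference,off_resonance
#'   geometry passed to [build_pellet_series()].
#' @param noise_sd,gain,pulse acquisition settings (see
#'   [acquisition_params()]).
#' @param n_replicates imaging occasions; default 3.
#' @param seed base integer seed; all study randomness derives from it.
#' @return Object of class \code{study_config}.
#' @export
study_config <- function(cell_counts = c(2e5, 4e5, 6e5, 8e5, 1e6, 2e6),
                         spins_per_cell = NULL,
                         c_ref = 2.6e16,
                         grid = voxel_grid(c(32, 32, 16)),
                         pellet_center_mm = c(10, 16, 16),
                         pellet_radius_mm = 2,
                         reference = NULL,
                         off_resonance = NULL,
                         noise_sd = 125, gain = 1e-12,
                         pulse = excitation_pulse("plain_sinc", 1.32),
                         n_replicates = 3, seed = 1L) {
  stopifnot(n_replicates >= 1, length(cell_counts) >= 1)
  structure(list(cell_counts = cell_counts, spins_per_cell = spins_per_cell,
                 c_ref = c_ref, grid = grid,
                 pellet_center_mm = pellet_center_mm,
                 pellet_radius_mm = pellet_radius_mm,
                 reference = reference, off_resonance = off_resonance,
                 noise_sd = noise_sd, gain = gain, pulse = pulse,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Linear fit of estimated versus true cell number
#'
#' Ordinary least squares of the estimates on the true counts, with the
#' coefficient of determination of that fit and the Pearson correlation of
#' the pairs. For simple linear regression R^2 equals r^2.
#'
#' @param true_counts true cell numbers (>= 3 distinct values).
#' @param estimates quantified cell numbers, same length.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{pearson_r}, \code{n_points}.
#' @export
fit_linearity <- function(true_counts, estimates) {
  stopifnot(length(true_counts) == length(estimates))
  if (length(true_counts) < 3)
    stop("at least 3 paired points required")
  if (stats::var(true_counts) == 0)
    stop("constant true counts: regression is degenerate")
  fit <- stats::lm(estimates ~ true_counts)
  # R^2 from the residuals directly (summary.lm warns on exact fits)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((estimates - mean(estimates))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       pearson_r = stats::cor(true_counts, estimates),
       n_points = length(true_counts))
}

#' Run the pellet linearity study
#'
#' For each replicate seed, generates the full pellet series, quantifies
#' every pellet with its ground-truth ROI and reference masks, and
#' aggregates: per-pellet mean and SD of the estimated count across
#' replicates, and the linear fit of the per-pellet means against the true
#' counts. Deterministic given the config seed.
#'
#' @param cfg a [study_config()].
#' @return Object of class \code{linearity_report}: \code{per_pellet}
#'   (data frame: true_count, mean_estimate, sd_estimate), \code{fit}
#'   (from [fit_linearity()]), \code{spins_per_cell} used, \code{results}
#'   (per-replicate data frame incl. every quant field), \code{config}.
#' @examples
#' \donttest{
#' rep <- run_pellet_study(study_config(n_replicates = 2, seed = 7))
#' rep$fit$r_squared
#' }
#' @export
run_pellet_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  loading <- cfg$spins_per_cell
  if (is.null(loading))
    loading <- withr::with_seed(cfg$seed, sample_loading(1))
  specs <- build_pellet_series(cfg$cell_counts, spins_per_cell = loading,
                               grid = cfg$grid,
                               pellet_center_mm = cfg$pellet_center_mm,
                               pellet_radius_mm = cfg$pellet_radius_mm,
                               reference = cfg$reference,
                               off_resonance = cfg$off_resonance)
  rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    for (i in seq_along(specs)) {
      seed_ri <- cfg$seed + 997L * r + i
      acq <- acquisition_params(noise_sd = cfg$noise_sd, gain = cfg$gain,
                                seed = seed_ri, pulse = cfg$pulse)
      ph <- generate_fluorine_image(specs[[i]], acq)
      bg <- !Reduce(`|`, ph$masks)
      q <- quantify_cells(ph$image, roi = ph$masks$pellet_1,
                          ref = ph$masks$reference,
                          spins_per_cell = loading, c_ref = cfg$c_ref,
                          background = bg)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, true_count = cfg$cell_counts[i],
        estimate = q$cell_count, background_x = q$background_x,
        roi_sum = q$roi_sum, total_spins = q$total_spins,
        snr = q$snr, detectable = q$detectable)
    }
  }
  res <- do.call(rbind, rows)
  per <- do.call(rbind, lapply(split(res, res$true_count), function(d) {
    data.frame(true_count = d$true_count[1],
               mean_estimate = mean(d$estimate),
               sd_estimate = if (nrow(d) > 1) stats::sd(d$estimate) else 0)
  }))
  per <- per[order(per$true_count), ]
  rownames(per) <- NULL
  fit <- fit_linearity(per$true_count, per$mean_estimate)
  structure(list(per_pellet = per, fit = fit, spins_per_cell = loading,
                 results = res, config = cfg),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat(sprintf(
    "Pellet linearity study: %d pellets x %d replicates (Y = %.3g spins/cell)\n",
    nrow(x$per_pellet), x$config$n_replicates, x$spins_per_cell))
  cat(sprintf("  slope = %.4f, intercept = %.4g\n",
              x$fit$slope, x$fit$intercept))
  cat(sprintf("  R^2 = %.4f, Pearson r = %.4f\n",
              x$fit$r_squared, x$fit$pearson_r))
  invisible(x)
}

#' Configuration for the synthetic two-cohort clearance study
#'
#' A stand-in for longitudinal in-vivo imaging: each subject starts with
#' \code{n0} implanted cells that clear exponentially,
#' \eqn{N(t) = N_0 e^{-k_s t}}, with the per-subject rate \eqn{k_s}
#' log-normal across subjects. Two cohorts differ only in their median
#' clearance rate: a fast one (immune-competent-like) and a slow one
#' (immune-compromised-like). This decay model is a fixture for exercising
#' the statistics, not a biological claim.
#'
#' @param n_subjects subjects per cohort, default 7.
#' @param n0 implanted cell number, default 2e6.
#' @param rate_median median clearance rate, per day.
#' @param rate_sdlog log-scale SD of the subject rates, default 0.3.
#' @param days imaging timepoints, default \code{c(0, 3, 9, 16)}.
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 7, n0 = 2e6, rate_median = 0.25,
                          rate_sdlog = 0.3, days = c(0, 3, 9, 16)) {
  stopifnot(n_subjects >= 2, n0 > 0, rate_median >= 0, rate_sdlog >= 0,
            length(days) >= 2)
  structure(list(n_subjects = as.integer(n_subjects), n0 = n0,
                 rate_median = rate_median, rate_sdlog = rate_sdlog,
                 days = days),
            class = "cohort_config")
}

simulate_cohort <- function(cohort, cfg, loading, seed) {
  rates <- withr::with_seed(seed, {
    if (cohort$rate_median == 0) rep(0, cohort$n_subjects)
    else stats::rlnorm(cohort$n_subjects, log(cohort$rate_median),
                       cohort$rate_sdlog)
  })
  rows <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (d in seq_along(cohort$days)) {
      n_true <- round(cohort$n0 * exp(-rates[s] * cohort$days[d]))
      spec <- phantom_spec(
        cfg$grid,
        pellet_spec(cfg$pellet_center_mm, cfg$pellet_radius_mm,
                    n_cells = n_true, spins_per_cell = loading),
        reference = if (is.null(cfg$reference))
          reference_tube_spec(c(24, 16, 16), 1.5, 24) else cfg$reference)
      acq <- acquisition_params(noise_sd = cfg$noise_sd, gain = cfg$gain,
                                seed = seed + 131L * s + d,
                                pulse = cfg$pulse)
      ph <- generate_fluorine_image(spec, acq)
      bg <- !Reduce(`|`, ph$masks)
      q <- quantify_cells(ph$image, ph$masks$pellet_1, ph$masks$reference,
                          spins_per_cell = loading, c_ref = cfg$c_ref,
                          background = bg)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s),
        timepoint = sprintf("day%d", cohort$days[d]),
        day = cohort$days[d], true_count = n_true,
        cell_count = q$cell_count, detectable = q$detectable, snr = q$snr)
    }
  }
  do.call(rbind, rows)
}

#' Run the synthetic two-cohort longitudinal study
#'
#' Simulates per-subject exponential clearance in a fast and a slow cohort,
#' images and quantifies every subject at every timepoint, and runs the
#' longitudinal statistics (repeated-measures ANOVA, Tukey post-hoc,
#' percent remaining, detectability tally) per cohort. The fast cohort
#' should lose detectability earlier; the report includes each cohort's
#' endpoint tally so that ordering can be checked.
#'
#' @param fast,slow [cohort_config()]s; defaults: median rates 0.25 and
#'   0.05 per day.
#' @param cfg a [study_config()] providing geometry and acquisition
#'   settings (its pellet series is ignored here).
#' @param seed integer seed for the whole study.
#' @return Object of class \code{cohort_report}: per cohort a list with
#'   \code{data} (long data frame), \code{table}, \code{anova},
#'   \code{tukey}, \code{percent_remaining}, \code{tally}; plus
#'   \code{spins_per_cell} and \code{seed}.
#' @export
run_longitudinal_study <- function(fast = cohort_config(rate_median = 0.25),
                                   slow = cohort_config(n0 = 1.5e6,
                                                        rate_median = 0.05),
                                   cfg = study_config(), seed = 1L) {
  seed <- as.integer(seed)
  loading <- cfg$spins_per_cell
  if (is.null(loading))
    loading <- withr::with_seed(seed, sample_loading(1))
  analyze <- function(dat) {
    tab <- longitudinal_table(dat[, c("subject", "timepoint", "cell_count")])
    list(data = dat, table = tab,
         anova = rm_anova(tab),
         tukey = tukey_posthoc(tab),
         percent_remaining = percent_remaining(tab),
         tally = detectability_tally(dat))
  }
  out <- list(
    fast = analyze(simulate_cohort(fast, cfg, loading, seed + 10007L)),
    slow = analyze(simulate_cohort(slow, cfg, loading, seed + 20011L)),
    spins_per_cell = loading, seed = seed)
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  for (nm in c("fast", "slow")) {
    co <- x[[nm]]
    endpoint <- co$tally[nrow(co$tally), ]
    cat(sprintf("%s cohort: F(%.3f, %.3f) = %.2f, p = %.3g; endpoint detectable %s\n",
                nm, co$anova$df1, co$anova$df2, co$anova$F, co$anova$p,
                endpoint$label))
  }
  invisible(x)
}
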