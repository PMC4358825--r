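# Independent oracles and fixture builders shared across tests.

# Brute-force repeated-measures ANOVA: explicit sums-of-squares loops and
# the classical Box/Greenhouse-Geisser epsilon formula on the sample
# covariance matrix. Deliberately written with loops and the closed-form
# epsilon (no eigen-decomposition, no matrix centering) so it shares no
# code path with rm_anova().
oracle_rm_anova <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_time <- 0
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(y[, j]) - grand)^2
  ss_sub <- 0
  for (i in seq_len(n)) ss_sub <- ss_sub + k * (mean(y[i, ]) - grand)^2
  ss_err <- sum((y - grand)^2) - ss_time - ss_sub
  Fstat <- (ss_time / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    S[a, b] <- sum((y[, a] - mean(y[, a])) * (y[, b] - mean(y[, b]))) /
      (n - 1)
  s_bar <- mean(S)
  d_bar <- mean(diag(S))
  row_bar <- rowMeans(S)
  eps <- (k * (d_bar - s_bar))^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(row_bar^2) + k^2 * s_bar^2))
  df1 <- eps * (k - 1)
  df2 <- eps * (k - 1) * (n - 1)
  list(F = Fstat, epsilon = eps, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# Random subjects x timepoints table with subject offsets, a time trend
# and noise; guaranteed non-degenerate.
random_table <- function(n, k) {
  subj <- rnorm(n, 0, 2)
  trend <- seq(0, 1, length.out = k) * runif(1, 0.5, 3)
  y <- outer(subj, trend, "+") + matrix(rnorm(n * k), n, k) + 10
  dimnames(y) <- list(paste0("S", 1:n), paste0("t", 1:k))
  y
}

# Table whose sample covariance is exactly the identity (hence exactly
# spherical / compound symmetric): whiten the columns of a random table.
whitened_table <- function(n, k) {
  y <- matrix(rnorm(n * k), n, k)
  yc <- scale(y, center = TRUE, scale = FALSE)
  W <- solve(chol(stats::cov(y)))
  out <- yc %*% W + 100   # keep counts nonnegative; constants do not
                          # affect F or epsilon
  dimnames(out) <- list(paste0("S", 1:n), paste0("t", 1:k))
  out
}

# Study config on a small grid for fast cohort simulations.
small_cfg <- function(...) {
  study_config(grid = voxel_grid(c(16, 16, 8)),
               pellet_center_mm = c(5, 8, 8),
               reference = reference_tube_spec(c(12, 8, 8), 1.5, 12),
               ...)
}

# One-pellet phantom used across quantification tests.
simple_phantom <- function(n_cells = 2e5, spins_per_cell = 1.5e11,
                           c_ref = 2.6e16, off_resonance = NULL) {
  phantom_spec(voxel_grid(c(32, 32, 16)),
               pellet_spec(c(10, 16, 16), 2, n_cells, spins_per_cell),
               reference = reference_tube_spec(c(24, 16, 16), 1.5, 24,
                                               c_ref),
               off_resonance = off_resonance)
}

background_of <- function(ph) !Reduce(`|`, ph$masks)
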