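#' Longitudinal cell-count table
#'
#' Subjects x timepoints matrix of estimated cell counts. Accepts a wide
#' numeric matrix (rows = subjects, columns = ordered timepoints) or a
#' long data frame with columns \code{subject}, \code{timepoint},
#' \code{cell_count}. Missing observations are allowed but flagged: the
#' repeated-measures analysis uses complete cases only. Zero counts are
#' valid observations (undetectable is not missing).
#'
#' @param x wide matrix or long data frame.
#' @param timepoints optional character vector fixing timepoint order;
#'   defaults to column order (matrix) or order of appearance (data frame).
#' @return Object of class \code{longitudinal_table} with elements
#'   \code{counts} (matrix), \code{subjects}, \code{timepoints},
#'   \code{complete} (logical per subject).
#' @export
longitudinal_table <- function(x, timepoints = NULL) {
  if (is.data.frame(x)) {
    need <- c("subject", "timepoint", "cell_count")
    if (!all(need %in% names(x)))
      stop("long data frame needs columns subject, timepoint, cell_count")
    tp <- if (is.null(timepoints)) unique(as.character(x$timepoint))
          else timepoints
    sub <- unique(as.character(x$subject))
    counts <- matrix(NA_real_, length(sub), length(tp),
                     dimnames = list(sub, tp))
    counts[cbind(match(as.character(x$subject), sub),
                 match(as.character(x$timepoint), tp))] <- x$cell_count
  } else if (is.matrix(x)) {
    counts <- x
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("S", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
      colnames(counts) <- paste0("t", seq_len(ncol(counts)))
    if (!is.null(timepoints)) counts <- counts[, timepoints, drop = FALSE]
  } else stop("'x' must be a matrix or a long data frame")
  if (ncol(counts) < 2) stop("at least 2 timepoints required")
  if (any(counts < 0, na.rm = TRUE)) stop("cell counts must be nonnegative")
  structure(list(counts = counts, subjects = rownames(counts),
                 timepoints = colnames(counts),
                 complete = stats::complete.cases(counts)),
            class = "longitudinal_table")
}

complete_counts <- function(tab) {
  stopifnot(inherits(tab, "longitudinal_table"))
  y <- tab$counts[tab$complete, , drop = FALSE]
  if (nrow(y) < nrow(tab$counts))
    warning(sprintf("%d subject(s) with missing timepoints dropped (complete-case analysis)",
                    nrow(tab$counts) - nrow(y)))
  if (nrow(y) < 2) stop("fewer than 2 complete-case subjects")
  y
}

#' Repeated-measures one-way ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA of counts over timepoints. The time effect
#' is tested against the subject-by-time interaction:
#' \code{F = MS_time / MS_error} with nominal df \code{(k-1, (k-1)(n-1))}.
#' Because repeated measures rarely satisfy sphericity, the reported df are
#' scaled by the Greenhouse-Geisser epsilon computed from the eigenvalues
#' of the double-centered covariance matrix of the timepoint columns,
#' \deqn{\hat\varepsilon = (\sum_i \lambda_i)^2 /
#'   ((k-1) \sum_i \lambda_i^2),}
#' yielding the fractional degrees of freedom familiar from
#' \code{F(1.703, 6.812)}-style reports; \code{df2 / df1 = n - 1} always.
#' The p-value comes from the F distribution at the corrected df.
#'
#' @param tab a [longitudinal_table()]; needs >= 2 complete-case subjects.
#' @return Object of class \code{rm_anova} with \code{F}, \code{df1},
#'   \code{df2}, \code{epsilon}, \code{p}, \code{n} (complete subjects),
#'   \code{k} (timepoints), \code{ms_error} and \code{df_error} (the
#'   uncorrected error df, used by [tukey_posthoc()]). A constant table
#'   returns \code{F = 0, p = 1}.
#' @export
rm_anova <- function(tab) {
  y <- complete_counts(tab)
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  col_m <- colMeans(y)
  row_m <- rowMeans(y)
  ss_time <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, col_m, "+") + grand
  ss_err <- sum(resid^2)
  df_time <- k - 1
  df_err <- (k - 1) * (n - 1)
  # GG epsilon from the double-centered covariance of timepoint columns
  S <- stats::cov(y)
  H <- diag(k) - matrix(1 / k, k, k)
  C <- H %*% S %*% H
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  eps <- if (sum(lam^2) <= 0) 1 else sum(lam)^2 / ((k - 1) * sum(lam^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  if (ss_time <= 0 || ss_err <= 0) {
    if (ss_time <= 0) {            # no time effect at all
      Fstat <- 0; p <- 1
    } else {                       # perfect fit: infinite evidence
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- (ss_time / df_time) / (ss_err / df_err)
    p <- stats::pf(Fstat, eps * df_time, eps * df_err, lower.tail = FALSE)
  }
  structure(list(F = Fstat, df1 = eps * df_time, df2 = eps * df_err,
                 epsilon = eps, p = p, n = n, k = k,
                 ms_error = if (df_err > 0) ss_err / df_err else NA_real_,
                 df_error = df_err, ss_time = ss_time, ss_error = ss_err),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures one-way ANOVA (n = %d complete subjects, k = %d timepoints)\n",
    x$n, x$k))
  cat(sprintf("  F(%.3f, %.3f) = %.3f, p = %.4g (GG epsilon = %.3f)\n",
              x$df1, x$df2, x$F, x$p, x$epsilon))
  invisible(x)
}

#' Tukey post-hoc comparisons between timepoints
#'
#' All pairwise timepoint comparisons using the studentized-range
#' distribution, with the within-subject error mean square and (by default)
#' its uncorrected df \code{(k-1)(n-1)}; set \code{df = "gg"} to use the
#' Greenhouse-Geisser corrected error df instead.
#'
#' @param tab a [longitudinal_table()].
#' @param df \code{"uncorrected"} (default) or \code{"gg"}.
#' @return Data frame of class \code{tukey_result}: one row per ordered
#'   pair with \code{timepoint_a}, \code{timepoint_b}, \code{mean_diff}
#'   (b minus a), \code{q} and \code{p_adj}.
#' @export
tukey_posthoc <- function(tab, df = c("uncorrected", "gg")) {
  df <- match.arg(df)
  a <- rm_anova(tab)
  y <- suppressWarnings(complete_counts(tab))
  k <- a$k; n <- a$n
  m <- colMeans(y)
  df_err <- if (df == "gg") a$epsilon * a$df_error else a$df_error
  se <- sqrt(a$ms_error / n)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    timepoint_a = colnames(y)[pairs[1, ]],
    timepoint_b = colnames(y)[pairs[2, ]],
    mean_diff = m[pairs[2, ]] - m[pairs[1, ]],
    row.names = NULL)
  out$q <- if (se > 0) abs(out$mean_diff) / se else
    ifelse(out$mean_diff == 0, 0, Inf)
  out$p_adj <- ifelse(is.infinite(out$q), 0,
                      stats::ptukey(out$q, nmeans = k, df = df_err,
                                    lower.tail = FALSE))
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Percent of baseline signal remaining
#'
#' Per subject and timepoint, \code{100 * count(t) / count(baseline)}; the
#' baseline column is 100 by construction. Subjects with a zero baseline
#' cannot be normalized: they are dropped with a warning and recorded in
#' the \code{excluded_subjects} attribute.
#'
#' @param tab a [longitudinal_table()].
#' @param baseline baseline timepoint label (default: first column).
#' @return Matrix of percentages (subjects x timepoints).
#' @export
percent_remaining <- function(tab, baseline = NULL) {
  stopifnot(inherits(tab, "longitudinal_table"))
  if (is.null(baseline)) baseline <- tab$timepoints[1]
  if (!baseline %in% tab$timepoints) stop("unknown baseline timepoint")
  base <- tab$counts[, baseline]
  bad <- !is.na(base) & base == 0
  if (any(bad)) {
    warning(sprintf("subject(s) %s have zero baseline and are excluded",
                    paste(tab$subjects[bad], collapse = ", ")))
  }
  keep <- !bad
  pct <- 100 * tab$counts[keep, , drop = FALSE] /
    tab$counts[keep, baseline]
  attr(pct, "excluded_subjects") <- tab$subjects[bad]
  pct
}

#' Detectability tally per timepoint
#'
#' How many subjects retain detectable signal at each timepoint, in the
#' "x/n" form used to report endpoint detectability (e.g. 2/7 subjects
#' with signal at day 16).
#'
#' @param flags data frame with columns \code{subject}, \code{timepoint},
#'   \code{detectable} (logical).
#' @param timepoints optional ordering of timepoint labels.
#' @return Data frame with \code{timepoint}, \code{n_detectable}, \code{n},
#'   \code{fraction} and \code{label} ("x/n").
#' @export
detectability_tally <- function(flags, timepoints = NULL) {
  need <- c("subject", "timepoint", "detectable")
  if (!is.data.frame(flags) || !all(need %in% names(flags)))
    stop("'flags' needs columns subject, timepoint, detectable")
  tp <- if (is.null(timepoints)) unique(as.character(flags$timepoint))
        else timepoints
  out <- do.call(rbind, lapply(tp, function(t) {
    sel <- flags$timepoint == t
    data.frame(timepoint = t,
               n_detectable = sum(flags$detectable[sel]),
               n = sum(sel))
  }))
  out$fraction <- out$n_detectable / out$n
  out$label <- sprintf("%d/%d", out$n_detectable, out$n)
  out
}

#' Read / write longitudinal count tables
#'
#' Long-format CSV with columns \code{subject}, \code{timepoint},
#' \code{cell_count} and optionally \code{detectable}.
#'
#' @param path CSV file path.
#' @param timepoints optional timepoint ordering passed to
#'   [longitudinal_table()].
#' @return \code{read_longitudinal_csv}: a list with \code{table} (a
#'   [longitudinal_table()]) and \code{flags} (detectability data frame or
#'   NULL).
#' @export
read_longitudinal_csv <- function(path, timepoints = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- longitudinal_table(df, timepoints = timepoints)
  flags <- if ("detectable" %in% names(df))
    df[, c("subject", "timepoint", "detectable")] else NULL
  list(table = tab, flags = flags)
}

#' @rdname read_longitudinal_csv
#' @param x a long data frame with the columns above.
#' @export
write_longitudinal_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
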