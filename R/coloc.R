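#' Pearson correlation of two channels over a mask
#'
#' @param A,B Co-registered numeric arrays of identical shape.
#' @param mask Logical array of the same shape selecting the ROI (e.g. a
#'   whole-cell mask); `NULL` uses every voxel.
#' @return Pearson's r over the masked voxels.
#' @export
pearson_r <- function(A, B, mask = NULL) {
  if (!identical(dim(A), dim(B)) && !(is.null(dim(A)) && is.null(dim(B)) &&
                                      length(A) == length(B))) {
    stop("'A' and 'B' must have identical shape", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(A))
  a <- as.numeric(A[mask]); b <- as.numeric(B[mask])
  if (length(a) < 2L) stop("need at least 2 masked voxels", call. = FALSE)
  if (var(a) == 0 || var(b) == 0) {
    stop("zero variance in a channel over the mask", call. = FALSE)
  }
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

#' Costes automatic threshold co-localization
#'
#' Fits B = a A + b by ordinary least squares over the mask, then lowers a
#' candidate threshold T_A through the sorted distinct masked values of A
#' (capped at `max_levels` evenly spaced levels for large images), with the
#' paired threshold T_B = a T_A + b, until the Pearson correlation of the
#' sub-threshold voxels drops to zero or below. Reports the thresholds, the
#' sub-threshold correlation at the stop, and the correlation of the voxels
#' above both thresholds, alongside the unthresholded correlation.
#'
#' @param A,B Co-registered arrays.
#' @param mask Logical ROI mask (`NULL` = all voxels).
#' @param max_levels Scan granularity: all distinct values when there are at
#'   most this many, otherwise this many evenly spaced levels.
#' @param below `"and"` (default): sub-threshold voxels satisfy A <= T_A and
#'   B <= T_B; `"or"`: either channel below its threshold. Published Costes
#'   implementations differ on this point, so both are available.
#' @return A `coloc_result`: list with `r_all`, `slope`, `intercept`,
#'   `threshold_A`, `threshold_B`, `r_below` (at the stopping point; NA if
#'   no sub-threshold set was scorable), `r_above` (NA if fewer than 2
#'   voxels remain above), `n_above`, and `flag` (`"ok"` or
#'   `"no-positive-correlation-threshold"` when the regression slope is
#'   not positive).
#' @export
costes_threshold <- function(A, B, mask = NULL, max_levels = 4096L,
                             below = c("and", "or")) {
  below <- match.arg(below)
  if (is.null(mask)) mask <- rep(TRUE, length(A))
  a <- as.numeric(A[mask]); b <- as.numeric(B[mask])
  r_all <- pearson_r(a, b)
  fit <- lm(b ~ a)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  res <- list(r_all = r_all, slope = slope, intercept = intercept,
              threshold_A = NA_real_, threshold_B = NA_real_,
              r_below = NA_real_, r_above = NA_real_, n_above = NA_integer_,
              flag = "ok")
  if (slope <= 0) {
    res$flag <- "no-positive-correlation-threshold"
    class(res) <- "coloc_result"
    return(res)
  }
  lev <- sort(unique(a), decreasing = TRUE)
  if (length(lev) > max_levels) {
    lev <- seq(max(a), min(a), length.out = max_levels)
  }
  t_stop <- lev[length(lev)]
  r_stop <- NA_real_
  for (ta in lev) {
    tb <- slope * ta + intercept
    sel <- if (below == "and") (a <= ta & b <= tb) else (a <= ta | b <= tb)
    if (sum(sel) < 2L) next
    av <- a[sel]; bv <- b[sel]
    if (var(av) == 0 || var(bv) == 0) next
    r_bel <- pearson_r(av, bv)
    t_stop <- ta; r_stop <- r_bel
    if (r_bel <= 0) break
  }
  res$threshold_A <- t_stop
  res$threshold_B <- slope * t_stop + intercept
  res$r_below <- r_stop
  above <- a > res$threshold_A & b > res$threshold_B
  res$n_above <- sum(above)
  if (res$n_above >= 2L && var(a[above]) > 0 && var(b[above]) > 0) {
    res$r_above <- pearson_r(a[above], b[above])
  }
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: r_all = %.3f (flag: %s)\n", x$r_all, x$flag))
  if (x$flag == "ok") {
    cat(sprintf("  thresholds A/B = %.4g / %.4g; r_below = %.3f; r_above = %.3f (n = %d)\n",
                x$threshold_A, x$threshold_B, x$r_below, x$r_above,
                x$n_above))
  }
  invisible(x)
}

#' Welch's unpaired two-sample t-test
#'
#' Two-sided unequal-variance t-test, as used for comparing group mean
#' co-localization coefficients. Computed via [stats::t.test()].
#'
#' @param sample1,sample2 Numeric vectors (n >= 2 each).
#' @return A `group_comparison`: per-group n/mean/SEM, the Welch t
#'   statistic, Welch-Satterthwaite degrees of freedom, and the two-sided
#'   p-value.
#' @export
welch_t_test <- function(sample1, sample2) {
  if (length(sample1) < 2L || length(sample2) < 2L) {
    stop("need n >= 2 per group", call. = FALSE)
  }
  if (var(sample1) == 0 && var(sample2) == 0) {
    if (mean(sample1) == mean(sample2)) {
      return(structure(list(
        n1 = length(sample1), n2 = length(sample2),
        mean1 = mean(sample1), mean2 = mean(sample2),
        sem1 = 0, sem2 = 0, t = 0, df = length(sample1) + length(sample2) - 2,
        p_value = 1), class = "group_comparison"))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tt <- t.test(sample1, sample2, var.equal = FALSE)
  structure(list(n1 = length(sample1), n2 = length(sample2),
                 mean1 = mean(sample1), mean2 = mean(sample2),
                 sem1 = std_err(sample1), sem2 = std_err(sample2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.3f, df = %.2f, p = %.3g\n",
              x$t, x$df, x$p_value))
  cat(sprintf("  group 1: n = %d, mean = %.3f +/- %.3f (SEM)\n",
              x$n1, x$mean1, x$sem1))
  cat(sprintf("  group 2: n = %d, mean = %.3f +/- %.3f (SEM)\n",
              x$n2, x$mean2, x$sem2))
  invisible(x)
}
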