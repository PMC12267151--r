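#' Analytic power for a main effect in a balanced two-way ANOVA
#'
#' Noncentral-F power for one main effect of a balanced between-subjects
#' factorial: numerator df `levels - 1`, denominator df `N - n_cells`
#' (cells model with interaction), noncentrality `lambda = f^2 N` where `f`
#' is Cohen's standardized effect size and `N` the total sample size.
#'
#' @param f Cohen's f for the effect (> 0).
#' @param n_per_group per-cell sample size.
#' @param alpha type-I error rate.
#' @param levels number of levels of the factor (numerator df + 1).
#' @param n_cells number of cells in the design (4 for 2x2).
#' @return power in (0, 1).
#' @export
power_2way_main_effect <- function(f, n_per_group, alpha = 0.05, levels = 2,
                                   n_cells = 4) {
  stopifnot(f > 0, n_per_group >= 2, alpha > 0, alpha < 1, levels >= 2)
  N <- n_per_group * n_cells
  df1 <- levels - 1
  df2 <- N - n_cells
  if (df2 < 1) return(0)
  lambda <- f^2 * N
  1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

#' Required per-group sample size for a 2x2 factorial
#'
#' Smallest per-cell n such that *both* main effects reach the target power
#' under the noncentral-F computation of [power_2way_main_effect()];
#' equivalently the larger of the two per-effect requirements. Deterministic
#' and quartile-free.
#'
#' @param f_A,f_B Cohen's f for the two main effects.
#' @param alpha type-I error rate.
#' @param power target power.
#' @param n_max search cap.
#' @return integer n per group.
#' @export
required_sample_size_2x2 <- function(f_A, f_B, alpha = 0.05, power = 0.80,
                                     n_max = 1e6) {
  stopifnot(f_A > 0, f_B > 0, power > 0, power < 1)
  need_n <- function(f) {
    for (n in 2:n_max) {
      if (power_2way_main_effect(f, n, alpha) >= power) return(n)
    }
    stop("target power unreachable within n <= ", n_max)
  }
  max(need_n(f_A), need_n(f_B))
}

#' Flag outliers by the 1.5 x IQR fence within cells
#'
#' Tukey fences computed within each grouping cell (e.g. birthweight class x
#' supplementation): a value is flagged if it exceeds `Q3 + k IQR` or falls
#' below `Q1 - k IQR`, quartiles by linear interpolation (type 7). Flags
#' only — removal is an explicit user decision. Cells with fewer than 4
#' values are skipped with a warning (no flags there).
#'
#' @param x numeric values.
#' @param group optional grouping (factor/character/interaction) of the same
#'   length; `NULL` treats all values as one cell.
#' @param multiplier fence multiplier k, default 1.5.
#' @param quartile_type quantile algorithm (see [stats::quantile()]).
#' @return logical vector of flags, same length as `x`.
#' @export
flag_iqr_outliers <- function(x, group = NULL, multiplier = 1.5,
                              quartile_type = 7) {
  stopifnot(is.numeric(x), multiplier > 0)
  if (is.null(group)) group <- rep.int(1L, length(x))
  stopifnot(length(group) == length(x))
  flags <- logical(length(x))
  for (g in unique(group)) {
    i <- which(group == g & !is.na(x))
    if (length(i) < 4L) {
      warning(sprintf("cell '%s' has fewer than 4 values; skipped", g))
      next
    }
    q <- stats::quantile(x[i], c(0.25, 0.75), type = quartile_type, names = FALSE)
    iqr <- q[2] - q[1]
    flags[i] <- x[i] > q[2] + multiplier * iqr | x[i] < q[1] - multiplier * iqr
  }
  flags
}

#' Zootechnical body indices
#'
#' Body mass index `BMI = BW / CRL^2` (kg/m^2) and ponderal index
#' `PI = BW / CRL^3` (kg/m^3) from bodyweight and crown-rump length.
#'
#' @param bw_kg bodyweight (kg).
#' @param crl_m crown-rump length (m), > 0.
#' @return data frame with `bmi_kg_m2` and `pi_kg_m3`.
#' @export
body_indices <- function(bw_kg, crl_m) {
  stopifnot(is.numeric(bw_kg), is.numeric(crl_m))
  if (any(crl_m <= 0)) stop("crown-rump length must be > 0")
  data.frame(bmi_kg_m2 = bw_kg / crl_m^2, pi_kg_m3 = bw_kg / crl_m^3)
}

#' Average daily gain over an age window
#'
#' `(BW_end - BW_start) / (d_end - d_start)`, the convention used for whole
#' study (1-16 d), pre-surgery (1-12 d) and post-surgery (13-16 d) windows.
#'
#' @param bw_start,bw_end bodyweights (kg) at the window bounds.
#' @param d_start,d_end ages (d), `d_end > d_start`.
#' @return ADG in kg/d.
#' @export
average_daily_gain <- function(bw_start, bw_end, d_start, d_end) {
  stopifnot(all(d_end > d_start))
  (bw_end - bw_start) / (d_end - d_start)
}
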