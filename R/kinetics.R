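#' Build a per-minute foci-per-cell kinetics table
#'
#' Mean and sample SD of the foci-per-cell (FPC) series across nuclei at each
#' minute, plus a smoothed (fitted) curve from local polynomial (LOESS)
#' regression. The smoothed curves are what the additive mixed-beam
#' expectation operates on.
#'
#' @param fpc matrix (nuclei in rows, frames in columns), or a list of
#'   per-nucleus FPC vectors of equal length, or a single vector.
#' @param condition condition label.
#' @param frame_interval minutes per frame.
#' @param span LOESS span.
#' @return data.frame of class `kinetics_table`: `minute`, `mean`, `sd`, `n`,
#'   `fitted`, with the condition label as attribute `"condition"`.
#' @export
build_kinetics <- function(fpc, condition = NA_character_,
                           frame_interval = 1, span = 0.4) {
  if (is.list(fpc)) fpc <- do.call(rbind, fpc)
  if (is.vector(fpc)) fpc <- matrix(fpc, nrow = 1)
  stopifnot(nrow(fpc) >= 1)
  minute <- (seq_len(ncol(fpc)) - 1) * frame_interval
  mn <- colMeans(fpc)
  sdv <- if (nrow(fpc) == 1) rep(0, ncol(fpc)) else apply(fpc, 2, stats::sd)
  fitted <- if (ncol(fpc) >= 10) {
    stats::predict(stats::loess(mn ~ minute, span = span, degree = 2))
  } else mn
  out <- data.frame(minute = minute, mean = mn, sd = sdv,
                    n = nrow(fpc), fitted = as.numeric(fitted))
  attr(out, "condition") <- condition
  class(out) <- c("kinetics_table", "data.frame")
  out
}

#' Kinetics table from anchor values
#'
#' Noiseless kinetics table whose mean and fitted curves are the anchor
#' profile itself ([fpc_profile()]); used to reproduce published summary
#' arithmetic from the printed anchor values.
#'
#' @param anchors anchor list (see [fpc_profile()]) or a condition label
#'   whose defaults are taken from [condition_defaults()].
#' @param minutes evaluation grid, minutes.
#' @return a `kinetics_table`.
#' @export
#' @examples
#' summarize_kinetics(anchor_kinetics("xray"), anchor_kinetics("control"))
anchor_kinetics <- function(anchors, minutes = 0:75) {
  condition <- NA_character_
  if (is.character(anchors)) {
    condition <- anchors
    anchors <- condition_defaults(anchors)$kinetics_anchors
  }
  m <- fpc_profile(minutes, anchors, t_final = max(minutes))
  out <- data.frame(minute = minutes, mean = m, sd = 0, n = NA_integer_,
                    fitted = m)
  attr(out, "condition") <- condition
  class(out) <- c("kinetics_table", "data.frame")
  out
}

#' Summarise a kinetics table against the control level
#'
#' Reports the initial (first-minute) mean FPC, the highest mean FPC with its
#' time, the final mean FPC, the maximum focus increase (highest FPC divided
#' by the mean control FPC) and the maximum focus reduction. The reduction is
#' computed as the ratio highest/final: the published table footnote calls it
#' a difference, but the printed values equal the ratios, which the
#' implementation follows.
#'
#' @param table a `kinetics_table`.
#' @param control the control `kinetics_table`.
#' @return data.frame of class `kinetics_summary` with `initial`, `highest`,
#'   `t_peak` (min), `final`, `max_increase`, `max_reduction`. Values carry
#'   full precision; `print` rounds FPC and ratios to one decimal.
#' @export
summarize_kinetics <- function(table, control) {
  stopifnot(inherits(table, "kinetics_table"))
  ctrl <- mean(control$mean)
  if (ctrl <= 0) stop("control mean FPC is zero")
  i_max <- which.max(table$mean)
  final <- table$mean[nrow(table)]
  out <- data.frame(
    initial = table$mean[1],
    highest = table$mean[i_max],
    t_peak = table$minute[i_max],
    final = final,
    max_increase = table$mean[i_max] / ctrl,
    max_reduction = table$mean[i_max] / final)
  class(out) <- c("kinetics_summary", "data.frame")
  out
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "FPC: initial %.1f, highest %.1f (%g min), final %.1f; max increase %.1f, max reduction %.1f\n",
    x$initial, x$highest, x$t_peak, x$final, x$max_increase,
    x$max_reduction))
  invisible(x)
}

#' Additive mixed-beam expectation
#'
#' Expected mixed-beam FPC kinetics under additivity: half the sum of the
#' fitted alpha-particle and X-ray curves, pointwise on a shared minute grid.
#'
#' @param fitted_alpha,fitted_xray `kinetics_table`s on identical minute
#'   grids.
#' @return a `kinetics_table` whose `mean` and `fitted` are the pointwise
#'   half-sums of the inputs' fitted curves.
#' @export
expected_mixed <- function(fitted_alpha, fitted_xray) {
  if (nrow(fitted_alpha) != nrow(fitted_xray) ||
      any(fitted_alpha$minute != fitted_xray$minute)) {
    stop("minute grids do not match")
  }
  e <- (fitted_alpha$fitted + fitted_xray$fitted) / 2
  out <- data.frame(minute = fitted_alpha$minute, mean = e, sd = NA_real_,
                    n = NA_integer_, fitted = e)
  attr(out, "condition") <- "expected"
  class(out) <- c("kinetics_table", "data.frame")
  out
}

#' Ratio of a treated statistic to the control statistic
#'
#' Fading correction by ratio: a treated per-minute statistic (focus area or
#' mean pixel intensity) expressed as a fraction of the control value at the
#' corresponding time point. Standard errors, when supplied, are propagated
#' to first order: `sem_r = r * sqrt((sem_t/t)^2 + (sem_c/c)^2)`.
#'
#' @param treated,control numeric per-minute statistics of equal length;
#'   control must be strictly positive.
#' @param treated_sem,control_sem optional standard errors.
#' @param minutes optional time axis.
#' @return data.frame with `minute`, `ratio` and `sem` (NA without input
#'   SEMs).
#' @export
relative_to_control <- function(treated, control, treated_sem = NULL,
                                control_sem = NULL, minutes = NULL) {
  stopifnot(length(treated) == length(control))
  if (any(control <= 0)) stop("control statistic must be > 0 at all minutes")
  r <- treated / control
  sem <- rep(NA_real_, length(r))
  if (!is.null(treated_sem) && !is.null(control_sem)) {
    sem <- r * sqrt((treated_sem / treated)^2 + (control_sem / control)^2)
  }
  if (is.null(minutes)) minutes <- seq_along(r) - 1
  data.frame(minute = minutes, ratio = r, sem = sem)
}

#' Fit the linear control fading line
#'
#' Ordinary least squares line through the control mean pixel intensity
#' series, and the percent signal loss over the observation window computed
#' from the fitted line.
#'
#' @param intensity control mean pixel intensities, AU.
#' @param minutes time points, minutes.
#' @param window two minutes between which the percent loss is evaluated.
#' @return list with `slope` (AU/min), `intercept` (AU), `percent_loss`, and
#'   the `lm` fit.
#' @export
#' @examples
#' fit_control_fading(139.3 - 0.4627 * (0:75), 0:75)$percent_loss  # ~25
fit_control_fading <- function(intensity, minutes, window = c(0, 75)) {
  stopifnot(length(intensity) >= 2, length(intensity) == length(minutes))
  fit <- stats::lm(intensity ~ minutes)
  b <- stats::coef(fit)
  y0 <- b[[1]] + b[[2]] * window[1]
  y1 <- b[[1]] + b[[2]] * window[2]
  list(slope = -b[[2]], intercept = b[[1]],
       percent_loss = 100 * (y0 - y1) / y0, fit = fit)
}

#' Coefficient of variation of an intensity series
#'
#' Sample SD divided by the mean over the measurement window (by default
#' minutes 1 to 75, the window used to compare intensity stability between
#' radiation qualities). Invariant under positive rescaling of the series.
#'
#' @param x series values.
#' @param minutes time points; default `0:(length(x)-1)`.
#' @param window inclusive minute window, or `NULL` for the full series.
#' @return the coefficient of variation (unitless).
#' @export
coefficient_of_variation <- function(x, minutes = NULL,
                                     window = c(1, 75)) {
  if (is.null(minutes)) minutes <- seq_along(x) - 1
  if (!is.null(window)) {
    keep <- minutes >= window[1] & minutes <= window[2]
    x <- x[keep]
  }
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 points")
  m <- mean(x)
  if (m == 0) stop("series mean is zero")
  stats::sd(x) / m
}

#' Gaussian kernel density estimate of focus intensities
#'
#' Standard Gaussian-kernel density, `f_h(x) = 1/(n h) * sum K((x - X_i)/h)`
#' with the standard normal kernel, evaluated on a uniform grid spanning the
#' data plus/minus `3 h` and normalised to unit area. The default bandwidth
#' is Silverman's rule of thumb.
#'
#' @param x relative focus intensities (n >= 1).
#' @param h bandwidth; `NULL` applies Silverman's rule (requires n >= 2).
#' @param n_grid grid size.
#' @return data.frame of class `intensity_kde` with `x` (grid) and `density`;
#'   bandwidth and trapezoidal area as attributes `"h"` and `"area"`.
#' @export
kde_intensity <- function(x, h = NULL, n_grid = 512) {
  stopifnot(length(x) >= 1)
  if (is.null(h)) {
    if (length(x) < 2) stop("automatic bandwidth needs n >= 2")
    h <- stats::bw.nrd0(x)
  }
  if (h <= 0) stop("bandwidth must be > 0")
  dens <- stats::density(x, bw = h, kernel = "gaussian",
                         from = min(x) - 3 * h, to = max(x) + 3 * h,
                         n = n_grid)
  out <- data.frame(x = dens$x, density = dens$y)
  dx <- diff(dens$x)
  area <- sum(dx * (dens$y[-1] + dens$y[-n_grid]) / 2)
  attr(out, "h") <- h
  attr(out, "area") <- area
  class(out) <- c("intensity_kde", "data.frame")
  out
}

#' Compare conditions by one-way ANOVA
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @param alpha significance level.
#' @return list with `statistic` (F), `df`, `p_value`, `significant`.
#' @export
compare_conditions <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(statistic = Fv, df = tab[["Df"]], p_value = p,
       significant = is.finite(p) && p < alpha)
}

#' Compare counts by a chi-square test on a 2 x 2 table
#'
#' @param counts 2 x 2 matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction.
#' @param alpha significance level.
#' @return list with `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_counts <- function(counts, correct = FALSE, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       significant = is.finite(ht$p.value) && ht$p.value < alpha)
}
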