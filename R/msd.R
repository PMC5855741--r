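#' Confined-diffusion mean square displacement model
#'
#' Closed form of the random-walk-in-a-confined-space (subdiffusion) model:
#' `MSD(dt) = rc^2 * (1 - exp(-2 * d * Dc * dt / rc^2))`. The curve rises
#' with initial slope `2 * d * Dc` and saturates at the plateau `rc^2`.
#'
#' @param dt time lag(s), minutes.
#' @param Dc diffusion coefficient, square micrometres per minute.
#' @param rc radius of constraint, micrometres (> 0).
#' @param d dimension of the analysed space (1, 2 or 3; live imaging at a
#'   fixed focal plane uses 2).
#' @return MSD value(s), square micrometres.
#' @export
#' @examples
#' msd_model(5, Dc = 0.01, rc = 0.5, d = 2)  # 0.25 * (1 - exp(-0.8))
msd_model <- function(dt, Dc, rc, d = 2) {
  if (rc <= 0) stop("rc must be > 0")
  if (!d %in% 1:3) stop("d must be 1, 2 or 3")
  rc^2 * (1 - exp(-2 * d * Dc * dt / rc^2))
}

#' Compute the pooled mean square displacement of focus tracks
#'
#' Time-and-ensemble average: for each lag, the squared displacements of all
#' valid position pairs of all non-excluded tracks are pooled. Pairs must be
#' exactly the lag apart in frame index, so gap-bridged tracks contribute no
#' pairs across their gaps. The number of contributing pairs is recorded per
#' lag and used as fit weights downstream.
#'
#' @param tracks data.frame with `track_id`, `frame`, `x`, `y` (micrometres)
#'   and optionally `excluded`.
#' @param max_lag maximum lag in frames; default one third of the track span,
#'   limiting pair starvation at long lags.
#' @param frame_interval minutes per frame.
#' @param use_excluded include tracks flagged `excluded`.
#' @return data.frame of class `msd_curve` with `lag` (min), `msd` (um^2) and
#'   `n_pairs`.
#' @export
compute_msd <- function(tracks, max_lag = NULL, frame_interval = 1,
                        use_excluded = FALSE) {
  if (!use_excluded && "excluded" %in% names(tracks)) {
    tracks <- tracks[!tracks$excluded, , drop = FALSE]
  }
  keep <- tracks$track_id %in%
    names(which(table(tracks$track_id) >= 2))
  tracks <- tracks[keep, , drop = FALSE]
  if (nrow(tracks) == 0) stop("no valid tracks for MSD")
  span <- max(tracks$frame) - min(tracks$frame)
  if (is.null(max_lag)) max_lag <- max(1L, floor(span / 3))

  # pivot to frame x track matrices (NA where a track has no detection);
  # every pair exactly `lag` frames apart is then one vectorized slice
  f0 <- min(tracks$frame)
  nF <- max(tracks$frame) - f0 + 1L
  ids <- factor(tracks$track_id)
  nTr <- nlevels(ids)
  MX <- matrix(NA_real_, nF, nTr)
  MY <- matrix(NA_real_, nF, nTr)
  idx <- cbind(tracks$frame - f0 + 1L, as.integer(ids))
  MX[idx] <- tracks$x
  MY[idx] <- tracks$y

  max_lag <- min(max_lag, nF - 1L)
  sumsq <- numeric(max_lag)
  npair <- integer(max_lag)
  for (l in seq_len(max_lag)) {
    dx <- MX[(1L + l):nF, , drop = FALSE] - MX[1:(nF - l), , drop = FALSE]
    dy <- MY[(1L + l):nF, , drop = FALSE] - MY[1:(nF - l), , drop = FALSE]
    sq <- dx^2 + dy^2
    ok <- !is.na(sq)
    npair[l] <- sum(ok)
    sumsq[l] <- sum(sq[ok])
  }
  lag_frames <- seq_len(max_lag)
  out <- data.frame(lag = lag_frames * frame_interval,
                    msd = ifelse(npair > 0, sumsq / npair, NA_real_),
                    n_pairs = npair)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the confined-diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of [msd_model()] against a pooled MSD
#' curve, estimating the diffusion coefficient `Dc` and radius of constraint
#' `rc`. Weights are proportional to the number of displacement pairs per lag
#' (pair counts shrink with lag, making long-lag points noisier). Starting
#' values: the plateau `rc^2` from the mean of the last quartile of the
#' curve, and `Dc` from the first lag's slope. Fits are bounded to
#' `Dc >= 0`, `rc > 0`.
#'
#' Identifiability diagnostics: a curve still rising steeply at the longest
#' lag (no plateau reached) gives `warn_rc = TRUE`; a curve already at its
#' plateau by the first lag gives `warn_Dc = TRUE` (for a perfectly flat
#' curve `rc` equals the square root of the plateau while `Dc` is
#' unidentified). Non-convergence is reported via `converged = FALSE`, never
#' as an error.
#'
#' @param curve an `msd_curve` (or data.frame with `lag`, `msd`, and
#'   optionally `n_pairs`), at least 4 lags.
#' @param d dimension of the analysed space.
#' @param weighted weight lags by pair count.
#' @return object of class `confined_fit` with `coefficients` (`Dc`, `rc`),
#'   standard errors, residual sum of squares, convergence and warning flags,
#'   and the data; supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @export
fit_confined <- function(curve, d = 2, weighted = TRUE) {
  stopifnot(all(c("lag", "msd") %in% names(curve)))
  cv <- curve[!is.na(curve$msd), , drop = FALSE]
  if (nrow(cv) < 4) stop("need at least 4 lags with data")
  w <- if (weighted && "n_pairs" %in% names(cv)) cv$n_pairs else
    rep(1, nrow(cv))

  q4 <- cv$msd[cv$lag >= stats::quantile(cv$lag, 0.75)]
  rc2_0 <- max(mean(q4), 1e-8)
  Dc_0 <- max(cv$msd[1] / (2 * d * cv$lag[1]), 1e-8)

  fit <- try(minpack.lm::nlsLM(
    msd ~ rc2 * (1 - exp(-2 * d * Dc * lag / rc2)),
    data = cv, weights = w,
    start = list(rc2 = rc2_0, Dc = Dc_0),
    lower = c(rc2 = 1e-12, Dc = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  if (inherits(fit, "try-error")) {
    co <- c(rc2 = rc2_0, Dc = Dc_0)
    se <- c(rc2 = NA_real_, Dc = NA_real_)
    converged <- FALSE
    rss <- sum(w * (cv$msd - co["rc2"] *
                      (1 - exp(-2 * d * co["Dc"] * cv$lag / co["rc2"])))^2)
  } else {
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(rc2 = NA_real_, Dc = NA_real_))
    converged <- fit$convInfo$isConv %||% TRUE
    rss <- sum(stats::residuals(fit)^2 * w)
  }

  rc <- sqrt(co[["rc2"]])
  Dc <- co[["Dc"]]
  se_rc <- if (is.na(se[["rc2"]])) NA_real_ else se[["rc2"]] / (2 * rc)
  # diagnostics: saturation of the model over the observed lag range
  sat_last <- 2 * d * Dc * max(cv$lag) / co[["rc2"]]
  sat_first <- 2 * d * Dc * min(cv$lag) / co[["rc2"]]
  # a curve already at >= 90% of the plateau by the first lag carries no
  # slope information, whatever the nominal parameters say
  at_plateau_first <- is.finite(co[["rc2"]]) && co[["rc2"]] > 0 &&
    cv$msd[1] >= 0.9 * co[["rc2"]]
  out <- list(
    coefficients = c(Dc = Dc, rc = rc),
    se = c(Dc = unname(se[["Dc"]]), rc = unname(se_rc)),
    d = d, rss = rss, converged = converged,
    warn_rc = sat_last < 1,       # plateau never reached: rc extrapolated
    warn_Dc = sat_first > 3 || at_plateau_first,  # Dc unidentified
    curve = cv,
    fitted = msd_model(cv$lag, Dc, rc, d),
    weights = w)
  class(out) <- "confined_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.confined_fit <- function(x, digits = 4, ...) {
  cat("Confined-diffusion fit (d =", x$d, ")\n")
  cat(sprintf("  Dc = %.*g um^2/min, rc = %.*g um\n",
              digits, x$coefficients["Dc"], digits, x$coefficients["rc"]))
  if (!x$converged) cat("  [fit did not converge]\n")
  if (x$warn_rc) cat("  warning: no plateau within lag range; rc extrapolated\n")
  if (x$warn_Dc) cat("  warning: curve at plateau from the first lag; Dc unidentified\n")
  invisible(x)
}

#' @export
summary.confined_fit <- function(object, ...) {
  co <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = co, d = object$d, rss = object$rss,
                 n = nrow(object$curve), converged = object$converged,
                 warn_rc = object$warn_rc, warn_Dc = object$warn_Dc),
            class = "summary.confined_fit")
}

#' @export
print.summary.confined_fit <- function(x, ...) {
  cat("Confined-diffusion model: MSD(dt) = rc^2 (1 - exp(-2 d Dc dt / rc^2)),",
      "d =", x$d, "\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nWeighted RSS: %.4g on %d lags; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' @export
coef.confined_fit <- function(object, ...) object$coefficients

#' @export
fitted.confined_fit <- function(object, ...) object$fitted

#' @export
residuals.confined_fit <- function(object, ...) {
  object$curve$msd - object$fitted
}

#' @export
#' @method predict confined_fit
predict.confined_fit <- function(object, newdata = NULL, ...) {
  lag <- if (is.null(newdata)) object$curve$lag else newdata$lag
  msd_model(lag, object$coefficients["Dc"], object$coefficients["rc"],
            object$d)
}

#' @export
#' @method plot confined_fit
plot.confined_fit <- function(x, ...) {
  graphics::plot(x$curve$lag, x$curve$msd, xlab = expression(Delta * t ~ "(min)"),
                 ylab = expression(MSD ~ (mu * m^2)), pch = 16, ...)
  lag_fine <- seq(0, max(x$curve$lag), length.out = 200)
  graphics::lines(lag_fine, msd_model(lag_fine, x$coefficients["Dc"],
                                      x$coefficients["rc"], x$d))
  graphics::abline(h = x$coefficients["rc"]^2, lty = 3)
  invisible(x)
}

#' Simulate tracks from a fitted confined-diffusion model
#'
#' Draws OU trajectories at the fitted `Dc` and `rc`, enabling parametric
#' bootstrap checks of the fit.
#'
#' @param object a `confined_fit`.
#' @param nsim number of tracks.
#' @param seed integer seed.
#' @param n_frames,frame_interval track length and spacing.
#' @param ... unused.
#' @return list of trajectories as in [simulate_confined_tracks()].
#' @export
#' @method simulate confined_fit
simulate.confined_fit <- function(object, nsim = 1, seed = 1,
                                  n_frames = 75, frame_interval = 1, ...) {
  cfg <- sim_config("control", n_frames = n_frames,
                    frame_interval = frame_interval,
                    Dc_true = unname(object$coefficients["Dc"]),
                    rc_true = unname(object$coefficients["rc"]),
                    seed = seed)
  simulate_confined_tracks(nsim, cfg, constrain_to_nucleus = FALSE)
}
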