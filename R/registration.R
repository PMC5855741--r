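#' Rigid-body transform utilities
#'
#' A rigid transform `(dx, dy, theta)` maps reference coordinates `p`
#' (pixels; x = column, y = row) to image coordinates
#' `R(theta) (p - c) + c + (dx, dy)`, rotating about the image centre `c`.
#' `compose_rigid(a, b)` returns the transform equivalent to applying `b`
#' then `a`; `invert_rigid(a)` its inverse.
#'
#' @param a,b numeric length-3 vectors `c(dx, dy, theta_deg)`.
#' @return a length-3 transform vector.
#' @export
compose_rigid <- function(a, b) {
  th <- a[3] * pi / 180
  Rb <- c(cos(th) * b[1] - sin(th) * b[2],
          sin(th) * b[1] + cos(th) * b[2])
  c(a[1] + Rb[1], a[2] + Rb[2], a[3] + b[3])
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(a) {
  th <- -a[3] * pi / 180
  c(-(cos(th) * a[1] - sin(th) * a[2]),
    -(sin(th) * a[1] + cos(th) * a[2]),
    -a[3])
}

#' Warp an image by a rigid transform
#'
#' Samples `img` at the transformed coordinates with bilinear interpolation:
#' `out(p) = img(R(theta)(p - c) + c + d)`. Pixels mapping outside the image
#' are set to `fill`.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param dx,dy translation in pixels.
#' @param theta rotation in degrees about the image centre.
#' @param fill value for out-of-field pixels; `NA` marks them invalid.
#' @return warped matrix of the same dimensions.
#' @export
rigid_warp <- function(img, dx, dy, theta, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- theta * pi / 180
  cth <- cos(th); sth <- sin(th)
  pX <- rep(seq_len(nx) - cx, each = ny)
  pY <- rep(seq_len(ny) - cy, times = nx)
  qx <- cth * pX - sth * pY + cx + dx
  qy <- sth * pX + cth * pY + cy + dy

  x0 <- floor(qx); y0 <- floor(qy)
  fx <- qx - x0; fy <- qy - y0
  ok <- x0 >= 1 & x0 <= nx - 1 & y0 >= 1 & y0 <= ny - 1
  out <- rep(as.numeric(fill), nx * ny)
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * ny + y0[ok]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00] +
      fx[ok] * (1 - fy[ok]) * img[i00 + ny] +
      (1 - fx[ok]) * fy[ok] * img[i00 + 1] +
      fx[ok] * fy[ok] * img[i00 + ny + 1]
    out[ok] <- v
  }
  matrix(out, ny, nx)
}

# mean squared difference between warp(moving, par) and fixed, over valid px;
# large finite penalty (not Inf, which breaks optim) when the overlap is poor
warp_mse <- function(par, moving, fixed) {
  w <- rigid_warp(moving, par[1], par[2], par[3])
  ok <- !is.na(w)
  if (mean(ok) < 0.5) return(1e12 * (1 + sum(abs(par))))
  mean((w[ok] - fixed[ok])^2)
}

# integer-shift cross-correlation candidates via FFT; returns best
# (dx, dy) shift and its MSE for J(p + s) ~ fixed(p)
xcorr_shift <- function(fixed, moving) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  a <- fixed - mean(fixed); b <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  peak <- which.max(cc)
  py <- (peak - 1) %% ny; px <- (peak - 1) %/% ny
  wrap <- function(v, n) ifelse(v > n / 2, v - n, v)
  s <- c(wrap(px, nx), wrap(py, ny))
  best <- c(0, 0); best_mse <- shift_mse(moving, fixed, 0, 0)
  for (cand in list(s, -s)) {
    m <- shift_mse(moving, fixed, cand[1], cand[2])
    if (m < best_mse) { best <- cand; best_mse <- m }
  }
  list(shift = best, mse = best_mse)
}

# MSE of moving(p + s) against fixed(p) over the overlap region
shift_mse <- function(moving, fixed, sx, sy) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  cs <- intersect(seq_len(nx), seq_len(nx) - sx)
  rs <- intersect(seq_len(ny), seq_len(ny) - sy)
  if (length(cs) < nx / 2 || length(rs) < ny / 2) return(Inf)
  mean((moving[rs + sy, cs + sx, drop = FALSE] -
          fixed[rs, cs, drop = FALSE])^2)
}

# rigid estimate of one frame against a fixed template: A with
# moving(A(p)) ~ fixed(p); local refine from `init`, backed up by a coarse
# rotation-grid + FFT-translation search when the refine leaves a poor match.
# `confidence` is the fraction of the template variance explained by the
# aligned frame, 1 - mse / var(fixed), clipped to [0, 1].
estimate_rigid_pair <- function(fixed, moving, init = c(0, 0, 0),
                                theta_grid = seq(-6, 6, by = 1),
                                coarse = "auto", reltol = 1e-7,
                                maxit = 150, theta_prior = NULL,
                                theta_penalty = 0) {
  v0 <- mean((fixed - mean(fixed))^2)
  mse0 <- mean((moving - fixed)^2)
  if (stats::sd(moving) < 1e-12 || v0 < 1e-24) {
    return(list(par = c(0, 0, 0), mse = mse0, mse0 = mse0,
                confidence = 0, degenerate = TRUE))
  }
  if (mse0 < 1e-12) {
    return(list(par = c(0, 0, 0), mse = mse0, mse0 = mse0,
                confidence = 1, degenerate = FALSE))
  }
  obj <- if (theta_penalty > 0 && !is.null(theta_prior)) {
    function(par, moving, fixed) {
      warp_mse(par, moving, fixed) +
        theta_penalty * (par[3] - theta_prior)^2
    }
  } else warp_mse
  refine <- function(start) {
    stats::optim(start, obj, moving = moving, fixed = fixed,
                 method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
  }
  fit <- refine(init)
  conf <- min(1, max(0, 1 - fit$value / v0))
  run_coarse <- isTRUE(coarse) ||
    (identical(coarse, "auto") && conf < 0.25)
  if (run_coarse) {
    cand <- NULL; cand_mse <- fit$value
    for (th in unique(c(theta_grid, init[3]))) {
      J <- rigid_warp(moving, 0, 0, th, fill = stats::median(moving))
      xc <- xcorr_shift(fixed, J)
      if (xc$mse < cand_mse) {
        rth <- th * pi / 180
        d <- c(cos(rth) * xc$shift[1] - sin(rth) * xc$shift[2],
               sin(rth) * xc$shift[1] + cos(rth) * xc$shift[2])
        cand <- c(d, th); cand_mse <- xc$mse
      }
    }
    if (!is.null(cand)) {
      fit2 <- refine(cand)
      if (fit2$value < fit$value) fit <- fit2
    }
  }
  mse <- warp_mse(fit$par, moving, fixed)  # data term without the prior
  conf <- min(1, max(0, 1 - mse / v0))
  list(par = fit$par, mse = mse, mse0 = mse0, confidence = conf,
       degenerate = FALSE)
}

#' Estimate per-frame rigid-body transforms of a stack
#'
#' Stabilises whole-nucleus motion: each frame, walking outward from the
#' reference frame, is registered with a rigid (translation + rotation)
#' transform minimising the mean squared intensity difference against a
#' running template -- the average of the previously registered frames in
#' reference coordinates, seeded with the reference frame. Registering
#' against already-registered material chains each frame to the reference
#' while keeping per-frame errors from accumulating as a random walk; the
#' template average suppresses the confined wobble of individual foci.
#' Frames are pre-smoothed (Gaussian, `smooth_sigma`), downscaled
#' (`scale_factor`) and z-scored (removing the photobleaching intensity
#' trend) for the estimation only; the transforms are applied to the raw
#' full-resolution frames by [apply_rigid()]. The Nelder--Mead local
#' search, initialised by extrapolating the previous frame's motion, is
#' backed up by a coarse rotation-grid + FFT-cross-correlation search
#' whenever the aligned frame explains < 25% of the template variance (or
#' always, with `coarse = TRUE`).
#'
#' The `confidence` column is the fraction of the template variance
#' explained by the aligned frame (1 for a perfect match, ~0 for pure
#' noise). Constant/empty frames and frames below `confidence_threshold`
#' are flagged `low_confidence` and still receive their best-effort
#' transform (identity for degenerate frames).
#'
#' @param stack a `timelapse_stack` with at least 2 frames.
#' @param reference_frame index of the frame defining the reference
#'   coordinates (identity transform).
#' @param theta_grid rotations (degrees) searched in the coarse stage.
#' @param coarse `"auto"` (coarse search only when the aligned frame explains
#'   < 25% of the template variance), `TRUE` (always) or `FALSE` (never).
#' @param confidence_threshold flag frames whose confidence falls below this.
#' @param smooth_sigma Gaussian smoothing SD (pixels) used during estimation;
#'   0 disables.
#' @param scale_factor integer downscaling factor for the estimation images
#'   (1 = full resolution). Estimated translations are rescaled to full
#'   resolution.
#' @param template_frames maximum effective number of frames averaged into
#'   the running template; the default (`Inf`) never forgets, which keeps the
#'   template anchored to the reference orientation. (Frames are z-scored
#'   before estimation, so photobleaching does not degrade the template.)
#' @param theta_penalty weight of a quadratic smoothness prior pulling each
#'   frame's rotation toward its neighbour's (z-scored MSE units per squared
#'   degree). Rotation is weakly identifiable in sparse scenes (a featureless
#'   nucleus is rotation-symmetric; few foci barely constrain it); the prior
#'   keeps the rotation trajectory from wandering there while leaving
#'   rotation-rich scenes essentially untouched. 0 disables.
#' @return data.frame of class `rigid_transforms` with one row per frame:
#'   `frame`, `dx`, `dy`, `theta` (mapping reference coordinates into that
#'   frame), `confidence`, `low_confidence`.
#' @export
estimate_rigid <- function(stack, reference_frame = 1L,
                           theta_grid = seq(-6, 6, by = 1),
                           coarse = "auto", confidence_threshold = 0.1,
                           smooth_sigma = 1.5, scale_factor = 2L,
                           template_frames = Inf, theta_penalty = 0.02) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nT <- n_frames(stack)
  if (nT < 2L) stop("need at least 2 frames")
  if (reference_frame < 1L || reference_frame > nT)
    stop("invalid reference frame")
  scale_factor <- max(1L, as.integer(scale_factor))
  d <- dim(stack$frames)
  if (scale_factor > 1L && any(d[1:2] %/% scale_factor < 16))
    scale_factor <- 1L

  sm <- lapply(seq_len(nT), function(t) {
    img <- EBImage::as.Image(stack$frames[, , t])
    if (smooth_sigma > 0) img <- EBImage::gblur(img, smooth_sigma)
    if (scale_factor > 1L) {
      img <- EBImage::resize(img, w = d[1] %/% scale_factor,
                             h = d[2] %/% scale_factor)
    }
    img <- EBImage::imageData(img)
    # z-score for estimation: removes the photobleaching scale change so the
    # template can average over the whole stack without forgetting
    s <- stats::sd(img)
    if (s > 1e-12) (img - mean(img)) / s else img
  })

  M <- vector("list", nT)
  conf <- rep(NA_real_, nT); degen <- rep(FALSE, nT)
  M[[reference_frame]] <- c(0, 0, 0)
  conf[reference_frame] <- 1
  tmpl <- sm[[reference_frame]]
  w <- 1
  order_out <- c(if (reference_frame < nT) (reference_frame + 1):nT,
                 if (reference_frame > 1L) (reference_frame - 1):1)
  inc <- c(0, 0, 0)
  for (t in order_out) {
    nb <- if (t > reference_frame) t - 1L else t + 1L
    if (t == reference_frame - 1L) inc <- c(0, 0, 0)  # switching direction
    init <- compose_rigid(M[[nb]], inc)
    half <- min(dim(sm[[t]])) / 2
    init[1:2] <- pmax(pmin(init[1:2], half), -half)
    init[3] <- max(min(init[3], 45), -45)
    est <- estimate_rigid_pair(tmpl, sm[[t]], init = init,
                               theta_grid = theta_grid, coarse = coarse,
                               reltol = 1e-5, maxit = 60,
                               theta_prior = M[[nb]][3],
                               theta_penalty = theta_penalty)
    M[[t]] <- est$par
    conf[t] <- est$confidence
    degen[t] <- est$degenerate
    if (degen[t]) M[[t]] <- M[[nb]]
    inc <- compose_rigid(invert_rigid(M[[nb]]), M[[t]])
    if (!degen[t]) {
      reg <- rigid_warp(sm[[t]], M[[t]][1], M[[t]][2], M[[t]][3],
                        fill = NA_real_)
      ok <- !is.na(reg)
      tmpl[ok] <- (w * tmpl[ok] + reg[ok]) / (w + 1)
      w <- min(w + 1, template_frames)
    }
  }
  m <- do.call(rbind, M)
  out <- data.frame(frame = seq_len(nT),
                    dx = m[, 1] * scale_factor,
                    dy = m[, 2] * scale_factor,
                    theta = m[, 3], confidence = conf,
                    low_confidence = degen |
                      (!is.na(conf) & conf < confidence_threshold))
  # the reference frame is trusted unless no other frame could be aligned
  out$low_confidence[reference_frame] <-
    all(out$low_confidence[-reference_frame])
  attr(out, "reference_frame") <- reference_frame
  class(out) <- c("rigid_transforms", "data.frame")
  out
}

#' Apply rigid transforms to register a stack
#'
#' Resamples every frame into the reference coordinates with bilinear
#' interpolation (`registered_t(p) = frame_t(M_t(p))`). Out-of-field pixels
#' are filled with the median border intensity of the frame. Image
#' dimensions are preserved; identity transforms return the input bit-exactly.
#'
#' @param stack a `timelapse_stack`.
#' @param transforms a `rigid_transforms` data.frame (one row per frame).
#' @return the registered `timelapse_stack`.
#' @export
apply_rigid <- function(stack, transforms) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nT <- n_frames(stack)
  if (nrow(transforms) != nT)
    stop("transform count does not match frame count")
  out <- stack
  for (t in seq_len(nT)) {
    tr <- transforms[t, ]
    if (tr$dx == 0 && tr$dy == 0 && tr$theta == 0) next
    img <- stack$frames[, , t]
    fill <- stats::median(c(img[1, ], img[nrow(img), ],
                            img[, 1], img[, ncol(img)]))
    out$frames[, , t] <- rigid_warp(img, tr$dx, tr$dy, tr$theta, fill = fill)
  }
  out
}

#' Read / write rigid transforms as CSV
#'
#' @param transforms a `rigid_transforms` data.frame.
#' @param path CSV file path.
#' @return `write_transforms` returns `path` invisibly; `read_transforms` the
#'   `rigid_transforms` data.frame.
#' @export
write_transforms <- function(transforms, path) {
  utils::write.csv(as.data.frame(transforms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("rigid_transforms", "data.frame")
  out
}
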