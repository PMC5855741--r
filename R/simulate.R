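#' Mean foci-per-cell anchor profile
#'
#' Smooth mean foci-per-cell (FPC) curve through three anchor values: the
#' initial level, a peak at `t_peak`, and the final level. The curve is a
#' piecewise cubic Hermite: the rising segment starts at the secant slope and
#' flattens to zero slope at the peak; the declining (or plateau) segment has
#' zero slope at both ends, so the curve never overshoots its anchors and the
#' maximum sits exactly at `t_peak`. A flat profile (all anchors equal)
#' reproduces the constant control level.
#'
#' @param t_min time points, minutes.
#' @param anchors list with `initial`, `peak`, `t_peak`, `final`.
#' @param t_final time (min) at which the `final` anchor applies.
#' @return numeric vector of mean FPC values at `t_min`.
#' @export
#' @examples
#' fpc_profile(c(0, 16, 75), list(initial = 9.7, peak = 15.3, t_peak = 16,
#'                                final = 8.7))
fpc_profile <- function(t_min, anchors, t_final = 75) {
  a <- anchors
  stopifnot(a$t_peak >= 0, t_final > a$t_peak)
  if (a$initial == a$peak && a$peak == a$final) {
    return(rep(a$peak, length(t_min)))
  }
  out <- numeric(length(t_min))
  rising <- t_min <= a$t_peak & a$t_peak > 0
  if (any(rising)) {
    m0 <- (a$peak - a$initial) / a$t_peak
    out[rising] <- cubic_hermite(t_min[rising], 0, a$t_peak,
                                 a$initial, a$peak, m0, 0)
  }
  decl <- !rising
  if (any(decl)) {
    tt <- pmin(t_min[decl], t_final)
    out[decl] <- cubic_hermite(tt, a$t_peak, t_final, a$peak, a$final, 0, 0)
  }
  out
}

# cubic Hermite segment on [x0, x1] with end values y0, y1 and slopes m0, m1
cubic_hermite <- function(t, x0, x1, y0, y1, m0, m1) {
  h <- x1 - x0
  s <- (t - x0) / h
  (2 * s^3 - 3 * s^2 + 1) * y0 + (s^3 - 2 * s^2 + s) * h * m0 +
    (-2 * s^3 + 3 * s^2) * y1 + (s^3 - s^2) * h * m1
}

#' Simulate confined random-walk focus trajectories
#'
#' Trajectories follow a stationary Ornstein--Uhlenbeck (OU) process per
#' dimension, parameterised so the ensemble mean square displacement equals
#' the confined-diffusion model [msd_model()] exactly in expectation:
#' per-dimension stationary SD `rc/2` and relaxation time
#' `rc^2 / (2 * d * Dc)` with `d = 2`. Initial positions are drawn from the
#' stationary distribution around each track's anchor. With `Dc = 0` the
#' relaxation time is infinite and tracks are frozen at their initial
#' position.
#'
#' @param n_tracks number of trajectories.
#' @param config a [sim_config()]; uses `Dc_true`, `rc_true`,
#'   `frame_interval`, `nucleus_radius`.
#' @param n_frames trajectory length in frames.
#' @param anchors optional `n_tracks x 2` matrix of anchor positions
#'   (micrometres, nucleus-centred); default uniform in the nucleus disc with
#'   a `3 * rc/2` margin.
#' @param constrain_to_nucleus project positions onto the nucleus disc.
#' @param set_seed seed the generator from `config$seed` before simulating.
#' @return list of `n_frames x 2` matrices (columns x, y in micrometres),
#'   with the anchor matrix attached as attribute `"anchors"`.
#' @export
simulate_confined_tracks <- function(n_tracks, config,
                                     n_frames = config$n_frames,
                                     anchors = NULL,
                                     constrain_to_nucleus = TRUE,
                                     set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_tracks >= 1, n_frames >= 1)
  if (config$rc_true <= 0) stop("rc_true must be > 0")
  if (config$Dc_true < 0) stop("Dc_true must be >= 0")
  if (set_seed) set.seed(config$seed)

  sigma <- config$rc_true / 2
  alpha <- ou_decay(config$Dc_true, config$rc_true, config$frame_interval)
  R <- config$nucleus_radius

  if (is.null(anchors)) {
    anchors <- runif_disc(n_tracks, max(R - 3 * sigma, 0))
  }
  stopifnot(nrow(anchors) == n_tracks)

  X <- matrix(0, n_frames, n_tracks)
  Y <- matrix(0, n_frames, n_tracks)
  X[1, ] <- rnorm(n_tracks, 0, sigma)
  Y[1, ] <- rnorm(n_tracks, 0, sigma)
  innov_sd <- sigma * sqrt(1 - alpha^2)
  if (n_frames > 1) {
    for (t in 2:n_frames) {
      X[t, ] <- alpha * X[t - 1, ] + rnorm(n_tracks, 0, innov_sd)
      Y[t, ] <- alpha * Y[t - 1, ] + rnorm(n_tracks, 0, innov_sd)
    }
  }
  X <- sweep(X, 2, anchors[, 1], `+`)
  Y <- sweep(Y, 2, anchors[, 2], `+`)
  if (constrain_to_nucleus) {
    r <- sqrt(X^2 + Y^2)
    over <- r > R
    if (any(over)) {
      shrink <- R / r[over]
      X[over] <- X[over] * shrink
      Y[over] <- Y[over] * shrink
    }
  }
  out <- lapply(seq_len(n_tracks), function(i) {
    cbind(x = X[, i], y = Y[, i])
  })
  attr(out, "anchors") <- anchors
  out
}

# OU autoregressive coefficient per frame; Dc = 0 gives a frozen process
ou_decay <- function(Dc, rc, dt, d = 2) {
  if (Dc == 0) return(1)
  tau <- rc^2 / (2 * d * Dc)
  exp(-dt / tau)
}

# uniform points in a disc of radius R centred at the origin
runif_disc <- function(n, R) {
  r <- R * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(phi), y = r * sin(phi))
}

#' Sample focus anchor positions with a minimum pairwise separation
#'
#' Dart-throwing sampler: points uniform in a disc of radius `R` centred at
#' the origin, subject to a minimum pairwise distance. This is the seeding
#' rule used by [simulate_scene()], reflecting that distinct foci are
#' optically resolvable; pass its result as the `anchors` argument of
#' [simulate_confined_tracks()] to reproduce that geometry. The constraint is
#' abandoned for a point after `max_tries` rejections, so overly dense
#' requests degrade gracefully instead of looping forever.
#'
#' @param n number of anchors.
#' @param R disc radius (µm).
#' @param min_sep minimum pairwise distance (µm); `<= 0` disables the
#'   constraint.
#' @param max_tries rejection attempts per point before giving up.
#' @return an `n x 2` matrix with columns `x`, `y` (µm).
#' @export
sample_anchors <- function(n, R, min_sep, max_tries = 200L) {
  a <- runif_disc(n, R)
  if (min_sep <= 0 || n < 2) return(a)
  for (i in 2:n) {
    tries <- 0L
    while (tries < max_tries) {
      d2 <- (a[1:(i - 1), 1] - a[i, 1])^2 + (a[1:(i - 1), 2] - a[i, 2])^2
      if (min(d2) >= min_sep^2) break
      a[i, ] <- runif_disc(1, R)
      tries <- tries + 1L
    }
  }
  a
}

#' Simulate per-frame focus counts as a birth--death process
#'
#' Realises focus appearance and decay so that the expected count follows the
#' condition's anchor profile [fpc_profile()]. With per-focus death rate
#' `mu = 1 / focus_lifetime_mean`, the time-varying birth rate is set to
#' `b(t) = max(0, m'(t) + mu * m(t))`, which makes the expectation of the
#' immigration--death process track the target mean `m(t)`. The initial count
#' is Poisson with mean `m(0)`.
#'
#' @param config a [sim_config()].
#' @param birth_rate optional constant birth rate (foci/min) overriding the
#'   profile-derived rate.
#' @param initial_foci optional fixed initial focus count (instead of a
#'   Poisson draw).
#' @param set_seed seed the generator from `config$seed`.
#' @return object of class `sim_kinetics`: list with `counts` (integer
#'   per-frame focus count), `foci` (data.frame `id`, `birth`, `death` in
#'   frame indices), `profile` (target mean per frame) and `minutes`.
#' @export
simulate_kinetics <- function(config, birth_rate = NULL, initial_foci = NULL,
                              set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  nT <- config$n_frames
  dt <- config$frame_interval
  minutes <- (seq_len(nT) - 1) * dt
  m <- fpc_profile(minutes, config$kinetics_anchors)
  mu <- 1 / config$focus_lifetime_mean

  if (is.null(birth_rate)) {
    dm <- c(diff(m) / dt, 0)
    b <- pmax(0, dm + mu * m)
  } else {
    b <- rep(birth_rate, nT)
  }

  n0 <- if (is.null(initial_foci)) rpois(1, m[1]) else as.integer(initial_foci)
  birth <- rep(1L, n0)
  death <- rep(NA_integer_, n0)
  alive <- seq_len(n0)
  p_die <- 1 - exp(-mu * dt)

  for (t in seq_len(nT - 1L)) {
    if (length(alive) > 0 && p_die > 0) {
      dies <- runif(length(alive)) < p_die
      death[alive[dies]] <- t
      alive <- alive[!dies]
    }
    nb <- rpois(1, b[t] * dt)
    if (nb > 0) {
      new_ids <- length(birth) + seq_len(nb)
      birth <- c(birth, rep(t + 1L, nb))
      death <- c(death, rep(NA_integer_, nb))
      alive <- c(alive, new_ids)
    }
  }
  death[is.na(death)] <- nT
  foci <- data.frame(id = seq_along(birth), birth = birth, death = death)
  counts <- vapply(seq_len(nT), function(t) {
    sum(foci$birth <= t & foci$death >= t)
  }, integer(1))
  structure(list(counts = counts, foci = foci, profile = m,
                 minutes = minutes),
            class = "sim_kinetics")
}

#' Assemble the ground-truth scene for one synthetic nucleus
#'
#' Combines the birth--death kinetics with confined OU motion, schedules
#' merge and split events, and records the per-frame rigid drift of the whole
#' nucleus. Merges replace two nearby parent foci by one child focus at their
#' amplitude-weighted midpoint with summed amplitude; splits replace a parent
#' by two children thrown apart symmetrically. Events are instantaneous, so
#' the ground-truth event log coincides frame-exactly with the topological
#' changes of the rendered label sequence at zero noise. Foci created by an
#' event inherit the remaining scheduled lifetime of their parents.
#'
#' @param config a [sim_config()].
#' @param merge_radius maximum parent separation (micrometres) for a merge.
#' @param split_offset half-distance (micrometres) between split children;
#'   freshly split children emerge adjacent, still inside the parent's
#'   rendered footprint.
#' @param set_seed seed the generator from `config$seed`.
#' @return object of class `sim_scene`: list with `foci` (id, birth, death,
#'   amplitude, origin), `positions` (data.frame `frame`, `id`, `x`, `y` in
#'   nucleus-centred micrometres), `events` (data.frame `type`, `frame`,
#'   `parents`, `children`), `transforms` (one rigid transform per frame),
#'   `counts`, and the `config`.
#' @export
simulate_scene <- function(config, merge_radius = 1.5,
                           split_offset = 0.7, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  kin <- simulate_kinetics(config, set_seed = FALSE)
  nT <- config$n_frames
  dt <- config$frame_interval
  sigma <- config$rc_true / 2
  R <- config$nucleus_radius

  foci <- kin$foci
  n <- nrow(foci)
  foci$amplitude <- rlnorm(n, meanlog = log(config$spot_amplitude), sdlog = 0.2)
  foci$origin <- rep("birth", n)
  anchors <- sample_anchors(n, max(R - 3 * sigma, 0), config$min_separation)

  # per-focus OU positions over the alive span; pos[[id]] row k = frame birth+k-1
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    pos[[i]] <- ou_path(foci$death[i] - foci$birth[i] + 1L, anchors[i, ],
                        sigma, config, R)
  }

  events <- list()
  p_merge <- 1 - exp(-config$merge_rate * dt)
  p_split <- 1 - exp(-config$split_rate * dt)

  f <- 1L
  while (f < nT) {
    alive <- which(foci$birth <= f & foci$death > f)
    consumed <- integer(0)
    if (length(alive) >= 2 && p_merge > 0) {
      initiators <- alive[runif(length(alive)) < p_merge]
      for (i in initiators) {
        if (i %in% consumed) next
        others <- setdiff(alive, c(i, consumed))
        if (length(others) == 0) next
        p_i <- focus_pos(pos, foci, i, f)
        po <- t(vapply(others, function(j) focus_pos(pos, foci, j, f),
                       numeric(2)))
        dists <- sqrt(rowSums(sweep(po, 2, p_i)^2))
        j <- others[which.min(dists)]
        if (min(dists) > merge_radius) next
        # fuse i and j into a new child at the amplitude-weighted midpoint
        wi <- foci$amplitude[i]; wj <- foci$amplitude[j]
        pj <- focus_pos(pos, foci, j, f)
        child_start <- (wi * p_i + wj * pj) / (wi + wj)
        child_death <- max(foci$death[i], foci$death[j])
        foci$death[c(i, j)] <- f
        cid <- nrow(foci) + 1L
        foci <- rbind(foci, data.frame(
          id = cid, birth = f + 1L, death = child_death,
          amplitude = wi + wj, origin = "merge"))
        pos[[cid]] <- ou_path(child_death - f, child_start, sigma, config, R,
                              start_at_anchor = TRUE)
        events[[length(events) + 1L]] <- data.frame(
          type = "merging", frame = f + 1L,
          parents = paste(c(i, j), collapse = ","),
          children = as.character(cid))
        consumed <- c(consumed, i, j)
      }
    }
    alive <- which(foci$birth <= f & foci$death > f & !(foci$id %in% consumed))
    if (length(alive) >= 1 && p_split > 0) {
      splitters <- alive[runif(length(alive)) < p_split]
      for (i in splitters) {
        p_i <- focus_pos(pos, foci, i, f)
        phi <- runif(1, 0, 2 * pi)
        off <- split_offset * c(cos(phi), sin(phi))
        child_death <- foci$death[i]
        foci$death[i] <- f
        cids <- nrow(foci) + (1:2)
        foci <- rbind(foci, data.frame(
          id = cids, birth = f + 1L, death = child_death,
          amplitude = foci$amplitude[i] / 2, origin = "split"))
        # children are born adjacent (split_offset) but relax toward home
        # positions far enough apart to stay optically resolvable
        aoff <- max(split_offset, config$min_separation / 2) *
          c(cos(phi), sin(phi))
        pos[[cids[1]]] <- ou_path(child_death - f, clamp_disc(p_i + aoff, R),
                                  sigma, config, R,
                                  start = clamp_disc(p_i + off, R))
        pos[[cids[2]]] <- ou_path(child_death - f, clamp_disc(p_i - aoff, R),
                                  sigma, config, R,
                                  start = clamp_disc(p_i - off, R))
        events[[length(events) + 1L]] <- data.frame(
          type = "splitting", frame = f + 1L,
          parents = as.character(i),
          children = paste(cids, collapse = ","))
      }
    }
    f <- f + 1L
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), frame = integer(0),
               parents = character(0), children = character(0))
  events <- events[order(events$frame), , drop = FALSE]
  # a merge whose fused child later splits is a merging-and-splitting pair
  if (nrow(events)) {
    merged_children <- events$children[events$type == "merging"]
    ms <- events$type == "splitting" & events$parents %in% merged_children
    events$type[events$type == "merging" &
                  events$children %in% events$parents[ms]] <-
      "merging_and_splitting"
    events$type[ms] <- "merging_and_splitting_resolution"
  }

  # a quiet nucleus (no foci at all) is a legitimate control outcome
  positions <- if (nrow(foci) == 0) {
    data.frame(frame = integer(0), id = integer(0),
               x = numeric(0), y = numeric(0))
  } else {
    do.call(rbind, lapply(seq_len(nrow(foci)), function(i) {
      frames <- foci$birth[i]:foci$death[i]
      # events may shorten a focus's life after its path was generated
      data.frame(frame = frames, id = foci$id[i],
                 x = pos[[i]][seq_along(frames), 1],
                 y = pos[[i]][seq_along(frames), 2])
    }))
  }
  positions <- positions[order(positions$frame, positions$id), ]
  rownames(positions) <- NULL

  counts <- vapply(seq_len(nT), function(t) {
    sum(foci$birth <= t & foci$death >= t)
  }, integer(1))

  drift <- config$nucleus_drift
  transforms <- data.frame(
    frame = seq_len(nT),
    dx = (seq_len(nT) - 1) * drift[1],
    dy = (seq_len(nT) - 1) * drift[2],
    theta = (seq_len(nT) - 1) * drift[3])

  structure(list(foci = foci, positions = positions, events = events,
                 transforms = transforms, counts = counts, config = config),
            class = "sim_scene")
}

# OU path of given length anchored at `anchor`; positions clipped to the
# nucleus disc of radius R. `start` pins the first position (e.g. a child
# focus born at its parent's location but relaxing toward its own anchor);
# the default draws it from the stationary distribution around the anchor.
ou_path <- function(len, anchor, sigma, config, R, start_at_anchor = FALSE,
                    start = NULL) {
  alpha <- ou_decay(config$Dc_true, config$rc_true, config$frame_interval)
  x <- numeric(len); y <- numeric(len)
  if (!is.null(start)) {
    x[1] <- start[1] - anchor[1]; y[1] <- start[2] - anchor[2]
  } else if (start_at_anchor) {
    x[1] <- 0; y[1] <- 0
  } else {
    x[1] <- rnorm(1, 0, sigma); y[1] <- rnorm(1, 0, sigma)
  }
  innov_sd <- sigma * sqrt(1 - alpha^2)
  if (len > 1) {
    for (t in 2:len) {
      x[t] <- alpha * x[t - 1] + rnorm(1, 0, innov_sd)
      y[t] <- alpha * y[t - 1] + rnorm(1, 0, innov_sd)
    }
  }
  p <- cbind(x + anchor[1], y + anchor[2])
  r <- sqrt(rowSums(p^2))
  over <- r > R
  if (any(over)) p[over, ] <- p[over, , drop = FALSE] * (R / r[over])
  p
}

focus_pos <- function(pos, foci, id, frame) {
  pos[[id]][frame - foci$birth[id] + 1L, ]
}

clamp_disc <- function(p, R) {
  r <- sqrt(sum(p^2))
  if (r > R) p * (R / r) else p
}

#' Render a synthetic scene into a time-lapse image stack
#'
#' Each live focus is drawn as a 2D Gaussian of width `spot_sigma` on the
#' nuclear disc background. The whole noiseless frame is multiplied by the
#' linear bleaching factor `(base_intensity - bleach_slope * t) /
#' base_intensity`, the per-frame rigid drift is applied exactly (foci and
#' nucleus are rendered directly at their transformed coordinates, so the
#' generator introduces no interpolation), and Poisson shot noise plus
#' additive Gaussian read noise are applied last. Foci whose centre falls
#' outside the field of view are clipped and flagged in the returned scene.
#'
#' @param scene a `sim_scene` from [simulate_scene()].
#' @param config a [sim_config()] (defaults to `scene$config`).
#' @return list with `stack` (a `timelapse_stack`) and `scene` (the input
#'   scene with image-coordinate columns `x_img`, `y_img` and a `clipped`
#'   flag added to `positions`).
#' @export
render_stack <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "sim_scene"))
  nT <- config$n_frames
  sz <- config$image_size
  px <- config$pixel_size
  ctr <- (sz + 1) / 2
  R_px <- config$nucleus_radius / px
  sig_px <- config$spot_sigma / px
  win <- ceiling(4 * sig_px)

  xs <- matrix(seq_len(sz), sz, sz, byrow = TRUE)  # column index
  ys <- matrix(seq_len(sz), sz, sz)                # row index

  frames <- array(0, dim = c(sz, sz, nT))
  pos <- scene$positions
  pos$x_img <- rep(NA_real_, nrow(pos))
  pos$y_img <- rep(NA_real_, nrow(pos))
  pos$clipped <- rep(FALSE, nrow(pos))
  amp <- scene$foci$amplitude[match(pos$id, scene$foci$id)]

  for (t in seq_len(nT)) {
    tr <- scene$transforms[t, ]
    th <- tr$theta * pi / 180
    cth <- cos(th); sth <- sin(th)
    # nucleus disc, drawn at its drifted position (inverse-map the pixel grid)
    qx <- xs - ctr - tr$dx
    qy <- ys - ctr - tr$dy
    pxb <- cth * qx + sth * qy
    pyb <- -sth * qx + cth * qy
    inside <- (pxb^2 + pyb^2) <= R_px^2
    img <- matrix(config$background_outside, sz, sz)
    img[inside] <- config$background_nucleus

    rows <- which(pos$frame == t)
    for (k in rows) {
      # nucleus-frame um -> nucleus-frame px -> drifted image px
      ux <- pos$x[k] / px
      uy <- pos$y[k] / px
      ix <- ctr + cth * ux - sth * uy + tr$dx
      iy <- ctr + sth * ux + cth * uy + tr$dy
      pos$x_img[k] <- ix; pos$y_img[k] <- iy
      if (ix < 1 || ix > sz || iy < 1 || iy > sz) pos$clipped[k] <- TRUE
      c0 <- max(1L, floor(ix) - win); c1 <- min(sz, ceiling(ix) + win)
      r0 <- max(1L, floor(iy) - win); r1 <- min(sz, ceiling(iy) + win)
      if (c0 > c1 || r0 > r1) next
      cc <- c0:c1; rr <- r0:r1
      g <- amp[k] * exp(-(outer((rr - iy)^2, (cc - ix)^2, `+`)) /
                          (2 * sig_px^2))
      img[rr, cc] <- img[rr, cc] + g
    }

    minute <- (t - 1) * config$frame_interval
    img <- img * (config$base_intensity - config$bleach_slope * minute) /
      config$base_intensity

    if (config$shot_noise) {
      img[] <- rpois(length(img), pmax(img, 0))
    }
    if (config$read_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, config$read_noise_sd)
    }
    frames[, , t] <- pmax(img, 0)
  }

  scene$positions <- pos
  stack <- timelapse_stack(frames, pixel_size = px,
                           frame_interval = config$frame_interval,
                           condition = config$condition)
  list(stack = stack, scene = scene)
}

#' Simulate one synthetic nucleus end to end
#'
#' Seeds the generator once from `config$seed`, assembles the ground-truth
#' scene and renders the image stack. Two calls with the same configuration
#' produce bit-identical stacks.
#'
#' @param config a [sim_config()].
#' @param ... passed to [simulate_scene()].
#' @return list with `stack` (a `timelapse_stack`) and `truth` (the
#'   `sim_scene` including image coordinates and clip flags).
#' @export
#' @examples
#' sim <- simulate_nucleus(sim_config("control", n_frames = 5, seed = 2))
#' dim(sim$stack$frames)
simulate_nucleus <- function(config, ...) {
  set.seed(config$seed)
  scene <- simulate_scene(config, set_seed = FALSE, ...)
  rendered <- render_stack(scene, config)
  list(stack = rendered$stack, truth = rendered$scene)
}

#' Convert simulated trajectories to a track table
#'
#' @param trajectories list of `n_frames x 2` matrices as returned by
#'   [simulate_confined_tracks()].
#' @param frame_interval minutes per frame.
#' @return data.frame with `track_id`, `frame`, `x`, `y` (micrometres) and an
#'   `excluded` flag (all `FALSE`), suitable for [compute_msd()].
#' @export
as_track_df <- function(trajectories, frame_interval = 1) {
  out <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    m <- trajectories[[i]]
    data.frame(track_id = i, frame = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2])
  }))
  out$excluded <- FALSE
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Write ground truth to plain-text files
#'
#' Positions go to CSV (`frame`, `id`, `x_um`, `y_um`, plus image coordinates
#' when rendered), the event log to JSON, and the per-frame rigid transforms
#' to CSV.
#'
#' @param scene a `sim_scene`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(scene, dir) {
  stopifnot(inherits(scene, "sim_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "positions.csv")
  p2 <- file.path(dir, "events.json")
  p3 <- file.path(dir, "transforms.csv")
  utils::write.csv(scene$positions, p1, row.names = FALSE)
  jsonlite::write_json(scene$events, p2, dataframe = "rows")
  utils::write.csv(scene$transforms, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
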