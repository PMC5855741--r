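# configuration with imaging noise and whole-nucleus drift switched off:
# ground-truth recovery oracles want the scene, not the camera
quiet_config <- function(condition, seed, ...) {
  sim_config(condition, seed = seed, shot_noise = FALSE, read_noise_sd = 0,
             nucleus_drift = c(0, 0, 0), ...)
}

# hand-built scene with a single static focus (rendering oracles)
static_scene <- function(cfg, x = 1.2, y = -0.8, amplitude = 180) {
  nT <- cfg$n_frames
  structure(list(
    foci = data.frame(id = 1L, birth = 1L, death = nT,
                      amplitude = amplitude, origin = "birth"),
    positions = data.frame(frame = seq_len(nT), id = 1L, x = x, y = y),
    events = data.frame(type = character(0), frame = integer(0),
                        parents = character(0), children = character(0)),
    transforms = data.frame(frame = seq_len(nT), dx = 0, dy = 0, theta = 0),
    counts = rep(1L, nT), config = cfg), class = "sim_scene")
}

# nucleus disc with optional Gaussian spots (positions in micrometres,
# image-centred), rendered deterministically
disc_frame <- function(sz = 128, px = 0.16, radius_um = 7.5, spots = NULL,
                       amplitude = 180, spot_sigma = 0.35, bg_in = 45,
                       bg_out = 5, centre = c(0, 0)) {
  img <- matrix(bg_out, sz, sz)
  ctr <- (sz + 1) / 2
  rr <- row(img); cc <- col(img)
  cy <- ctr + centre[2] / px; cx <- ctr + centre[1] / px
  img[((rr - cy)^2 + (cc - cx)^2) <= (radius_um / px)^2] <- bg_in
  if (!is.null(spots)) {
    sig <- spot_sigma / px
    for (i in seq_len(nrow(spots))) {
      iy <- ctr + spots[i, 2] / px
      ix <- ctr + spots[i, 1] / px
      img <- img + amplitude * exp(-((rr - iy)^2 + (cc - ix)^2) / (2 * sig^2))
    }
  }
  img
}

# perfect detections table from simulated trajectories, carrying the
# ground-truth trajectory id in a `truth` column
tracks_from_truth <- function(trajs) {
  do.call(rbind, lapply(seq_along(trajs), function(i) {
    m <- trajs[[i]]
    data.frame(frame = seq_len(nrow(m)), label = i,
               x = m[, 1], y = m[, 2], truth = i)
  }))
}

# correct and total within-track links against the `truth` column
link_counts <- function(tracks) {
  ord <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[ord]
  gt <- tracks$truth[ord]
  same <- tid[-1] == tid[-length(tid)]
  c(correct = sum(gt[-1][same] == gt[-length(gt)][same]), total = sum(same))
}

# label-matrix sequence with two blobs that fuse over [fuse_from, fuse_to]
# (1-based frames, inclusive); outside that window the two blobs are apart
fusion_labels <- function(nT, fuse_from, fuse_to, sz = 24L) {
  apart <- matrix(0L, sz, sz)
  apart[10:12, 4:6] <- 1L
  apart[10:12, 16:18] <- 2L
  fused <- matrix(0L, sz, sz)
  fused[10:12, 4:18] <- 1L
  lapply(seq_len(nT), function(t) {
    if (t >= fuse_from && t <= fuse_to) fused else apart
  })
}

# per-frame centroid detections derived from a label sequence
dets_from_labels <- function(labs, px = 0.16) {
  out <- lapply(seq_along(labs), function(t) {
    l <- labs[[t]]
    ids <- sort(unique(l[l > 0]))
    if (length(ids) == 0) return(NULL)
    ctr <- (nrow(l) + 1) / 2
    data.frame(frame = t, label = ids,
               x = vapply(ids, function(i) (mean(col(l)[l == i]) - ctr) * px,
                          numeric(1)),
               y = vapply(ids, function(i) (mean(row(l)[l == i]) - ctr) * px,
                          numeric(1)))
  })
  do.call(rbind, out)
}

# event-type counts in a fixed order
event_counts <- function(events) {
  vapply(c("merging", "splitting", "merging_and_splitting"),
         function(k) sum(events$type == k), integer(1))
}
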