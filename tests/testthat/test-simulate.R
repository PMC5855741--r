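test_that("sim_config validates its parameters", {
  expect_error(sim_config("control", n_frames = 1), "n_frames")
  expect_error(sim_config("control", rc_true = 0), "rc_true")
  expect_error(sim_config("control", Dc_true = -0.01), "Dc_true")
  expect_error(sim_config("control", merge_rate = -0.1), "rates")
  expect_error(sim_config("control", min_separation = -1), "min_separation")
  expect_error(sim_config("control", bleach_slope = 10), "bleach")
  expect_error(sim_config("gamma"))

  cfg <- sim_config("xray", seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$kinetics_anchors$peak, 15.3)
  expect_output(print(cfg), "xray")

  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  # YAML serialises doubles at reduced precision
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-6)
})

test_that("confined tracks: frozen, free-diffusion and stationary behaviour", {
  # Dc = 0: every trajectory constant over time
  cfg0 <- sim_config("control", Dc_true = 0, rc_true = 0.5, seed = 1)
  frz <- simulate_confined_tracks(5, cfg0, n_frames = 10)
  for (tr in frz) expect_equal(max(abs(apply(tr, 2, diff))), 0)

  # rc >> range: MSD at the first lag approaches free diffusion 2*d*Dc*dt
  cfgf <- sim_config("control", Dc_true = 0.01, rc_true = 50,
                     n_frames = 5, seed = 3)
  trf <- simulate_confined_tracks(2000, cfgf, constrain_to_nucleus = FALSE)
  mf <- compute_msd(as_track_df(trf), max_lag = 1)
  expect_lte(abs(mf$msd[1] - 2 * 2 * 0.01 * 1) / (2 * 2 * 0.01), 0.05)

  # constrained trajectories never leave the nucleus disc
  cfgc <- sim_config("control", seed = 5, n_frames = 30)
  trc <- simulate_confined_tracks(50, cfgc)
  rmax <- max(vapply(trc, function(m) max(sqrt(rowSums(m^2))), numeric(1)))
  expect_lte(rmax, cfgc$nucleus_radius + 1e-9)

  expect_error(simulate_confined_tracks(2, sim_config("control"), anchors = cbind(0, 0)))
})

test_that("simulate_kinetics realises the anchor profiles", {
  # no births, no deaths: the count stays at the initial value
  cfg <- sim_config("control", seed = 2, focus_lifetime_mean = Inf)
  kin <- simulate_kinetics(cfg, birth_rate = 0, initial_foci = 3)
  expect_equal(kin$counts, rep(3L, cfg$n_frames))

  # control long-run mean ~ 1.5 foci per cell
  cc <- vapply(1:40, function(i)
    mean(simulate_kinetics(sim_config("control", seed = 200 + i))$counts),
    numeric(1))
  expect_lte(abs(mean(cc) - 1.5), 0.35)

  # X-ray-like profile peaks within +-3 min of 16 on the 25-nucleus average
  cnts <- vapply(1:25, function(i)
    simulate_kinetics(sim_config("xray", seed = 100 + i))$counts,
    integer(sim_config("xray")$n_frames))
  peak_minute <- which.max(rowMeans(cnts)) - 1
  expect_lte(abs(peak_minute - 16), 3)
})

test_that("scene assembly keeps its invariants", {
  cfg <- quiet_config("alpha", seed = 11)
  scene <- simulate_scene(cfg)
  expect_false(is.unsorted(scene$events$frame))
  expect_equal(nrow(scene$transforms), cfg$n_frames)
  expect_equal(unlist(scene$transforms[1, c("dx", "dy", "theta")]),
               c(dx = 0, dy = 0, theta = 0))
  expect_lte(max(sqrt(scene$positions$x^2 + scene$positions$y^2)),
             cfg$nucleus_radius + 1e-9)
  expect_equal(length(scene$counts), cfg$n_frames)
  expect_true(all(scene$counts >= 0))
  # per-frame true counts agree with the birth/death table
  t10 <- sum(scene$foci$birth <= 10 & scene$foci$death >= 10)
  expect_equal(scene$counts[10], t10)
})

test_that("rendering places, bleaches and clips foci as configured", {
  cfg <- quiet_config("control", seed = 1, n_frames = 76, Dc_true = 0)
  r <- render_stack(static_scene(cfg), cfg)
  ctr <- (cfg$image_size + 1) / 2
  ix <- ctr + 1.2 / cfg$pixel_size
  iy <- ctr - 0.8 / cfg$pixel_size
  for (t in c(1, 40, 76)) {
    k <- which.max(r$stack$frames[, , t])
    row_t <- (k - 1) %% cfg$image_size + 1
    col_t <- (k - 1) %/% cfg$image_size + 1
    expect_lte(max(abs(c(row_t - iy, col_t - ix))), 1)
  }
  # multiplicative linear bleaching: minute-75 / minute-0 peak = 104.6/139.3
  ratio <- max(r$stack$frames[, , 76]) / max(r$stack$frames[, , 1])
  expect_equal(ratio, 104.6 / 139.3, tolerance = 1e-10)

  # a focus rendered outside the field of view is flagged as clipped
  r2 <- render_stack(static_scene(cfg, x = 15, y = 0), cfg)
  expect_true(all(r2$scene$positions$clipped))

  # two runs with the same configuration are bit-identical
  cfg3 <- sim_config("xray", seed = 9, n_frames = 6)
  s1 <- simulate_nucleus(cfg3)
  s2 <- simulate_nucleus(cfg3)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth$positions, s2$truth$positions)
})

test_that("ground truth writes to plain-text files", {
  cfg <- quiet_config("xray", seed = 2, n_frames = 5)
  sim <- simulate_nucleus(cfg)
  dir <- tempfile()
  paths <- write_ground_truth(sim$truth, dir)
  expect_true(all(file.exists(paths)))
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  expect_equal(nrow(pos), nrow(sim$truth$positions))
})
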