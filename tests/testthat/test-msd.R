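test_that("msd_model evaluates the confined-diffusion closed form", {
  expect_equal(msd_model(5, Dc = 0.01, rc = 0.5, d = 2),
               0.25 * (1 - exp(-0.8)))
  expect_lt(abs(msd_model(5, 0.01, 0.5, 2) - 0.1377), 5e-4)
  # plateau and small-lag limits
  expect_equal(msd_model(1e9, 0.01, 0.5), 0.25)
  dt <- 1e-8
  expect_equal(msd_model(dt, 0.01, 0.5) / (2 * 2 * 0.01 * dt), 1,
               tolerance = 1e-4)
  # monotone increasing, bounded by rc^2
  v <- msd_model(seq(0.5, 50, by = 0.5), 0.02, 0.6)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 0.36))
  expect_error(msd_model(1, 0.01, 0), "rc")
  expect_error(msd_model(1, 0.01, 0.5, d = 4), "d must")
})

test_that("compute_msd matches hand enumeration and a brute-force oracle", {
  # 3-frame track at (0,0), (1,0), (1,1)
  tr <- data.frame(track_id = 1, frame = 1:3, x = c(0, 1, 1), y = c(0, 0, 1))
  m <- compute_msd(tr, max_lag = 2)
  expect_equal(m$msd, c(1.0, 2.0))
  expect_equal(m$n_pairs, c(2L, 1L))
  expect_equal(m$lag, c(1, 2))

  # stationary track: zero at all lags
  st <- data.frame(track_id = 1, frame = 1:10, x = 2, y = -1)
  expect_true(all(compute_msd(st, max_lag = 5)$msd == 0))

  # ballistic track: MSD(dt) = (v dt)^2
  v <- 0.3
  bal <- data.frame(track_id = 1, frame = 1:20, x = v * (1:20), y = 0)
  mb <- compute_msd(bal, max_lag = 6)
  expect_equal(mb$msd, (v * mb$lag)^2, tolerance = 1e-12)

  # brute-force all-pairs oracle on random gapped 10-frame tracks
  set.seed(11)
  tracks <- do.call(rbind, lapply(1:4, function(i) {
    frames <- sort(sample(1:10, sample(5:10, 1)))
    data.frame(track_id = i, frame = frames,
               x = cumsum(rnorm(length(frames))),
               y = cumsum(rnorm(length(frames))))
  }))
  got <- compute_msd(tracks, max_lag = 9)
  for (k in seq_len(nrow(got))) {
    l <- got$lag[k]
    sq <- c(); n <- 0L
    for (i in unique(tracks$track_id)) {
      sub <- tracks[tracks$track_id == i, ]
      for (a in seq_len(nrow(sub))) {
        b <- which(sub$frame == sub$frame[a] + l)
        if (length(b) == 1) {
          sq <- c(sq, (sub$x[b] - sub$x[a])^2 + (sub$y[b] - sub$y[a])^2)
          n <- n + 1L
        }
      }
    }
    expect_equal(got$msd[k], mean(sq), tolerance = 1e-12)
    expect_equal(got$n_pairs[k], n)
  }
  # n_pairs non-increasing with lag on gap-free data
  full <- compute_msd(bal, max_lag = 10)
  expect_true(all(diff(full$n_pairs) <= 0))

  # excluded tracks are dropped; nothing left is an error
  tr$excluded <- TRUE
  expect_error(compute_msd(tr), "no valid tracks")
})

test_that("fit_confined inverts noiseless curves and flags identifiability", {
  cv <- data.frame(lag = 1:25, msd = msd_model(1:25, 0.02, 0.4),
                   n_pairs = 1000)
  f <- fit_confined(cv)
  expect_true(f$converged)
  expect_lte(abs(coef(f)[["Dc"]] / 0.02 - 1), 0.001)
  expect_lte(abs(coef(f)[["rc"]] / 0.4 - 1), 0.001)
  expect_false(f$warn_rc)
  expect_false(f$warn_Dc)

  # perfectly flat curve: rc = sqrt(c), Dc unidentified
  flat <- fit_confined(data.frame(lag = 1:10, msd = 0.25, n_pairs = 100))
  expect_equal(coef(flat)[["rc"]], 0.5, tolerance = 1e-6)
  expect_true(flat$warn_Dc)

  # steeply rising curve with no plateau inside the lag range
  steep <- fit_confined(data.frame(lag = 1:10,
                                   msd = msd_model(1:10, 0.05, 10),
                                   n_pairs = 100))
  expect_true(steep$warn_rc)

  expect_error(fit_confined(cv[1:3, ]), "4 lags")
})

test_that("confined_fit supports the standard modelling generics", {
  cv <- data.frame(lag = 1:20, msd = msd_model(1:20, 0.015, 0.5),
                   n_pairs = 500)
  f <- fit_confined(cv)
  expect_named(coef(f), c("Dc", "rc"))
  expect_equal(fitted(f), predict(f), tolerance = 1e-12)
  expect_equal(residuals(f), cv$msd - fitted(f))
  expect_equal(predict(f, newdata = data.frame(lag = 5)),
               msd_model(5, coef(f)["Dc"], coef(f)["rc"]),
               ignore_attr = TRUE)
  expect_output(print(f), "Dc")
  s <- summary(f)
  expect_s3_class(s, "summary.confined_fit")
  expect_output(print(s), "Confined-diffusion")
  sim <- simulate(f, nsim = 3, seed = 2, n_frames = 10)
  expect_length(sim, 3)
  expect_equal(dim(sim[[1]]), c(10L, 2L))
  pdf(NULL)
  expect_invisible(plot(f))
  dev.off()
})

test_that("parameter recovery bias shrinks with track count", {
  err <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config("control", Dc_true = 0.01, rc_true = 0.5, seed = s)
      trj <- simulate_confined_tracks(n, cfg, constrain_to_nucleus = FALSE)
      f <- fit_confined(compute_msd(as_track_df(trj)))
      abs(coef(f)[["Dc"]] - 0.01) / 0.01
    }, numeric(1)))
  }
  expect_lt(err(1500, 1:4), err(150, 1:4))
})
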