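test_that("link_tracks: basic linking behaviour", {
  expect_error(link_tracks(data.frame(), linking_radius = 0), "linking_radius")

  # one static detection per frame: exactly one track spanning the stack
  det <- data.frame(frame = 1:20, label = 1, x = 0.5, y = -0.5)
  lt <- link_tracks(det, linking_radius = 1)
  expect_equal(length(unique(lt$track_id)), 1)
  expect_equal(sum(lt$track_id == lt$track_id[1]), 20)

  # two distant foci: two tracks, no identity swaps
  det2 <- rbind(data.frame(frame = 1:10, label = 1, x = -3, y = 0),
                data.frame(frame = 1:10, label = 2, x = 3, y = 0))
  lt2 <- link_tracks(det2, linking_radius = 1)
  expect_equal(length(unique(lt2$track_id)), 2)
  expect_true(all(tapply(lt2$x, lt2$track_id,
                         function(v) length(unique(v))) == 1))

  # per-track frames strictly increase; links stay within the radius
  set.seed(8)
  cfg <- sim_config("control", Dc_true = 0.01, rc_true = 0.5, seed = 8)
  trj <- simulate_confined_tracks(10, cfg)
  lt3 <- link_tracks(tracks_from_truth(trj), linking_radius = 0.6)
  for (id in unique(lt3$track_id)) {
    sub <- lt3[lt3$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    expect_true(all(diff(sub$frame) >= 1))
    if (nrow(sub) > 1) {
      expect_true(all(sqrt(diff(sub$x)^2 + diff(sub$y)^2) <= 0.6 + 1e-9))
    }
  }

  # gaps up to max_gap are bridged
  detg <- data.frame(frame = c(1, 2, 5), label = 1, x = 0, y = 0)
  expect_equal(length(unique(link_tracks(detg, 1, max_gap = 2)$track_id)), 1)
  expect_equal(length(unique(link_tracks(detg, 1, max_gap = 1)$track_id)), 2)
})

test_that("classify_events recognises constructed merge/split scenarios", {
  run <- function(labs) {
    lt <- link_tracks(dets_from_labels(labs), linking_radius = 1.0)
    classify_events(lt, labs)
  }

  # two blobs fuse and stay fused: one merging event
  mg <- run(fusion_labels(6, fuse_from = 4, fuse_to = 6))
  expect_equal(event_counts(mg$events),
               c(merging = 1L, splitting = 0L, merging_and_splitting = 0L))
  expect_equal(mg$events$frame, 4L)
  expect_equal(length(strsplit(mg$events$parent_tracks, ",")[[1]]), 2)

  # one blob becomes two: one splitting event
  sp <- run(fusion_labels(6, fuse_from = 1, fuse_to = 3))
  expect_equal(event_counts(sp$events),
               c(merging = 0L, splitting = 1L, merging_and_splitting = 0L))
  expect_equal(length(strsplit(sp$events$child_tracks, ",")[[1]]), 2)

  # merge at frame 10, split of the fused focus at frame 30:
  # one merging_and_splitting event, no residual merge/split
  ms <- run(fusion_labels(40, fuse_from = 10, fuse_to = 29))
  expect_equal(event_counts(ms$events),
               c(merging = 0L, splitting = 0L, merging_and_splitting = 1L))

  # fused for a single frame: a sub-resolution pass, no event at all
  pass <- run(fusion_labels(8, fuse_from = 4, fuse_to = 4))
  expect_equal(nrow(pass$events), 0)

  # tracks touched by the merge are excluded with a recorded reason
  expect_true(any(mg$tracks$excluded))
  expect_true(all(!is.na(mg$tracks$reason[mg$tracks$excluded])))
})

test_that("event_rates computes participation fractions", {
  tracks <- data.frame(track_id = rep(1:20, each = 2),
                       frame = rep(1:2, 20))
  none <- data.frame(type = character(0), frame = integer(0),
                     parent_tracks = character(0),
                     child_tracks = character(0))
  er0 <- event_rates(none, tracks)
  expect_equal(er0$fraction, c(0, 0, 0))

  # 4 of 20 foci in merges: merge fraction 0.20
  ev <- data.frame(type = c("merging", "merging"), frame = c(3, 5),
                   parent_tracks = c("1,2", "3,4"),
                   child_tracks = c("2", "4"))
  er <- event_rates(ev, tracks)
  expect_equal(er$fraction[er$type == "merging"], 0.20)

  expect_warning(event_rates(none, tracks[0, ]), "no foci")

  agg <- aggregate_event_rates(list(er, er0, NULL))
  expect_equal(agg$n_nuclei[1], 2)
  expect_equal(agg$mean_fraction[agg$type == "merging"], 0.10)
})

test_that("merge and split counts swap exactly under time reversal", {
  for (s in c(3, 7)) {
    cfg <- quiet_config("xray", seed = s, merge_rate = 0.004,
                        split_rate = 0.004)
    sim <- simulate_nucleus(cfg)
    a <- analyze_stack(sim$stack, register = FALSE)
    nT <- n_frames(sim$stack)
    det_r <- a$detections
    det_r$frame <- nT + 1L - det_r$frame
    lt_r <- link_tracks(det_r, linking_radius = 1.0, max_gap = 2L)
    ev_r <- classify_events(lt_r, rev(a$labels))
    fwd <- event_counts(a$events)
    rev_ <- event_counts(ev_r$events)
    expect_equal(unname(rev_[c(2, 1, 3)]), unname(fwd))
    # every exclusion carries a justification
    expect_true(all(!is.na(a$tracks$reason[a$tracks$excluded])))
  }
})

test_that("tracks and events round-trip through files", {
  labs <- fusion_labels(6, 4, 6)
  lt <- link_tracks(dets_from_labels(labs), linking_radius = 1.0)
  ev <- classify_events(lt, labs)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".json")
  write_tracks(ev$tracks, ev$events, p1, p2)
  expect_equal(nrow(utils::read.csv(p1)), nrow(ev$tracks))
  ev_back <- jsonlite::fromJSON(p2)
  expect_equal(ev_back$type, ev$events$type)
})
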