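#' Link per-frame focus detections into tracks
#'
#' Greedy mutually-nearest-first assignment: for every frame, distances
#' between the current heads of open tracks and the new detections are
#' computed, and pairs are linked in order of increasing distance while the
#' distance stays within `linking_radius`. Unassigned detections start new
#' tracks; a track stays open for up to `max_gap` missing frames.
#'
#' @param detections data.frame with `frame`, `label`, `x`, `y` (micrometres)
#'   and any further per-focus columns, sorted or sortable by frame.
#' @param linking_radius maximum link displacement, micrometres (> 0).
#' @param max_gap maximum number of bridged missing frames.
#' @return data.frame of class `focus_tracks`: the detections plus
#'   `track_id`, `excluded` (FALSE) and `reason` (NA) columns.
#' @export
link_tracks <- function(detections, linking_radius, max_gap = 2L) {
  if (linking_radius <= 0) stop("linking_radius must be > 0")
  det <- detections[order(detections$frame), , drop = FALSE]
  n <- nrow(det)
  track_id <- rep(NA_integer_, n)
  if (n > 0) {
    last_x <- numeric(0); last_y <- numeric(0)
    last_frame <- integer(0); track_ids <- integer(0)
    next_id <- 1L
    for (f in sort(unique(det$frame))) {
      rows <- which(det$frame == f)
      open <- which(f - last_frame <= max_gap + 1L & last_frame < f)
      assigned_det <- rep(FALSE, length(rows))
      if (length(open) > 0) {
        dmat <- outer(last_x[open], det$x[rows], `-`)^2 +
          outer(last_y[open], det$y[rows], `-`)^2
        dmat <- sqrt(dmat)
        repeat {
          m <- which.min(dmat)
          if (length(m) == 0 || dmat[m] > linking_radius) break
          i <- (m - 1) %% length(open) + 1
          j <- (m - 1) %/% length(open) + 1
          tr <- open[i]
          track_id[rows[j]] <- track_ids[tr]
          last_x[tr] <- det$x[rows[j]]; last_y[tr] <- det$y[rows[j]]
          last_frame[tr] <- f
          assigned_det[j] <- TRUE
          dmat[i, ] <- Inf; dmat[, j] <- Inf
          if (all(is.infinite(dmat))) break
        }
      }
      for (j in which(!assigned_det)) {
        track_id[rows[j]] <- next_id
        last_x <- c(last_x, det$x[rows[j]])
        last_y <- c(last_y, det$y[rows[j]])
        last_frame <- c(last_frame, f)
        track_ids <- c(track_ids, next_id)
        next_id <- next_id + 1L
      }
    }
  }
  det$track_id <- track_id
  det$excluded <- rep(FALSE, n)
  det$reason <- rep(NA_character_, n)
  class(det) <- c("focus_tracks", "data.frame")
  det
}

# qualifying label-overlap links between consecutive frames:
# overlap >= frac * the smaller of the two label areas
overlap_links <- function(l1, l2, frac) {
  both <- l1 > 0 & l2 > 0
  if (!any(both)) return(NULL)
  a1 <- tabulate(l1[l1 > 0])
  a2 <- tabulate(l2[l2 > 0])
  tab <- table(l1[both], l2[both])
  pairs <- which(tab > 0, arr.ind = TRUE)
  i <- as.integer(rownames(tab))[pairs[, 1]]
  j <- as.integer(colnames(tab))[pairs[, 2]]
  ov <- tab[pairs]
  ok <- ov >= frac * pmin(a1[i], a2[j])
  if (!any(ok)) return(NULL)
  data.frame(from = i[ok], to = j[ok], overlap = as.numeric(ov[ok]))
}

#' Classify focus merge and split events
#'
#' A merge is recorded when two or three labels in frame `t` each overlap a
#' single label in frame `t + 1` by at least `overlap_fraction` of the
#' smaller label; a split is the time-reverse. A merge whose fused focus
#' later splits within the observation window is reclassified as a single
#' merging-and-splitting event, unless the fused state lasted fewer than
#' `min_fused` frames, in which case the merge/split pair is discarded as a
#' sub-resolution pass. Events with four or more participants are
#' returned with type `"unclassified"`. Tracks touched by a merge are flagged
#' excluded (`merge-contaminated`) for displacement analysis, and tracks that
#' first appear at the nucleus border after the first frame are flagged
#' `ROI-migrant`.
#'
#' @param tracks a `focus_tracks` data.frame from [link_tracks()].
#' @param labels list of per-frame label matrices (from
#'   [detect_foci_stack()]).
#' @param overlap_fraction minimum overlap as a fraction of the smaller
#'   label's area.
#' @param min_fused minimum number of frames the fused focus must persist: a
#'   merge undone by a split after fewer frames is discarded as a
#'   sub-resolution pass of two foci (symmetric under time reversal), not an
#'   interaction event.
#' @return list with `events` (data.frame `type`, `frame`, `parent_tracks`,
#'   `child_tracks` as comma-separated track ids) and `tracks` (the input
#'   with `excluded`/`reason` updated).
#' @export
classify_events <- function(tracks, labels, overlap_fraction = 0.3,
                            min_fused = 2L) {
  nT <- length(labels)
  links <- vector("list", nT)
  for (t in seq_len(nT - 1L)) {
    # single-bracket assignment: a NULL result must not delete the element
    links[t] <- list(overlap_links(labels[[t]], labels[[t + 1L]],
                                   overlap_fraction))
  }
  track_of <- function(frame, label) {
    hit <- tracks$track_id[tracks$frame == frame & tracks$label %in% label]
    unique(hit)
  }

  events <- list()
  merge_heads <- list()  # per merge event: list(frame, label) of fused focus
  for (t in seq_len(nT - 1L)) {
    lk <- links[[t]]
    if (is.null(lk)) next
    for (j in unique(lk$to[duplicated(lk$to)])) {
      parents <- lk$from[lk$to == j]
      type <- if (length(parents) > 3) "unclassified" else "merging"
      events[[length(events) + 1L]] <- list(
        type = type, frame = t + 1L,
        parent_tracks = track_of(t, parents),
        child_tracks = track_of(t + 1L, j),
        head = list(frame = t + 1L, label = j))
    }
    for (i in unique(lk$from[duplicated(lk$from)])) {
      children <- lk$to[lk$from == i]
      type <- if (length(children) > 3) "unclassified" else "splitting"
      events[[length(events) + 1L]] <- list(
        type = type, frame = t + 1L,
        parent_tracks = track_of(t, i),
        child_tracks = track_of(t + 1L, children),
        parent_head = list(frame = t, label = i))
    }
  }

  # follow each fused focus forward; if it becomes the parent of a split,
  # pair the two into one merging-and-splitting event
  if (length(events) > 0) {
    is_merge <- vapply(events, function(e) e$type == "merging", logical(1))
    is_split <- vapply(events, function(e) e$type == "splitting", logical(1))
    split_keys <- vapply(events, function(e) {
      if (e$type == "splitting")
        paste(e$parent_head$frame, e$parent_head$label) else ""
    }, character(1))
    drop <- rep(FALSE, length(events))
    for (m in which(is_merge)) {
      cur <- events[[m]]$head
      repeat {
        key <- paste(cur$frame, cur$label)
        s <- which(split_keys == key & is_split & !drop)
        if (length(s) > 0) {
          s <- s[1]
          fused_frames <- events[[s]]$frame - events[[m]]$frame
          if (fused_frames < min_fused) {
            # sub-resolution pass: two foci fused for a single frame, then
            # apart again -- not an interaction event
            drop[m] <- TRUE
            drop[s] <- TRUE
            break
          }
          events[[m]]$type <- "merging_and_splitting"
          events[[m]]$child_tracks <- unique(c(events[[m]]$child_tracks,
                                               events[[s]]$child_tracks))
          drop[s] <- TRUE
          break
        }
        lk <- if (cur$frame <= nT - 1L) links[[cur$frame]] else NULL
        if (is.null(lk)) break
        nxt <- lk$to[lk$from == cur$label]
        if (length(nxt) != 1L) break
        if (sum(lk$to == nxt) != 1L) break  # swallowed by another merge
        cur <- list(frame = cur$frame + 1L, label = nxt)
      }
    }
    events <- events[!drop]
  }

  ev_df <- if (length(events) == 0) {
    data.frame(type = character(0), frame = integer(0),
               parent_tracks = character(0), child_tracks = character(0))
  } else {
    data.frame(
      type = vapply(events, `[[`, character(1), "type"),
      frame = vapply(events, `[[`, integer(1), "frame"),
      parent_tracks = vapply(events, function(e)
        paste(sort(e$parent_tracks), collapse = ","), character(1)),
      child_tracks = vapply(events, function(e)
        paste(sort(e$child_tracks), collapse = ","), character(1)))
  }
  ev_df <- ev_df[order(ev_df$frame), , drop = FALSE]
  rownames(ev_df) <- NULL

  tracks <- exclude_tracks(tracks, ev_df)
  list(events = ev_df, tracks = tracks)
}

#' Flag tracks to exclude from displacement analysis
#'
#' Tracks involved in a merging (or merging-and-splitting) event are flagged
#' `merge-contaminated`; tracks first detected at the nucleus border after
#' frame 1 are flagged `ROI-migrant`.
#'
#' @param tracks a `focus_tracks` data.frame.
#' @param events events data.frame from [classify_events()].
#' @return the tracks with updated `excluded` and `reason` columns.
#' @export
exclude_tracks <- function(tracks, events) {
  merge_ev <- events[events$type %in% c("merging", "merging_and_splitting"), ]
  contaminated <- unique(unlist(lapply(
    c(merge_ev$parent_tracks, merge_ev$child_tracks),
    function(s) as.integer(strsplit(s, ",")[[1]]))))
  hit <- tracks$track_id %in% contaminated
  tracks$excluded[hit] <- TRUE
  tracks$reason[hit] <- "merge-contaminated"

  if ("touches_border" %in% names(tracks)) {
    first_rows <- !duplicated(tracks$track_id[order(tracks$frame)])
    ord <- order(tracks$frame)
    firsts <- tracks[ord, ][first_rows, ]
    migrants <- firsts$track_id[firsts$frame > 1 & firsts$touches_border]
    mig <- tracks$track_id %in% migrants & !tracks$excluded
    tracks$excluded[mig] <- TRUE
    tracks$reason[mig] <- "ROI-migrant"
  }
  tracks
}

#' Per-nucleus focus interaction rates
#'
#' Fraction of foci (tracks) participating in merging, splitting, and
#' merging-and-splitting events in one nucleus.
#'
#' @param events events data.frame from [classify_events()].
#' @param tracks the nucleus's `focus_tracks` data.frame.
#' @return data.frame with `type`, `n_foci` (participating tracks) and
#'   `fraction` (of all tracks in the nucleus), one row per event class.
#' @export
event_rates <- function(events, tracks) {
  total <- length(unique(tracks$track_id))
  if (total == 0) {
    warning("nucleus has no foci; skipped")
    return(NULL)
  }
  classes <- c("merging", "splitting", "merging_and_splitting")
  n <- vapply(classes, function(cl) {
    ev <- events[events$type == cl, ]
    length(unique(unlist(lapply(
      c(ev$parent_tracks, ev$child_tracks),
      function(s) as.integer(strsplit(s, ",")[[1]])))))
  }, integer(1))
  data.frame(type = classes, n_foci = n, fraction = n / total,
             row.names = NULL)
}

#' Aggregate event rates across nuclei
#'
#' @param rate_list list of per-nucleus data.frames from [event_rates()]
#'   (`NULL` entries are dropped).
#' @return data.frame with `type`, `mean_fraction`, `sd_fraction`, `n_nuclei`.
#' @export
aggregate_event_rates <- function(rate_list) {
  rate_list <- Filter(Negate(is.null), rate_list)
  stopifnot(length(rate_list) > 0)
  classes <- rate_list[[1]]$type
  m <- sapply(rate_list, function(r) r$fraction[match(classes, r$type)])
  m <- matrix(m, nrow = length(classes))
  data.frame(type = classes,
             mean_fraction = rowMeans(m),
             sd_fraction = apply(m, 1, stats::sd),
             n_nuclei = ncol(m))
}

#' Write tracks (CSV) and events (JSON)
#'
#' @param tracks a `focus_tracks` data.frame.
#' @param events events data.frame.
#' @param tracks_path,events_path output paths.
#' @return invisibly, the paths written.
#' @export
write_tracks <- function(tracks, events, tracks_path, events_path) {
  utils::write.csv(as.data.frame(tracks), tracks_path, row.names = FALSE)
  jsonlite::write_json(events, events_path, dataframe = "rows")
  invisible(c(tracks_path, events_path))
}
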