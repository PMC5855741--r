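#' Extract the nucleus region of interest
#'
#' Automated surrogate for drawing a region of interest around the nucleus:
#' each frame is Gaussian-smoothed, thresholded with Otsu's method, and the
#' largest connected component above the threshold (holes filled) becomes the
#' per-frame nucleus mask. Downstream operations only consider pixels inside
#' the mask.
#'
#' @param stack a `timelapse_stack`.
#' @param sigma smoothing SD in pixels before thresholding.
#' @param min_area minimum acceptable nuclear area, square micrometres.
#' @return object of class `nucleus_roi`: list with `masks` (logical array
#'   `rows x cols x frames`) and `area_um2` (per-frame nuclear area).
#' @export
extract_nucleus_roi <- function(stack, sigma = 2, min_area = 20) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nT <- n_frames(stack)
  d <- dim(stack$frames)
  masks <- array(FALSE, dim = d)
  area <- numeric(nT)
  px2 <- stack$pixel_size^2
  for (t in seq_len(nT)) {
    img <- stack$frames[, , t]
    rng <- range(img)
    if (diff(rng) < 1e-9) stop("no nucleus found in frame ", t)
    sm <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(img), sigma))
    smn <- (sm - min(sm)) / (max(sm) - min(sm))
    thr <- EBImage::otsu(EBImage::as.Image(smn))
    bw <- smn > thr
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(bw)))
    if (max(lab) < 1) stop("no nucleus found in frame ", t)
    sizes <- tabulate(lab[lab > 0])
    biggest <- which.max(sizes)
    m <- lab == biggest
    m <- EBImage::imageData(EBImage::fillHull(EBImage::as.Image(m * 1))) > 0
    if (sum(m) * px2 < min_area) stop("no nucleus found in frame ", t)
    masks[, , t] <- m
    area[t] <- sum(m) * px2
  }
  structure(list(masks = masks, area_um2 = area), class = "nucleus_roi")
}

#' Detect foci in one frame
#'
#' After Gaussian smoothing, pixels inside the nucleus mask brighter than
#' `nuclear mean + k * nuclear SD` are segmented into foci by an intensity
#' watershed (separating touching foci) and filtered by area. The nuclear mean and SD are computed on the smoothed
#' masked frame with iterative sigma-clipping (pixels above mean + 3 SD are
#' excluded and the statistics recomputed, three times), so that the bright
#' foci themselves do not inflate the background estimate; `min_prominence`
#' puts a floor under the threshold offset so that on noiseless images the
#' components do not grow into the full Gaussian tails. Focus area is the
#' pixel count times the pixel area; mean intensity is taken from the
#' unsmoothed pixel values under the label. Foci touching the nucleus border
#' are flagged, not discarded.
#'
#' @param img numeric matrix, one (registered) frame.
#' @param mask logical nucleus mask for the frame.
#' @param pixel_size micrometres per pixel.
#' @param k threshold in (sigma-clipped) nuclear SD units above the nuclear
#'   mean.
#' @param sigma smoothing SD in pixels.
#' @param min_area,max_area focus area filter, square micrometres.
#' @param min_prominence minimum threshold offset above the nuclear mean, AU.
#' @param watershed_tol intensity watershed tolerance (AU): touching foci are
#'   separated when each peak rises at least this far above the saddle
#'   between them.
#' @return data.frame with one row per focus: `label`, `x`, `y`
#'   (micrometres, image-centred), `area` (square micrometres),
#'   `mean_intensity` (AU), `touches_border`; the filtered label matrix is
#'   attached as attribute `"labels"`.
#' @export
detect_foci <- function(img, mask, pixel_size, k = 3, sigma = 1,
                        min_area = 0.3, max_area = 10, min_prominence = 15,
                        watershed_tol = 10) {
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      touches_border = logical(0))
  attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
  if (!any(mask)) return(empty)

  sm <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(img), sigma))
  nuc <- sm[mask]
  bg <- nuc
  for (i in 1:3) {
    m0 <- mean(bg); s0 <- stats::sd(bg)
    if (!is.finite(s0) || s0 == 0) break
    bg <- bg[bg <= m0 + 3 * s0]
  }
  thr <- mean(bg) + max(k * stats::sd(bg), min_prominence)
  bw <- sm > thr & mask
  if (!any(bw)) return(empty)
  # intensity watershed separates touching foci whose peaks both rise at
  # least `watershed_tol` above the saddle between them
  lab <- EBImage::imageData(EBImage::watershed(
    EBImage::as.Image((sm - thr) * bw), tolerance = watershed_tol, ext = 1))
  storage.mode(lab) <- "integer"

  idx <- which(lab > 0)
  ids <- lab[idx]
  px2 <- pixel_size^2
  area_px <- tabulate(ids)
  keep <- which(area_px * px2 >= min_area & area_px * px2 <= max_area)
  if (length(keep) == 0) return(empty)

  # border-adjacent pixels: outside-of-mask dilated by one, plus image edge
  outside <- !mask
  outside[1, ] <- TRUE; outside[nrow(mask), ] <- TRUE
  outside[, 1] <- TRUE; outside[, ncol(mask)] <- TRUE
  near_border <- EBImage::imageData(EBImage::dilate(
    EBImage::as.Image(outside * 1), EBImage::makeBrush(3, "box"))) > 0

  cx <- (ncol(img) + 1) / 2
  cy <- (nrow(img) + 1) / 2
  sel <- ids %in% keep
  idk <- idx[sel]; idsk <- ids[sel]
  f <- factor(idsk, levels = keep)
  col_i <- ((idk - 1) %/% nrow(img)) + 1
  row_i <- ((idk - 1) %% nrow(img)) + 1
  out <- data.frame(
    label = keep,
    x = (tapply(col_i, f, mean) - cx) * pixel_size,
    y = (tapply(row_i, f, mean) - cy) * pixel_size,
    area = area_px[keep] * px2,
    mean_intensity = as.numeric(tapply(img[idk], f, mean)),
    touches_border = as.logical(tapply(near_border[idk], f, any))
  )
  rownames(out) <- NULL
  lab[!(lab %in% keep)] <- 0L
  attr(out, "labels") <- lab
  out
}

#' Detect foci in every frame of a stack
#'
#' @param stack a registered `timelapse_stack`.
#' @param roi a `nucleus_roi` from [extract_nucleus_roi()].
#' @param ... passed to [detect_foci()].
#' @return list with `detections` (data.frame of all per-frame detections
#'   with a `frame` column) and `labels` (list of per-frame label matrices).
#' @export
detect_foci_stack <- function(stack, roi, ...) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(roi, "nucleus_roi"))
  nT <- n_frames(stack)
  dets <- vector("list", nT)
  labs <- vector("list", nT)
  for (t in seq_len(nT)) {
    d <- detect_foci(stack$frames[, , t], roi$masks[, , t],
                     stack$pixel_size, ...)
    labs[[t]] <- attr(d, "labels")
    if (nrow(d) > 0) d <- cbind(frame = t, d)
    dets[[t]] <- d
  }
  dets <- dets[vapply(dets, nrow, integer(1)) > 0]
  detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(frame = integer(0), label = integer(0), x = numeric(0),
               y = numeric(0), area = numeric(0),
               mean_intensity = numeric(0), touches_border = logical(0))
  rownames(detections) <- NULL
  list(detections = detections, labels = labs)
}

#' Foci-per-cell series
#'
#' Integer focus count per frame for one nucleus, zero-filled for frames
#' without detections.
#'
#' @param detections per-frame detections of one nucleus (needs a `frame`
#'   column).
#' @param n_frames series length.
#' @return integer vector of length `n_frames`.
#' @export
measure_fpc <- function(detections, n_frames) {
  tabulate(factor(detections$frame, levels = seq_len(n_frames)),
           nbins = n_frames)
}

#' Per-frame summary of focus measurements
#'
#' @param detections detections data.frame with a `frame` column.
#' @param n_frames series length.
#' @return data.frame with `frame`, `n`, `mean_area`, `mean_intensity`
#'   (NA where no foci were detected).
#' @export
summarize_detections <- function(detections, n_frames) {
  f <- factor(detections$frame, levels = seq_len(n_frames))
  data.frame(
    frame = seq_len(n_frames),
    n = as.integer(table(f)),
    mean_area = as.numeric(tapply(detections$area, f, mean)),
    mean_intensity = as.numeric(tapply(detections$mean_intensity, f, mean))
  )
}

#' Write focus detections as CSV
#'
#' @param detections detections data.frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
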