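#' Classify a mitochondrial track as mobile or stationary
#'
#' A mitochondrion is mobile if its net displacement over the bout -- the
#' absolute distance between its last and first observed positions, not the
#' path length -- is strictly greater than the threshold (5 um by default);
#' otherwise it is stationary. A track observed at exactly 5 um of net
#' displacement is therefore stationary.
#'
#' @param positions numeric vector of axial positions (um), one per observed
#'   frame, in frame order; at least two positions are required.
#' @param threshold_um motility threshold in um (strict \code{>}), default 5.
#' @return list with \code{net_displacement} (um, >= 0) and \code{label}
#'   (\code{"mobile"} or \code{"stationary"}).
#' @examples
#' classify_motility(c(0, 2, 6.2))$label      # mobile
#' classify_motility(c(0, 5))$label           # stationary (boundary)
#' @export
classify_motility <- function(positions, threshold_um = 5) {
  positions <- positions[is.finite(positions)]
  if (length(positions) < 2)
    stop("a track needs at least 2 observed positions", call. = FALSE)
  net <- abs(positions[length(positions)] - positions[1])
  list(net_displacement = net,
       label = if (net > threshold_um) "mobile" else "stationary")
}

#' Summarise the motility of one kymograph bout
#'
#' Counts mobile and stationary tracks in a bout with
#' \code{\link{classify_motility}}. A bout with no tracks (e.g. acquired
#' after fragmentation) gives \code{mobile_fraction = 0} and is flagged
#' degenerate.
#'
#' @param bout a \code{kymo_bout}, or a data frame with columns
#'   \code{track_id}, \code{frame}, \code{position_um}.
#' @param threshold_um motility threshold (um), default 5.
#' @return one-row data frame: \code{bout_start}, \code{n_tracks},
#'   \code{n_mobile}, \code{mobile_fraction}, \code{degenerate}.
#' @export
summarize_bout <- function(bout, threshold_um = 5) {
  if (inherits(bout, "kymo_bout")) {
    tracks <- bout$tracks
    b <- bout$bout_start
  } else {
    tracks <- bout
    b <- NA_real_
  }
  n <- length(unique(tracks$track_id))
  if (n == 0)
    return(data.frame(bout_start = b, n_tracks = 0L, n_mobile = 0L,
                      mobile_fraction = 0, degenerate = TRUE))
  o <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[o]
  pos <- tracks$position_um[o]
  first <- !duplicated(tid)
  last <- !duplicated(tid, fromLast = TRUE)
  net <- abs(pos[last] - pos[first])   # net displacement, as classify_motility
  mob <- net > threshold_um
  data.frame(bout_start = b, n_tracks = n, n_mobile = sum(mob),
             mobile_fraction = sum(mob) / n, degenerate = FALSE)
}

#' Summarise a time-ordered list of bouts
#'
#' @param bouts list of \code{kymo_bout} objects.
#' @param threshold_um motility threshold (um), default 5.
#' @return data frame with one row per bout, sorted by \code{bout_start}.
#' @export
summarize_bouts <- function(bouts, threshold_um = 5) {
  out <- do.call(rbind, lapply(bouts, summarize_bout, threshold_um = threshold_um))
  out[order(out$bout_start), , drop = FALSE]
}

#' Estimate the mitochondrial arrest time of an axon
#'
#' The arrest time is the start of the first bout in which no mitochondrion
#' is mobile \emph{and} after which no later observed bout shows mobile
#' mitochondria again -- a single all-stationary bout followed by renewed
#' movement does not count. Returns \code{NA} if movement never ceases
#' within the observed bouts.
#'
#' @param bout_summaries data frame from \code{\link{summarize_bouts}},
#'   sorted by \code{bout_start}; must be non-empty.
#' @return arrest time in hours, or \code{NA_real_} if never arrested.
#' @examples
#' s <- data.frame(bout_start = 0:4, n_tracks = 20,
#'                 n_mobile = c(6, 4, 2, 0, 0),
#'                 mobile_fraction = c(.3, .2, .1, 0, 0), degenerate = FALSE)
#' arrest_time(s)  # 3
#' @export
arrest_time <- function(bout_summaries) {
  if (is.null(bout_summaries) || nrow(bout_summaries) == 0)
    stop("no bout summaries supplied", call. = FALSE)
  if (is.unsorted(bout_summaries$bout_start))
    stop("bout summaries must be sorted by bout_start", call. = FALSE)
  mob <- bout_summaries$n_mobile > 0
  if (mob[length(mob)]) return(NA_real_)
  last_mobile <- max(c(0L, which(mob)))
  if (last_mobile == nrow(bout_summaries)) return(NA_real_)
  bout_summaries$bout_start[last_mobile + 1L]
}

#' Extract mitochondrial tracks from a kymograph image
#'
#' Per-frame peak detection (local intensity maxima above a threshold)
#' followed by greedy nearest-neighbour frame-to-frame linking under a
#' maximum step constraint. Detections that cannot be linked to an active
#' track start a new track; tracks shorter than \code{min_length} frames are
#' discarded.
#'
#' @param img numeric matrix, frames (rows) by space (columns).
#' @param pixel_size_um um per pixel.
#' @param frame_interval_s seconds between frames (metadata, carried along).
#' @param intensity_threshold minimum peak intensity, default 0.3.
#' @param max_step_um maximum frame-to-frame movement allowed when linking,
#'   default 2 um.
#' @param min_length minimum track length in frames, default 10.
#' @return data frame \code{track_id, frame, position_um}; empty for a blank
#'   image.
#' @export
extract_tracks <- function(img, pixel_size_um, frame_interval_s,
                           intensity_threshold = 0.3, max_step_um = 2,
                           min_length = 10) {
  empty <- data.frame(track_id = integer(), frame = integer(),
                      position_um = numeric())
  if (length(img) == 0 || all(img <= intensity_threshold)) return(empty)
  n_frames <- nrow(img)
  peaks_px <- lapply(seq_len(n_frames), function(f) {
    v <- img[f, ]
    i <- which(v > intensity_threshold)
    i[vapply(i, function(k) {
      lft <- if (k > 1) v[k - 1] else -Inf
      rgt <- if (k < length(v)) v[k + 1] else -Inf
      v[k] >= lft && v[k] > rgt
    }, logical(1))]
  })
  # active track bookkeeping: id, last position, per-track frame/position store
  store <- list(); last_pos <- numeric(0); last_id <- integer(0); next_id <- 1L
  for (f in seq_len(n_frames)) {
    det <- (peaks_px[[f]] - 0.5) * pixel_size_um
    assigned_trk <- rep(FALSE, length(last_id))
    assigned_det <- rep(FALSE, length(det))
    if (length(det) > 0 && length(last_id) > 0) {
      d <- abs(outer(last_pos, det, "-"))
      repeat {
        d[assigned_trk, ] <- Inf; d[, assigned_det] <- Inf
        if (all(!is.finite(d)) || min(d) > max_step_um) break
        ij <- arrayInd(which.min(d), dim(d))
        ti <- ij[1]; dj <- ij[2]
        id <- last_id[ti]
        store[[id]]$frame <- c(store[[id]]$frame, f)
        store[[id]]$pos <- c(store[[id]]$pos, det[dj])
        last_pos[ti] <- det[dj]
        assigned_trk[ti] <- TRUE; assigned_det[dj] <- TRUE
      }
    }
    # unmatched detections open new tracks; unmatched tracks terminate
    for (dj in which(!assigned_det)) {
      store[[next_id]] <- list(frame = f, pos = det[dj])
      last_id <- c(last_id[assigned_trk], next_id)
      last_pos <- c(last_pos[assigned_trk], det[dj])
      assigned_trk <- rep(TRUE, length(last_id))
      next_id <- next_id + 1L
    }
    if (length(det) > 0 || length(last_id) > 0) {
      keep <- assigned_trk | vapply(seq_along(last_id), function(k) {
        # tracks matched this frame stay active; others are closed
        id <- last_id[k]
        length(store[[id]]$frame) > 0 && store[[id]]$frame[length(store[[id]]$frame)] == f
      }, logical(1))
      last_id <- last_id[keep]; last_pos <- last_pos[keep]
    }
  }
  keep <- vapply(store, function(s) length(s$frame) >= min_length, logical(1))
  if (!any(keep)) return(empty)
  out <- do.call(rbind, lapply(which(keep), function(id) {
    data.frame(track_id = id, frame = store[[id]]$frame,
               position_um = store[[id]]$pos)
  }))
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}
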