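#' Simulate axon morphology images
#'
#' Renders grayscale snapshots of the axon at the requested times: an
#' elongated connected strip while the axon is intact, the same strip with
#' local swellings between calcium onset and fragmentation, and disconnected
#' near-circular particles after fragmentation. The geometry (a 1024 x 64 px
#' strip at 0.3 um/px) is chosen so that the degeneration index behaves as
#' in real morphology data: DI ~ 0 while the axon is connected, DI ~ 1 when
#' only fragments remain.
#'
#' @param schedule one-row \code{event_schedule}.
#' @param params \code{\link{cascade_params}}.
#' @param times sorted acquisition times (hours).
#' @param width,height image size in pixels (default 1024 x 64).
#' @param pixel_size_um um per pixel, default 0.3.
#' @return list of \code{axon_image} objects: \code{time}, \code{pixels}
#'   (matrix in [0, 1], rows = height), \code{pixel_size_um},
#'   \code{morphology_state} (\code{"intact"}, \code{"swollen"} or
#'   \code{"fragmented"}).
#' @export
simulate_axon_images <- function(schedule, params, times, width = 1024,
                                 height = 64, pixel_size_um = 0.3) {
  stopifnot(nrow(schedule) == 1)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  lapply(times, function(tm) {
    state <- if (tm >= schedule$t_fragmentation) "fragmented"
             else if (tm >= schedule$t_ca_onset) "swollen" else "intact"
    px <- matrix(0.05, nrow = height, ncol = width)
    mid <- round(height / 2)
    if (state == "fragmented") {
      nfrag <- 28
      cx <- round(seq(18, width - 18, length.out = nfrag)) +
        round(stats::runif(nfrag, -6, 6))
      cy <- mid + round(stats::rnorm(nfrag, 0, 3))
      r <- stats::runif(nfrag, 2.5, 4.5)
      for (k in seq_len(nfrag)) px <- .draw_disc(px, cx[k], cy[k], r[k], 0.8)
    } else {
      px[(mid - 1):(mid + 2), ] <- 0.8
      if (state == "swollen") {
        nsw <- 8
        cx <- round(stats::runif(nsw, 30, width - 30))
        for (k in seq_len(nsw))
          px <- .draw_ellipse(px, cx[k], mid, a = 9, b = 7, value = 0.8)
      }
    }
    px <- px + matrix(stats::rnorm(length(px), 0, 0.02), nrow = height)
    px <- pmin(pmax(px, 0), 1)
    structure(list(time = tm, pixels = px, pixel_size_um = pixel_size_um,
                   morphology_state = state), class = "axon_image")
  })
}

.draw_disc <- function(px, cx, cy, r, value) {
  xs <- max(1, floor(cx - r)):min(ncol(px), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(nrow(px), ceiling(cy + r))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) px[y, x] <- value
  px
}

.draw_ellipse <- function(px, cx, cy, a, b, value) {
  xs <- max(1, floor(cx - a)):min(ncol(px), ceiling(cx + a))
  ys <- max(1, floor(cy - b)):min(nrow(px), ceiling(cy + b))
  for (x in xs) for (y in ys)
    if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) px[y, x] <- value
  px
}
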