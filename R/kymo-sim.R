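#' Simulate mitochondrial kymograph bouts for one axon
#'
#' Generates the per-bout mitochondrial position tracks implied by an event
#' schedule. A fixed population of \code{n_mito} mitochondria (injury does
#' not change the count) is followed across bouts; the fraction still mobile
#' tracks the axon's relative ATP through the power-law coupling
#' \code{fraction = atp^gamma}, individual mitochondria stalling one by one
#' as ATP crosses their quantile level, and every remaining mobile
#' mitochondrion arresting at \code{t_mito_stop}. Mobile tracks cover a net
#' distance well above the 5-um motility criterion within one 300-s bout;
#' stationary tracks only jitter.
#'
#' @param schedule one-row \code{event_schedule}.
#' @param params \code{\link{cascade_params}}.
#' @param bout_times sorted bout start times (hours); see
#'   \code{\link{bout_schedule}} for the standard acquisition design.
#' @param positions logical; if \code{TRUE} each track carries all
#'   \code{n_frames} per-frame positions, if \code{FALSE} only the first and
#'   last frame (sufficient for net-displacement motility analysis, and much
#'   lighter for large cohorts).
#' @return A list of bouts (class \code{kymo_bout}): each has
#'   \code{bout_start} (h), \code{frame_interval_s}, \code{n_frames},
#'   \code{tracks} (data frame \code{track_id, frame, position_um}),
#'   \code{truth} (data frame \code{track_id, mobile} -- simulator ground
#'   truth), and \code{post_fragmentation} (bouts scheduled after the axon
#'   has fragmented contain no tracks and are flagged).
#' @examples
#' p <- cascade_params()
#' set.seed(2)
#' sch <- sample_event_schedule(p, "ax1")
#' bouts <- simulate_kymograph_bouts(sch, p, bout_times = c(-0.25, 4.0))
#' summarize_bouts(bouts)
#' @export
simulate_kymograph_bouts <- function(schedule, params, bout_times,
                                     positions = TRUE) {
  validate_cascade_params(params)
  stopifnot(nrow(schedule) == 1)
  if (is.unsorted(bout_times)) stop("bout_times must be sorted", call. = FALSE)
  bt <- params$bout
  n_frames <- as.integer(bt["n_frames"])
  dt_s <- bt["frame_interval_s"]
  dur_s <- n_frames * dt_s
  dur_h <- dur_s / 3600

  m <- params$motility
  n <- as.integer(m$n_mito)
  n_mob <- round(n * m$baseline_fraction)
  gamma <- schedule$motility_gamma
  arrest <- params$atp$arrest_level

  # persistent per-track state: start position and stall time
  x0 <- stats::runif(n, 10, 90)
  stall <- rep(-Inf, n)              # never-mobile tracks "stalled" from the start
  if (n_mob > 0) {
    q <- (seq_len(n_mob) - 0.5) / n_mob
    lev <- q^(1 / gamma)
    s <- ifelse(lev <= arrest | !is.finite(schedule$atp_t_half),
                schedule$t_mito_stop,
                schedule$atp_t_half + schedule$atp_tau * log((1 - lev) / lev))
    # independent per-track half-normal delay on individual stall times
    # (a mitochondrion may keep moving past its coupling quantile, never
    # stall sooner, so the ATP drop still leads the motility drop);
    # mitochondria at or below the arrest ATP level stall collectively at
    # t_mito_stop, which keeps the true arrest time exact
    sj <- m$stall_jitter_sd_h
    early <- lev > arrest & is.finite(s)
    if (sj > 0 && any(early))
      s[early] <- s[early] + abs(stats::rnorm(sum(early), 0, sj))
    s <- pmin(pmax(s, 0.05), schedule$t_mito_stop)
    s[!early] <- schedule$t_mito_stop
    stall[seq_len(n_mob)] <- s
  }

  jsd <- m$jitter_sd_um
  lapply(bout_times, function(b) {
    if (b >= schedule$t_fragmentation) {
      return(structure(list(bout_start = b, frame_interval_s = dt_s,
                            n_frames = n_frames,
                            tracks = data.frame(track_id = integer(),
                                                frame = integer(),
                                                position_um = numeric()),
                            truth = data.frame(track_id = integer(),
                                               mobile = logical()),
                            post_fragmentation = TRUE),
                       class = "kymo_bout"))
    }
    overlap_s <- pmin(pmax((stall - b) * 3600, 0), dur_s)
    dirn <- sample(c(-1, 1), n, replace = TRUE)
    span <- stats::runif(n, m$speed_um_per_bout["min"], m$speed_um_per_bout["max"])
    v <- span / dur_s                         # um per second while moving
    net_true <- dirn * v * overlap_s
    frames <- if (positions) seq_len(n_frames) else c(1L, n_frames)
    el_s <- (frames - 1L) * dt_s
    tracks <- do.call(rbind, lapply(seq_len(n), function(j) {
      x <- x0[j] + dirn[j] * v[j] * pmin(el_s, overlap_s[j]) +
        stats::rnorm(length(frames), 0, jsd)
      data.frame(track_id = j, frame = frames, position_um = x)
    }))
    structure(list(bout_start = b, frame_interval_s = dt_s, n_frames = n_frames,
                   tracks = tracks,
                   truth = data.frame(track_id = seq_len(n),
                                      mobile = abs(net_true) > 5),
                   post_fragmentation = FALSE),
              class = "kymo_bout")
  })
}

#' Standard bout acquisition times for one axon
#'
#' The acquisition design used for the ATP/motility experiments: one
#' pre-injury baseline bout, then bouts every \code{spacing_min} minutes from
#' \code{from} hours post-injury until a little after the axon's arrest (so
#' the arrest is always bracketed and confirmed by later all-stationary
#' bouts).
#'
#' @param schedule one-row \code{event_schedule}.
#' @param params \code{\link{cascade_params}}.
#' @param from first post-injury bout time (h), default 3.5.
#' @param confirm number of bouts to acquire beyond the arrest (default 3).
#' @return numeric vector of bout start times in hours.
#' @export
bout_schedule <- function(schedule, params, from = 3.5, confirm = 3) {
  sp <- params$bout["spacing_min"] / 60
  t_stop <- schedule$t_mito_stop
  last <- if (is.finite(t_stop)) t_stop + confirm * sp else from + 20 * sp
  c(-3 * sp, seq(from, last + sp, by = sp))
}

#' Render a kymograph image from a bout
#'
#' Draws the space-time intensity image (frames by space) of one bout, each
#' mitochondrion a Gaussian spot along its track. Used for the
#' track-extraction round trip; requires a bout simulated with full
#' per-frame positions.
#'
#' @param bout a \code{kymo_bout} with per-frame positions.
#' @param pixel_size_um spatial sampling (um per pixel), default 0.3.
#' @param width_um spatial extent of the image, default 100 um.
#' @param spot_sd_um Gaussian spot size, default 0.45 um.
#' @return numeric matrix, \code{n_frames} rows by space columns, in [0, 1].
#' @export
render_kymograph <- function(bout, pixel_size_um = 0.3, width_um = 100,
                             spot_sd_um = 0.45) {
  stopifnot(inherits(bout, "kymo_bout"))
  npx <- ceiling(width_um / pixel_size_um)
  img <- matrix(0, nrow = bout$n_frames, ncol = npx)
  if (nrow(bout$tracks) == 0) return(img)
  xs <- (seq_len(npx) - 0.5) * pixel_size_um
  for (i in seq_len(nrow(bout$tracks))) {
    f <- bout$tracks$frame[i]
    mu <- bout$tracks$position_um[i]
    img[f, ] <- img[f, ] + exp(-(xs - mu)^2 / (2 * spot_sd_um^2))
  }
  pmin(img, 1)
}
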