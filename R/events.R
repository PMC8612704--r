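#' Baseline intensity of a channel
#'
#' Mean intensity over the pre-injury window. At least three frames must fall
#' inside the window, and the mean must be strictly positive (fold-change
#' readouts divide by it).
#'
#' @param time_h frame times (hours).
#' @param intensity frame intensities (a.u.).
#' @param window \code{c(start, end)} in hours; frames with
#'   \code{start <= t < end} are used. Default \code{c(-0.5, 0)}.
#' @return baseline intensity (a.u.).
#' @examples
#' compute_baseline(c(-0.5, -0.3, -0.1), c(100, 102, 98))  # 100
#' @export
compute_baseline <- function(time_h, intensity, window = c(-0.5, 0)) {
  i <- time_h >= window[1] & time_h < window[2]
  if (sum(i) < 3)
    stop("baseline window contains fewer than 3 frames", call. = FALSE)
  b <- mean(intensity[i])
  if (!is.finite(b) || b <= 0)
    stop("baseline must be strictly positive", call. = FALSE)
  b
}

# shared sustained-crossing scanner: first index (after `from_idx`) at which
# `hit` holds for `sustain` consecutive frames; NA if never.
.first_sustained <- function(hit, sustain, from_idx = 1L) {
  n <- length(hit)
  for (i in seq.int(from_idx, max(from_idx, n - sustain + 1L))) {
    if (i + sustain - 1L > n) break
    if (all(hit[i:(i + sustain - 1L)])) return(i)
  }
  NA_integer_
}

#' Detect calcium-influx onset on a GCaMP6 trace
#'
#' Calcium influx is a rise of the GCaMP6 intensity to at least
#' \code{fold} times baseline (two-fold or greater by default). The first
#' injury-site calcium transient is excluded by ignoring frames up to
#' \code{exclude_h} after injury, and the crossing must be sustained for
#' \code{sustain} consecutive frames so that ~10\% frame-to-frame
#' fluctuations are not called.
#'
#' @param time_h,intensity the trace.
#' @param baseline baseline intensity (see \code{\link{compute_baseline}});
#'   must be positive.
#' @param fold threshold fold change (\code{>=}), default 2.
#' @param exclude_h end of the injury-transient exclusion window (h), default 0.5.
#' @param sustain consecutive frames required at/above threshold, default 2.
#' @return list: \code{time} (h of the first sustained crossing frame, or
#'   \code{NA} if never crossed), \code{fold} (fold change at that frame),
#'   \code{qc} (character vector of quality flags).
#' @examples
#' t <- seq(0, 50, by = 10) / 60
#' detect_calcium_onset(t, c(100, 105, 98, 210, 400, 420), baseline = 100,
#'                      exclude_h = 0)
#' @export
detect_calcium_onset <- function(time_h, intensity, baseline, fold = 2,
                                 exclude_h = 0.5, sustain = 2) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive", call. = FALSE)
  qc <- character(0)
  eligible <- which(time_h > exclude_h)
  if (length(eligible) < sustain) {
    return(list(time = NA_real_, fold = NA_real_,
                qc = "trace shorter than exclusion window"))
  }
  hit <- intensity >= fold * baseline
  i <- .first_sustained(hit, sustain, from_idx = eligible[1])
  if (is.na(i)) return(list(time = NA_real_, fold = NA_real_, qc = qc))
  list(time = time_h[i], fold = intensity[i] / baseline, qc = qc)
}

#' Detect the TMRM drastic drop
#'
#' Computes the per-frame fractional change from the previous frame
#' (Diff_TMRM) and calls the earliest frame whose reduction exceeds
#' \code{drop} (30\% by default), provided the signal stays below the same
#' reduction relative to the pre-drop frame on the following frame (the
#' 2-frame sustain guards against single-frame fluctuations). Also reports
#' the frame with the largest frame-to-frame reduction -- the
#' "drastic change" locator -- which coincides with the threshold call on
#' compliant traces.
#'
#' @param time_h,intensity the trace (at least 2 frames).
#' @param drop fractional reduction threshold (strict \code{>}), default 0.30.
#' @param sustain if \code{TRUE} (default) require the next frame to remain
#'   below the threshold level relative to the pre-drop frame.
#' @return list: \code{time} (h, or \code{NA}), \code{drop} (fractional
#'   reduction at the called frame), \code{largest_change_time} (h of the
#'   largest frame-to-frame reduction), \code{qc}.
#' @examples
#' detect_tmrm_drop(0:3 / 6, c(1.00, 0.95, 0.60, 0.55))  # frame 2, drop 36.8%
#' @export
detect_tmrm_drop <- function(time_h, intensity, drop = 0.30, sustain = TRUE) {
  n <- length(intensity)
  if (n < 2) stop("TMRM trace needs at least 2 frames", call. = FALSE)
  rel <- diff(intensity) / intensity[-n]   # rel[i] = change at frame i+1
  cand <- which(rel < -drop) + 1L
  tcall <- NA_real_; dcall <- NA_real_
  for (i in cand) {
    ok <- TRUE
    if (sustain) {
      if (i < n) ok <- intensity[i + 1L] < (1 - drop) * intensity[i - 1L]
      else ok <- FALSE
    }
    if (ok) { tcall <- time_h[i]; dcall <- -rel[i - 1L]; break }
  }
  ilarg <- which.min(rel) + 1L
  list(time = tcall, drop = dcall,
       largest_change_time = time_h[ilarg], qc = character(0))
}

#' Percent PercevalHR decline from baseline at a fixed time
#'
#' Reads the PercevalHR (relative ATP) signal at the frame at, or latest
#' before, \code{at_time} and reports the percent decline from baseline,
#' clipped to [0, 100]. Imaging is discrete, so the frame value is used
#' rather than an interpolation.
#'
#' @param time_h,intensity the trace; it must span \code{at_time}.
#' @param baseline baseline intensity.
#' @param at_time readout time (h), default 3.5.
#' @return percent decline in [0, 100].
#' @export
perceval_decline <- function(time_h, intensity, baseline, at_time = 3.5) {
  if (max(time_h) < at_time)
    stop(sprintf("trace ends at %.2f h, before the %.2f h readout",
                 max(time_h), at_time), call. = FALSE)
  i <- max(which(time_h <= at_time))
  min(max(100 * (1 - intensity[i] / baseline), 0), 100)
}

#' Detect the beginning of axon degeneration on an mRuby3 trace
#'
#' The beginning of axon degeneration is a reduction of the cytosolic mRuby3
#' signal by more than \code{drop} (50\%) from baseline, sustained for
#' \code{sustain} consecutive frames. A frame at exactly half baseline is
#' not a call (strict "more than 50\% reduction").
#'
#' @param time_h,intensity the trace.
#' @param baseline baseline intensity (> 0).
#' @param drop fractional reduction from baseline (strict \code{>}), default 0.5.
#' @param sustain consecutive frames required, default 2.
#' @return onset time in hours, or \code{NA_real_} if continuity is never lost.
#' @export
detect_continuity_loss <- function(time_h, intensity, baseline, drop = 0.5,
                                   sustain = 2) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive", call. = FALSE)
  hit <- intensity < (1 - drop) * baseline
  i <- .first_sustained(hit, sustain)
  if (is.na(i)) NA_real_ else time_h[i]
}

#' Detect phosphatidylserine exposure on an Annexin-V trace
#'
#' Annexin-V labelling starts near zero, so the fold-change readout uses a
#' small positive pseudo-baseline. Onset is the first sustained frame with
#' \code{F / F_base >= fold} (2 by default, the same rule family as the
#' calcium call).
#'
#' @param time_h,intensity the trace.
#' @param baseline_floor positive pseudo-baseline.
#' @param fold threshold fold change (\code{>=}), default 2.
#' @param sustain consecutive frames required, default 2.
#' @return onset time in hours, or \code{NA_real_}.
#' @export
detect_annexin_onset <- function(time_h, intensity, baseline_floor, fold = 2,
                                 sustain = 2) {
  if (!is.finite(baseline_floor) || baseline_floor <= 0)
    stop("baseline floor must be positive", call. = FALSE)
  hit <- intensity >= fold * baseline_floor
  i <- .first_sustained(hit, sustain)
  if (is.na(i)) NA_real_ else time_h[i]
}

#' Metrics of the second calcium peak
#'
#' The second (pre-degeneration) calcium peak initiates at the calcium-onset
#' call and persists until the axon fragments, so its duration is the
#' interval from onset to fragmentation; its intensity is the maximum fold
#' change over baseline within that window.
#'
#' @param time_h,intensity the GCaMP6 trace.
#' @param baseline baseline intensity.
#' @param onset_time calcium-onset call (h); an error if missing.
#' @param fragmentation_time fragmentation time (h).
#' @return list \code{initiation}, \code{duration}, \code{intensity}.
#' @export
second_peak_metrics <- function(time_h, intensity, baseline, onset_time,
                                fragmentation_time) {
  if (is.na(onset_time))
    stop("no calcium onset was called for this axon", call. = FALSE)
  w <- time_h >= onset_time & time_h <= fragmentation_time
  if (!any(w)) stop("no frames between onset and fragmentation", call. = FALSE)
  list(initiation = onset_time,
       duration = fragmentation_time - onset_time,
       intensity = max(intensity[w]) / baseline)
}

#' Call all trace events for one axon
#'
#' Runs every applicable detector on the channels present in a trace table
#' and assembles one row of event calls. Channels that are absent simply
#' yield \code{NA} calls.
#'
#' @param traces data frame with columns \code{axon_id}, \code{channel},
#'   \code{time_h}, \code{intensity} for a single axon.
#' @param config a \code{\link{detection_config}}.
#' @return one-row data frame: \code{axon_id}, \code{t_ca_onset},
#'   \code{ca_fold}, \code{t_tmrm_drop}, \code{tmrm_drop_frac},
#'   \code{t_ps_exposure}, \code{t_degeneration},
#'   \code{perceval_decline_pct}, \code{qc}.
#' @export
call_axon_events <- function(traces, config = detection_config()) {
  stopifnot(length(unique(traces$axon_id)) == 1)
  getch <- function(ch) {
    x <- traces[traces$channel == ch, , drop = FALSE]
    if (nrow(x) == 0) NULL else x[order(x$time_h), , drop = FALSE]
  }
  bw <- config$baseline_window
  qc <- character(0)
  out <- data.frame(axon_id = traces$axon_id[1], t_ca_onset = NA_real_,
                    ca_fold = NA_real_, t_tmrm_drop = NA_real_,
                    tmrm_drop_frac = NA_real_, t_ps_exposure = NA_real_,
                    t_degeneration = NA_real_,
                    perceval_decline_pct = NA_real_, qc = "",
                    stringsAsFactors = FALSE)
  g <- getch("GCaMP6")
  if (!is.null(g)) {
    b <- compute_baseline(g$time_h, g$intensity, bw)
    ca <- detect_calcium_onset(g$time_h, g$intensity, b, fold = config$ca_fold,
                               exclude_h = config$exclude_first_peak_h,
                               sustain = config$sustain_frames)
    out$t_ca_onset <- ca$time; out$ca_fold <- ca$fold; qc <- c(qc, ca$qc)
  }
  tm <- getch("TMRM")
  if (!is.null(tm)) {
    dr <- detect_tmrm_drop(tm$time_h, tm$intensity, drop = config$tmrm_drop)
    out$t_tmrm_drop <- dr$time; out$tmrm_drop_frac <- dr$drop
  }
  an <- getch("AnnexinV")
  if (!is.null(an)) {
    bfl <- compute_baseline(an$time_h, an$intensity, bw)
    out$t_ps_exposure <- detect_annexin_onset(an$time_h, an$intensity, bfl,
                                              fold = config$annexin_fold,
                                              sustain = config$sustain_frames)
  }
  mr <- getch("mRuby3")
  if (!is.null(mr)) {
    bmr <- compute_baseline(mr$time_h, mr$intensity, bw)
    out$t_degeneration <- detect_continuity_loss(mr$time_h, mr$intensity, bmr,
                                                 drop = config$mruby_drop,
                                                 sustain = config$sustain_frames)
  }
  pv <- getch("PercevalHR")
  if (!is.null(pv) && max(pv$time_h) >= config$perceval_at_h) {
    bpv <- compute_baseline(pv$time_h, pv$intensity, bw)
    out$perceval_decline_pct <- perceval_decline(pv$time_h, pv$intensity, bpv,
                                                 at_time = config$perceval_at_h)
  }
  out$qc <- paste(qc, collapse = "; ")
  out
}
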