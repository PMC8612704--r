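#' Simulate per-channel fluorescence traces for one axon
#'
#' Renders the multi-channel intensity time series implied by an event
#' schedule, at the per-channel acquisition cadences, with multiplicative
#' log-normal frame noise. Channel phenomenology:
#' \itemize{
#'   \item \strong{GCaMP6}: stable baseline, a two-frame injury transient at
#'     t = 0 that clears, then a sustained >= 2-fold rise from
#'     \code{t_ca_onset} persisting until fragmentation.
#'   \item \strong{TMRM}: stable, a single drastic (40\%) frame-to-frame drop
#'     at \code{t_tmrm_drop}, then a steady 5\%-per-frame decline.
#'   \item \strong{PercevalHR}: follows the logistic relative-ATP curve
#'     through the monotone ATP-to-sensor map (a 60\% ATP drop reads as a
#'     ~70\% signal drop).
#'   \item \strong{mRuby3}: stable until \code{t_degeneration}, where it
#'     falls below half baseline and keeps declining; near zero after
#'     fragmentation.
#'   \item \strong{AnnexinV}: at its small pseudo-baseline until
#'     \code{t_ps_exposure}, then a rapid sustained rise.
#' }
#'
#' @param schedule one-row \code{event_schedule} (use
#'   \code{\link{sample_event_schedule}}; event-free control schedules give
#'   flat noisy traces).
#' @param params \code{\link{cascade_params}}.
#' @param channels channels to render (default: all five).
#' @param t_end end of acquisition in hours; defaults to one hour past
#'   fragmentation (or 12 h for event-free axons).
#' @param cadences_min optional named vector overriding the per-channel frame
#'   intervals in minutes (the acquisition designs differ between
#'   experiments: e.g. GCaMP6 once per minute when paired with mitochondrial
#'   bouts, every 10 min when paired with TMRM).
#' @param cccp logical; render the PercevalHR validation condition in which
#'   ATP is forced linearly down by 60\% over 2 h (CCCP mode) instead of the
#'   injury schedule.
#' @return A data frame (class \code{axon_traces}) with columns
#'   \code{axon_id}, \code{channel}, \code{time_h}, \code{intensity}, and a
#'   \code{baseline_window} attribute (pre-injury window, hours).
#' @examples
#' p <- cascade_params()
#' set.seed(7)
#' tr <- simulate_traces(sample_event_schedule(p, "ax1"), p)
#' head(tr)
#' @export
simulate_traces <- function(schedule, params,
                            channels = names(params$cadences_min),
                            t_end = NULL, cadences_min = NULL, cccp = FALSE) {
  validate_cascade_params(params)
  stopifnot(nrow(schedule) == 1)
  bad <- setdiff(channels, names(params$cadences_min))
  if (length(bad) > 0)
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cad <- params$cadences_min
  if (!is.null(cadences_min)) cad[names(cadences_min)] <- cadences_min
  if (is.null(t_end))
    t_end <- if (is.finite(schedule$t_fragmentation))
      schedule$t_fragmentation + 1 else 12
  injured <- is.finite(schedule$t_mito_stop)
  cv <- params$frame_noise_cv

  out <- lapply(channels, function(ch) {
    dt <- cad[[ch]] / 60
    t <- seq(-0.5, t_end, by = dt)
    B <- params$baselines[[ch]]
    s <- switch(ch,
      GCaMP6 = {
        x <- rep(B, length(t))
        if (injured) x[t >= 0 & t < 2 * dt] <- 2.5 * B
        i2 <- t >= schedule$t_ca_onset & t <= schedule$t_fragmentation
        x[i2] <- 3.5 * B
        x[t > schedule$t_fragmentation] <- 1.2 * B
        x
      },
      TMRM = {
        x <- rep(B, length(t))
        k <- which(t >= schedule$t_tmrm_drop)
        if (length(k) > 0) {
          i <- k[1]
          x[i:length(t)] <- 0.60 * B * 0.95^(seq_len(length(t) - i + 1) - 1)
        }
        x
      },
      PercevalHR = {
        a <- if (cccp) 1 - 0.3 * pmin(pmax(t, 0), 2) else atp_level(t, schedule)
        B * perceval_from_atp(a)
      },
      mRuby3 = {
        x <- rep(B, length(t))
        k <- which(t >= schedule$t_degeneration)
        if (length(k) > 0) {
          i <- k[1]
          x[i:length(t)] <- 0.45 * B * 0.92^(seq_len(length(t) - i + 1) - 1)
        }
        x[t > schedule$t_fragmentation] <- pmin(
          x[t > schedule$t_fragmentation], 0.08 * B)
        x
      },
      AnnexinV = {
        x <- rep(B, length(t))
        k <- which(t >= schedule$t_ps_exposure)
        if (length(k) > 0) {
          i <- k[1]
          x[i:length(t)] <- pmin(4 * B * 1.3^(seq_len(length(t) - i + 1) - 1),
                                 10 * B)
        }
        x
      })
    data.frame(axon_id = schedule$axon_id, channel = ch, time_h = t,
               intensity = s * .frame_noise(length(t), cv),
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, out)
  rownames(tr) <- NULL
  attr(tr, "baseline_window") <- c(-0.5, 0)
  class(tr) <- c("axon_traces", "data.frame")
  tr
}
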