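#' Sample a per-axon event schedule
#'
#' Draws the ground-truth event times for one injured axon: the latent crisis
#' time (complete mitochondrial arrest) from the truncated-normal crisis
#' distribution, then the downstream events by adding the configured offsets,
#' clipped where necessary so that the cascade order
#' \code{t_atp_onset <= t_mito_stop <= t_tmrm_drop <= t_ca_onset <=
#' t_ps_exposure <= t_degeneration <= t_fragmentation} always holds (ties are
#' allowed). The ATP-decline onset and the per-axon ATP time scale are derived
#' from the logistic ATP model anchored at the crisis time.
#'
#' With every spread parameter set to zero the schedule is the deterministic
#' cascade. For an uninjured control axon (\code{injured = FALSE}) all event
#' times are \code{Inf}: no cascade event occurs during any finite
#' observation window.
#'
#' @param params a \code{\link{cascade_params}} object.
#' @param axon_id identifier stored in the schedule.
#' @param injured logical; \code{FALSE} yields the event-free control mode.
#' @return A one-row data frame of class \code{event_schedule} with columns
#'   \code{axon_id}, \code{t_injury}, \code{t_atp_onset}, \code{t_mito_stop},
#'   \code{t_tmrm_drop}, \code{t_ca_onset}, \code{t_ps_exposure},
#'   \code{t_degeneration}, \code{t_fragmentation} (hours post-injury) plus
#'   the simulator-internal columns \code{atp_tau}, \code{atp_t_half} and
#'   \code{motility_gamma}.
#' @examples
#' p <- cascade_params()
#' set.seed(1)
#' sample_event_schedule(p, "axon01")
#' @export
sample_event_schedule <- function(params, axon_id = "axon1", injured = TRUE) {
  validate_cascade_params(params)
  if (!injured) {
    s <- data.frame(axon_id = axon_id, t_injury = 0, t_atp_onset = Inf,
                    t_mito_stop = Inf, t_tmrm_drop = Inf, t_ca_onset = Inf,
                    t_ps_exposure = Inf, t_degeneration = Inf,
                    t_fragmentation = Inf, atp_tau = params$atp$tau,
                    atp_t_half = Inf,
                    motility_gamma = params$motility$gamma,
                    stringsAsFactors = FALSE)
    class(s) <- c("event_schedule", "data.frame")
    return(s)
  }
  ct <- params$crisis_time
  t_stop <- .rtruncnorm(1, ct["mean"], ct["sd"], ct["min"], ct["max"])

  atp <- params$atp
  tau <- atp$tau * exp(if (atp$tau_sd > 0) stats::rnorm(1, 0, atp$tau_sd) else 0)
  # logistic A(t) = 1/(1 + exp((t - t_half)/tau)) pinned to arrest_level at t_stop
  lo <- function(q) log((1 - q) / q)
  t_half <- t_stop - tau * lo(atp$arrest_level)
  t_atp_onset <- if (tau == 0) t_stop else t_half - tau * lo(1 - atp$onset_level)
  t_atp_onset <- min(max(t_atp_onset, 0), t_stop)

  dca <- max(.rspread(params$offset_mito_stop_to_ca), 0)
  t_ca <- t_stop + dca
  dtm <- .rspread(params$offset_tmrm_to_ca_min) / 60
  t_tmrm <- max(t_ca - min(max(dtm, 0), dca), t_stop)
  dps <- max(.rspread(params$offset_ca_to_ps), 0)
  t_ps <- t_ca + dps
  ddeg <- max(.rspread(params$offset_ca_to_degeneration), 0)
  t_deg <- max(t_ca + ddeg, t_ps)
  t_frag <- t_deg + max(.rspread(params$fragmentation_delay), 0)

  gm <- params$motility
  gamma <- gm$gamma * exp(if (gm$gamma_sd > 0) stats::rnorm(1, 0, gm$gamma_sd) else 0)
  gamma <- min(gamma, 1)

  s <- data.frame(axon_id = axon_id, t_injury = 0, t_atp_onset = t_atp_onset,
                  t_mito_stop = t_stop, t_tmrm_drop = t_tmrm, t_ca_onset = t_ca,
                  t_ps_exposure = t_ps, t_degeneration = t_deg,
                  t_fragmentation = t_frag, atp_tau = tau, atp_t_half = t_half,
                  motility_gamma = gamma, stringsAsFactors = FALSE)
  rownames(s) <- NULL
  class(s) <- c("event_schedule", "data.frame")
  validate_schedule(s)
  s
}

.rspread <- function(ms) {
  if (ms["sd"] == 0) unname(ms["mean"]) else stats::rnorm(1, ms["mean"], ms["sd"])
}

#' Check the cascade ordering invariant of a schedule
#'
#' @param schedule an \code{event_schedule} data frame (one or more rows).
#' @return the schedule, invisibly; errors if any row violates the event order.
#' @export
validate_schedule <- function(schedule) {
  cols <- c("t_atp_onset", "t_mito_stop", "t_tmrm_drop", "t_ca_onset",
            "t_ps_exposure", "t_degeneration", "t_fragmentation")
  miss <- setdiff(cols, names(schedule))
  if (length(miss) > 0)
    stop("schedule lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(schedule[, cols])
  ok <- apply(m, 1L, function(r) all(diff(r) >= -1e-9) || all(!is.finite(r)))
  if (!all(ok))
    stop("cascade ordering violated for axon(s): ",
         paste(schedule$axon_id[!ok], collapse = ", "), call. = FALSE)
  invisible(schedule)
}

#' Relative ATP level of an axon
#'
#' Evaluates the per-axon logistic ATP model at the requested times. The
#' curve equals 1 long before the decline, passes \code{onset_level} at the
#' scheduled ATP-onset time and \code{arrest_level} exactly at the crisis
#' time (\code{t_mito_stop}).
#'
#' @param t times in hours (vector).
#' @param schedule a one-row \code{event_schedule}.
#' @return relative ATP in (0, 1], same length as \code{t}.
#' @export
atp_level <- function(t, schedule) {
  stopifnot(nrow(schedule) == 1)
  tau <- schedule$atp_tau
  th <- schedule$atp_t_half
  if (!is.finite(th)) return(rep(1, length(t)))
  if (tau == 0) return(ifelse(t < th, 1, 1e-6))
  1 / (1 + exp((t - th) / tau))
}

# monotone piecewise-linear map from relative ATP to relative PercevalHR
# signal, anchored at (0,0), (0.4, 0.3) and (1,1): a 60% ATP drop reads out
# as a ~70% sensor drop.
perceval_from_atp <- function(atp_rel) {
  stats::approx(x = c(0, 0.4, 1), y = c(0, 0.3, 1),
                xout = pmin(pmax(atp_rel, 0), 1), rule = 2)$y
}
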