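#' Cascade generator parameters
#'
#' Builds the parameter set that drives the synthetic single-axon cohort
#' generator. The defaults encode the statistical structure of the
#' injury-induced, SARM1-dependent degeneration cascade as measured in live
#' single-axon imaging: a per-axon latent "crisis" time (the moment all
#' mitochondria arrest) drawn from a truncated normal, followed by fixed-order
#' offsets to calcium influx, phosphatidylserine exposure and loss of axon
#' continuity, with the TMRM drastic drop placed shortly before calcium
#' influx. Relative ATP follows a per-axon logistic decline that reaches the
#' arrest level exactly at the crisis time, and mitochondrial motility is
#' coupled to ATP through a power law (see Details).
#'
#' @param crisis_time named numeric, \code{c(mean, sd, min, max)} in hours:
#'   distribution of the per-axon mitochondrial-arrest time (truncated
#'   normal). Default mean 5.5 h, sd 1.5 h, support 3.5--10 h, matching the
#'   observed spread of second-calcium-peak onsets (just under 4 h to nearly
#'   10 h post-axotomy).
#' @param offset_mito_stop_to_ca named numeric \code{c(mean, sd)} in hours:
#'   interval from mitochondrial arrest to calcium-influx onset. Default mean
#'   0.42 h; sd 0.06 h so that n = 9 cohorts reproduce the reported SEM of
#'   0.02 h (sd = SEM * sqrt(n)).
#' @param offset_tmrm_to_ca_min named numeric \code{c(mean, sd)} in
#'   \emph{minutes}: interval from the TMRM drastic drop to calcium onset.
#'   Default mean 7.9 min, sd 4.0 min, calibrated so that with 10-min
#'   acquisition frames the drop lands strictly one frame before calcium in
#'   about 5/7 of axons and in the same frame in about 2/7.
#' @param offset_ca_to_ps named numeric \code{c(mean, sd)} in hours: calcium
#'   onset to phosphatidylserine (Annexin-V) exposure. Default mean 0.51 h,
#'   sd 0.1265 h (SEM 0.04 h at n = 10).
#' @param offset_ca_to_degeneration named numeric \code{c(mean, sd)} in
#'   hours: calcium onset to the beginning of axon degeneration (sustained
#'   >50\% mRuby3 loss). Default mean 100 min (1.667 h), sd 0.25 h.
#' @param fragmentation_delay named numeric \code{c(mean, sd)} in hours:
#'   interval from the beginning of degeneration to full fragmentation. The
#'   fragmentation endpoint is an imaging convention rather than a sharply
#'   defined quantity; the default 0.25 h is configurable.
#' @param atp list: \code{tau} (h), the time scale of the logistic ATP
#'   decline; \code{tau_sd}, log-normal sd of the per-axon time scale;
#'   \code{arrest_level}, relative ATP at which mitochondria arrest;
#'   \code{onset_level}, relative ATP defining the scheduled ATP-decline
#'   onset time.
#' @param motility list: \code{baseline_fraction}, fraction of mitochondria
#'   mobile before injury; \code{n_mito}, mitochondria per imaged axon
#'   segment (constant across injury -- injury does not change the count);
#'   \code{gamma}, exponent coupling relative mobile fraction to relative
#'   ATP (\code{frac = atp^gamma}, gamma < 1 keeps the motility drop below
#'   the ATP drop in every axon); \code{gamma_sd}, log-normal per-axon jitter
#'   of gamma; \code{stall_jitter_sd_h}, independent per-mitochondrion noise
#'   (h, sd) on individual stall times around the coupling curve
#'   (mitochondria already at the arrest ATP level stall collectively at the
#'   crisis time, so the true arrest time is unaffected);
#'   \code{speed_um_per_bout}, \code{c(min, max)} of the net
#'   distance a mobile mitochondrion covers in one 300-s bout;
#'   \code{jitter_sd_um}, per-frame positional jitter of stationary
#'   mitochondria.
#' @param frame_noise_cv coefficient of variation of the multiplicative
#'   log-normal per-frame intensity noise applied to every channel. Default
#'   0.10 (fluorescence fluctuates ~10\% between frames).
#' @param cadences_min named numeric, frame interval in minutes per channel.
#' @param bout named numeric \code{c(frame_interval_s, n_frames,
#'   spacing_min)}: kymograph bouts are \code{n_frames} frames at
#'   \code{frame_interval_s} seconds (default 60 x 5 s = 300 s), repeated
#'   every \code{spacing_min} minutes.
#' @param baselines named numeric, pre-injury mean intensity (a.u.) per
#'   channel; the Annexin-V entry is the small positive pseudo-baseline used
#'   for fold-change calls.
#' @param seed optional integer stored with the parameters; cohort-level
#'   functions use it when no explicit seed is given.
#'
#' @details
#' Relative ATP in axon \eqn{i} is \eqn{A_i(t) = 1/(1 + e^{(t - m_i)/\tau_i}}),
#' with \eqn{m_i} chosen so that \eqn{A_i} reaches \code{arrest_level} exactly
#' at the axon's crisis time. The relative mobile fraction is
#' \eqn{A_i(t)^{\gamma_i}} until the crisis time, at which point all
#' remaining mobile mitochondria arrest together. Because
#' \eqn{A^{\gamma} > A} for \eqn{0 < A < 1} and \eqn{\gamma < 1}, the percent
#' drop in the ATP signal always exceeds the percent drop in the mobile
#' fraction, as observed in every imaged axon.
#'
#' @return An object of class \code{cascade_params} (a validated list).
#' @examples
#' p <- cascade_params()
#' p$offset_mito_stop_to_ca
#' # deterministic cascade: all spread parameters zero
#' p0 <- cascade_params(crisis_time = c(mean = 4, sd = 0, min = 4, max = 4))
#' @export
cascade_params <- function(crisis_time = c(mean = 5.5, sd = 1.5, min = 3.5, max = 10),
                           offset_mito_stop_to_ca = c(mean = 0.42, sd = 0.06),
                           offset_tmrm_to_ca_min = c(mean = 7.9, sd = 4.0),
                           offset_ca_to_ps = c(mean = 0.51, sd = 0.1265),
                           offset_ca_to_degeneration = c(mean = 100 / 60, sd = 0.25),
                           fragmentation_delay = c(mean = 0.25, sd = 0.05),
                           atp = list(tau = 0.7, tau_sd = 0.20,
                                      arrest_level = 0.15, onset_level = 0.9),
                           motility = list(baseline_fraction = 0.3, n_mito = 20,
                                           gamma = 0.5, gamma_sd = 0.4,
                                           stall_jitter_sd_h = 0.95,
                                           speed_um_per_bout = c(min = 6, max = 14),
                                           jitter_sd_um = 0.3),
                           frame_noise_cv = 0.10,
                           cadences_min = c(GCaMP6 = 10, TMRM = 10, PercevalHR = 5,
                                            mRuby3 = 10, AnnexinV = 10),
                           bout = c(frame_interval_s = 5, n_frames = 60, spacing_min = 5),
                           baselines = c(GCaMP6 = 100, TMRM = 100, PercevalHR = 100,
                                         mRuby3 = 200, AnnexinV = 5),
                           seed = NULL) {
  p <- list(crisis_time = .named(crisis_time, c("mean", "sd", "min", "max")),
            offset_mito_stop_to_ca = .named(offset_mito_stop_to_ca, c("mean", "sd")),
            offset_tmrm_to_ca_min = .named(offset_tmrm_to_ca_min, c("mean", "sd")),
            offset_ca_to_ps = .named(offset_ca_to_ps, c("mean", "sd")),
            offset_ca_to_degeneration = .named(offset_ca_to_degeneration, c("mean", "sd")),
            fragmentation_delay = .named(fragmentation_delay, c("mean", "sd")),
            atp = atp, motility = motility,
            frame_noise_cv = frame_noise_cv,
            cadences_min = cadences_min, bout = .named(bout,
              c("frame_interval_s", "n_frames", "spacing_min")),
            baselines = baselines, seed = seed)
  class(p) <- "cascade_params"
  validate_cascade_params(p)
  p
}

.named <- function(x, nm) {
  if (is.null(names(x))) names(x) <- nm[seq_along(x)]
  miss <- setdiff(nm, names(x))
  if (length(miss) > 0)
    stop("missing component(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x[nm]
}

#' Validate cascade parameters
#'
#' Checks the invariants of a \code{cascade_params} object: non-negative
#' spreads, a proper crisis-time support, positive cadences and baselines.
#' Called by \code{\link{cascade_params}}; exported so that configurations
#' read from file can be re-validated.
#'
#' @param p a \code{cascade_params} object.
#' @return \code{p}, invisibly; errors on the first violated invariant.
#' @export
validate_cascade_params <- function(p) {
  stopifnot(inherits(p, "cascade_params"))
  sds <- c(p$crisis_time["sd"], p$offset_mito_stop_to_ca["sd"],
           p$offset_tmrm_to_ca_min["sd"], p$offset_ca_to_ps["sd"],
           p$offset_ca_to_degeneration["sd"], p$fragmentation_delay["sd"],
           tau_sd = p$atp$tau_sd, gamma_sd = p$motility$gamma_sd,
           stall_jitter = p$motility$stall_jitter_sd_h)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all spread parameters (sd) must be finite and >= 0", call. = FALSE)
  ct <- p$crisis_time
  if (!(ct["min"] <= ct["max"]))
    stop("crisis_time: min must be <= max", call. = FALSE)
  if (ct["min"] < 0) stop("crisis_time: support must be non-negative", call. = FALSE)
  if (ct["sd"] > 0 && ct["min"] >= ct["max"])
    stop("crisis_time: degenerate support with positive sd", call. = FALSE)
  if (p$atp$tau < 0) stop("atp$tau must be >= 0", call. = FALSE)
  if (p$atp$arrest_level <= 0 || p$atp$arrest_level >= 1)
    stop("atp$arrest_level must lie in (0, 1)", call. = FALSE)
  if (p$atp$onset_level <= p$atp$arrest_level || p$atp$onset_level >= 1)
    stop("atp$onset_level must lie in (arrest_level, 1)", call. = FALSE)
  m <- p$motility
  if (m$baseline_fraction < 0 || m$baseline_fraction > 1)
    stop("motility$baseline_fraction must lie in [0, 1]", call. = FALSE)
  if (m$n_mito < 1) stop("motility$n_mito must be >= 1", call. = FALSE)
  if (m$gamma <= 0 || m$gamma > 1)
    stop("motility$gamma must lie in (0, 1]", call. = FALSE)
  if (p$frame_noise_cv < 0) stop("frame_noise_cv must be >= 0", call. = FALSE)
  if (any(p$cadences_min <= 0)) stop("cadences must be positive", call. = FALSE)
  if (any(p$bout <= 0)) stop("bout settings must be positive", call. = FALSE)
  if (any(p$baselines <= 0)) stop("baselines must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Cascade generator parameters\n")
  cat(sprintf("  crisis time: %.2f +/- %.2f h (support %.1f-%.1f h)\n",
              x$crisis_time["mean"], x$crisis_time["sd"],
              x$crisis_time["min"], x$crisis_time["max"]))
  cat(sprintf("  mito arrest -> Ca: %.2f +/- %.2f h\n",
              x$offset_mito_stop_to_ca["mean"], x$offset_mito_stop_to_ca["sd"]))
  cat(sprintf("  TMRM drop -> Ca: %.1f +/- %.1f min\n",
              x$offset_tmrm_to_ca_min["mean"], x$offset_tmrm_to_ca_min["sd"]))
  cat(sprintf("  Ca -> PS exposure: %.2f +/- %.2f h\n",
              x$offset_ca_to_ps["mean"], x$offset_ca_to_ps["sd"]))
  cat(sprintf("  Ca -> degeneration: %.2f +/- %.2f h\n",
              x$offset_ca_to_degeneration["mean"], x$offset_ca_to_degeneration["sd"]))
  cat(sprintf("  frame noise cv: %.2f\n", x$frame_noise_cv))
  invisible(x)
}

#' Event-detection configuration
#'
#' Thresholds used by the event detectors, each with its operational default:
#' calcium influx is a >= 2-fold sustained GCaMP6 rise over baseline; the TMRM
#' drastic drop is a > 30\% frame-to-frame reduction; the beginning of axon
#' degeneration is a sustained > 50\% mRuby3 reduction; Annexin-V onset is a
#' >= 2-fold sustained rise over its pseudo-baseline; axons are degenerated at
#' DI > 0.4 and fail baseline QC at DI >= 0.2; mitochondria are mobile at a
#' net displacement > 5 um.
#'
#' @param ca_fold fold-change threshold for calcium influx (>=, default 2).
#' @param annexin_fold fold-change threshold for Annexin-V onset (>=, default 2).
#' @param tmrm_drop fractional frame-to-frame reduction for the TMRM drastic
#'   drop (strict >, default 0.30).
#' @param mruby_drop fractional reduction from baseline that marks the
#'   beginning of degeneration (strict >, default 0.50).
#' @param sustain_frames number of consecutive frames a threshold crossing
#'   must persist before it is called (default 2); suppresses the ~10\%
#'   frame-to-frame fluctuation.
#' @param exclude_first_peak_h window after injury excluded from calcium-onset
#'   detection so the injury-site transient is not called (default 0.5 h).
#' @param perceval_at_h time at which the PercevalHR percent decline is read
#'   out (default 3.5 h post-axotomy).
#' @param baseline_window pre-injury window (h) used for channel baselines.
#' @param motility_threshold_um net-displacement threshold (strict >) for a
#'   mobile mitochondrion, in micrometres (default 5).
#' @param di_degenerated DI above which an axon is degenerated (strict >, 0.4).
#' @param di_baseline_max DI at/above which a baseline axon fails QC (0.2).
#' @param circularity_min minimum circularity (4*pi*area/perimeter^2) for a
#'   particle to count as fragment-like (default 0.2).
#' @param min_particle_px connected components smaller than this many pixels
#'   are ignored (default 4).
#' @return A named list of class \code{detection_config}.
#' @export
detection_config <- function(ca_fold = 2, annexin_fold = 2, tmrm_drop = 0.30,
                             mruby_drop = 0.50, sustain_frames = 2,
                             exclude_first_peak_h = 0.5, perceval_at_h = 3.5,
                             baseline_window = c(-0.5, 0),
                             motility_threshold_um = 5,
                             di_degenerated = 0.4, di_baseline_max = 0.2,
                             circularity_min = 0.2, min_particle_px = 4) {
  cfg <- list(ca_fold = ca_fold, annexin_fold = annexin_fold,
              tmrm_drop = tmrm_drop, mruby_drop = mruby_drop,
              sustain_frames = sustain_frames,
              exclude_first_peak_h = exclude_first_peak_h,
              perceval_at_h = perceval_at_h, baseline_window = baseline_window,
              motility_threshold_um = motility_threshold_um,
              di_degenerated = di_degenerated, di_baseline_max = di_baseline_max,
              circularity_min = circularity_min, min_particle_px = min_particle_px)
  stopifnot(ca_fold > 0, annexin_fold > 0, tmrm_drop > 0, tmrm_drop < 1,
            mruby_drop > 0, mruby_drop < 1, sustain_frames >= 1,
            motility_threshold_um >= 0)
  class(cfg) <- "detection_config"
  cfg
}

# log-normal multiplicative frame noise with unit mean and the requested cv
.frame_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# truncated-normal draws by inverse cdf (exact, vectorised)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, a, b), mean, sd)
}
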