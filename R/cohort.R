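#' Generate a synthetic single-axon cohort
#'
#' Draws \code{n} independent axons -- event schedule plus the observables
#' of the chosen acquisition protocol -- with per-axon sub-seeds derived
#' deterministically from \code{seed}, so the same seed always reproduces
#' the identical cohort.
#'
#' The protocols mirror the acquisition designs used for the different
#' single-axon experiments:
#' \describe{
#'   \item{\code{"calcium_annexin"}}{GCaMP6, Annexin-V and mRuby3 traces at
#'     their default cadences (the calcium / phosphatidylserine /
#'     degeneration ordering experiments).}
#'   \item{\code{"calcium_tmrm"}}{GCaMP6 and TMRM traces, both every 10 min
#'     (the depolarization-versus-calcium frame-ordering experiment).}
#'   \item{\code{"calcium_mito"}}{Mitochondrial kymograph bouts plus a
#'     GCaMP6 trace acquired once per minute (the arrest-versus-calcium
#'     experiment: calcium imaging is switched to 1/min once mitochondria
#'     stop).}
#'   \item{\code{"atp_motility"}}{PercevalHR every 5 min until 3.5 h plus
#'     kymograph bouts every 5 min from 3.5 h until arrest (the ATP /
#'     motility coupling experiment).}
#'   \item{\code{"full"}}{all five channels plus bouts (and images when
#'     \code{images = TRUE}).}
#' }
#'
#' @param n number of axons (>= 1).
#' @param params \code{\link{cascade_params}}.
#' @param seed integer seed; defaults to \code{params$seed}.
#' @param protocol acquisition protocol, see Details.
#' @param injured logical; \code{FALSE} generates the event-free control
#'   cohort.
#' @param images logical; also render morphology image series (protocols
#'   \code{"full"} and \code{"calcium_annexin"}).
#' @param positions logical; keep full per-frame kymograph positions
#'   (default \code{FALSE} stores track endpoints, which determine the
#'   net-displacement motility calls exactly).
#' @return list of class \code{axon_cohort}: \code{schedules} (data frame),
#'   \code{traces} (long data frame), \code{bouts} (named list per axon, or
#'   NULL), \code{images} (named list per axon, or NULL), \code{params},
#'   \code{protocol}, \code{seed}.
#' @examples
#' co <- generate_cohort(3, cascade_params(), seed = 11,
#'                       protocol = "calcium_annexin")
#' co$schedules[, c("axon_id", "t_ca_onset", "t_ps_exposure")]
#' @export
generate_cohort <- function(n, params = cascade_params(), seed = params$seed,
                            protocol = c("calcium_annexin", "calcium_tmrm",
                                         "calcium_mito", "atp_motility", "full"),
                            injured = TRUE, images = FALSE, positions = FALSE) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  protocol <- match.arg(protocol)
  validate_cascade_params(params)
  if (is.null(seed)) stop("a seed is required for reproducible cohorts",
                          call. = FALSE)
  set.seed(as.integer(seed))
  sub <- sample.int(2147483646L, n)
  ids <- sprintf("axon%03d", seq_len(n))

  schedules <- vector("list", n); traces <- vector("list", n)
  bouts <- NULL; imgs <- NULL
  want_bouts <- protocol %in% c("calcium_mito", "atp_motility", "full")
  want_images <- images && protocol %in% c("calcium_annexin", "full")
  if (want_bouts) bouts <- stats::setNames(vector("list", n), ids)
  if (want_images) imgs <- stats::setNames(vector("list", n), ids)

  for (i in seq_len(n)) {
    set.seed(sub[i])
    sch <- sample_event_schedule(params, ids[i], injured = injured)
    schedules[[i]] <- sch
    traces[[i]] <- switch(protocol,
      calcium_annexin = simulate_traces(sch, params,
        channels = c("GCaMP6", "AnnexinV", "mRuby3")),
      calcium_tmrm = simulate_traces(sch, params,
        channels = c("GCaMP6", "TMRM")),
      calcium_mito = simulate_traces(sch, params, channels = "GCaMP6",
        cadences_min = c(GCaMP6 = 1),
        t_end = if (is.finite(sch$t_ca_onset)) sch$t_ca_onset + 0.5 else 12),
      atp_motility = simulate_traces(sch, params, channels = "PercevalHR",
        t_end = 3.6),
      full = simulate_traces(sch, params))
    if (want_bouts)
      bouts[[i]] <- simulate_kymograph_bouts(sch, params,
        bout_schedule(sch, params), positions = positions)
    if (want_images)
      imgs[[i]] <- simulate_axon_images(sch, params,
        times = c(0, sch$t_ca_onset + 0.5, sch$t_fragmentation + 0.5))
  }
  schedules <- do.call(rbind, schedules)
  class(schedules) <- c("event_schedule", "data.frame")
  traces <- do.call(rbind, traces)
  structure(list(schedules = schedules, traces = traces, bouts = bouts,
                 images = imgs, params = params, protocol = protocol,
                 seed = as.integer(seed)),
            class = "axon_cohort")
}

#' @export
print.axon_cohort <- function(x, ...) {
  cat(sprintf("Synthetic axon cohort: %d axons, protocol '%s', seed %d\n",
              nrow(x$schedules), x$protocol, x$seed))
  invisible(x)
}

#' Run the event detectors and motility analysis over a cohort
#'
#' Applies \code{\link{call_axon_events}} to every axon's traces and, when
#' kymograph bouts are present, summarises them, estimates the arrest time
#' and derives the ATP/motility pairing quantities (percent motility drop at
#' the PercevalHR readout time and the remaining time to arrest).
#'
#' @param cohort an \code{axon_cohort} (or any list with \code{traces} and
#'   optionally \code{bouts} in the same layout).
#' @param config \code{\link{detection_config}}.
#' @return data frame with one row per axon: the trace event calls plus,
#'   when bouts exist, \code{t_mito_stop} (estimated arrest time),
#'   \code{baseline_mobile_fraction}, \code{motility_drop_pct} and
#'   \code{time_to_arrest_h}. Bout summaries are attached as the
#'   \code{"bout_summaries"} attribute.
#' @export
analyze_cohort <- function(cohort, config = detection_config()) {
  traces <- cohort$traces
  ids <- unique(traces$axon_id)
  calls <- do.call(rbind, lapply(ids, function(id) {
    call_axon_events(traces[traces$axon_id == id, , drop = FALSE], config)
  }))
  sums <- NULL
  if (!is.null(cohort$bouts)) {
    thr <- config$motility_threshold_um
    sums <- lapply(cohort$bouts, summarize_bouts, threshold_um = thr)
    km <- do.call(rbind, lapply(ids, function(id) {
      s <- sums[[id]]
      if (is.null(s)) return(data.frame(t_mito_stop = NA_real_,
                                        baseline_mobile_fraction = NA_real_,
                                        motility_drop_pct = NA_real_,
                                        time_to_arrest_h = NA_real_))
      arr <- arrest_time(s)
      pre <- s$bout_start < 0 & !s$degenerate
      f0 <- if (any(pre)) mean(s$mobile_fraction[pre]) else NA_real_
      post <- which(s$bout_start >= config$perceval_at_h)
      f35 <- if (length(post) > 0) s$mobile_fraction[post[1]] else NA_real_
      drop <- if (is.finite(f0) && f0 > 0 && is.finite(f35))
        min(max(100 * (1 - f35 / f0), 0), 100) else NA_real_
      data.frame(t_mito_stop = arr, baseline_mobile_fraction = f0,
                 motility_drop_pct = drop,
                 time_to_arrest_h = if (is.finite(arr))
                   arr - config$perceval_at_h else NA_real_)
    }))
    calls <- cbind(calls, km)
  }
  rownames(calls) <- NULL
  attr(calls, "bout_summaries") <- sums
  calls
}
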