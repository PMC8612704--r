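.event_col <- function(calls, event) {
  col <- if (event %in% names(calls)) event else paste0("t_", event)
  if (!col %in% names(calls))
    stop("event '", event, "' not found in the calls table", call. = FALSE)
  calls[[col]]
}

#' Signed time difference between two events across a cohort
#'
#' For every axon in which both events were called, computes
#' \eqn{\Delta T = t_{later} - t_{earlier}} (positive when the claimed order
#' holds, negative when it is violated) and summarises the cohort as
#' mean +/- SEM. Axons missing either event are excluded pairwise and
#' counted.
#'
#' @param calls cohort calls: a data frame with one row per axon and event
#'   columns named \code{t_<event>} (e.g. from \code{\link{analyze_cohort}}).
#' @param earlier,later event names (\code{"mito_stop"}, \code{"ca_onset"},
#'   \code{"tmrm_drop"}, \code{"ps_exposure"}, \code{"degeneration"}, ...).
#' @return object of class \code{delta_t_summary}: \code{pair},
#'   \code{delta_t} (per-axon, h), \code{n}, \code{n_excluded}, \code{mean},
#'   \code{sd}, \code{sem} (sd/sqrt(n)).
#' @examples
#' calls <- data.frame(t_mito_stop = c(4.0, 4.5), t_ca_onset = c(4.40, 4.94))
#' delta_t(calls, "mito_stop", "ca_onset")$mean  # 0.42
#' @export
delta_t <- function(calls, earlier, later) {
  te <- .event_col(calls, earlier)
  tl <- .event_col(calls, later)
  ok <- is.finite(te) & is.finite(tl)
  if (!any(ok))
    stop("no axon has both '", earlier, "' and '", later, "' called",
         call. = FALSE)
  dt <- tl[ok] - te[ok]
  n <- length(dt)
  structure(list(pair = c(earlier = earlier, later = later), delta_t = dt,
                 n = n, n_excluded = sum(!ok), mean = mean(dt),
                 sd = stats::sd(dt),
                 sem = if (n > 1) stats::sd(dt) / sqrt(n) else NA_real_),
            class = "delta_t_summary")
}

#' @export
print.delta_t_summary <- function(x, ...) {
  cat(sprintf("deltaT(%s -> %s): %.3f +/- %.3f h (mean +/- SEM, n = %d, %d excluded)\n",
              x$pair["earlier"], x$pair["later"], x$mean, x$sem, x$n,
              x$n_excluded))
  invisible(x)
}

#' Frame-level ordering fraction of an event pair
#'
#' Bins both event times to acquisition frames of the given interval and
#' counts, across axons with both events, how often the earlier event's
#' frame strictly precedes the later event's frame, how often both fall in
#' the same frame, and how often the order is reversed. This is the
#' statistic behind "the drop occurs one frame prior ... in five out of
#' seven axons".
#'
#' @param calls cohort calls data frame (see \code{\link{delta_t}}).
#' @param earlier,later event names.
#' @param frame_interval_min acquisition frame interval in minutes
#'   (default 10, the TMRM/GCaMP6 cadence).
#' @return list of class \code{ordering_fraction}: \code{n},
#'   \code{n_strict_before}, \code{n_same_frame}, \code{n_after},
#'   \code{fraction_strict}.
#' @export
ordering_fraction <- function(calls, earlier, later, frame_interval_min = 10) {
  if (frame_interval_min <= 0) stop("frame interval must be positive", call. = FALSE)
  te <- .event_col(calls, earlier)
  tl <- .event_col(calls, later)
  ok <- is.finite(te) & is.finite(tl)
  bin <- function(t) floor(t * 60 / frame_interval_min + 1e-6)
  be <- bin(te[ok]); bl <- bin(tl[ok])
  n <- sum(ok)
  structure(list(n = n, n_strict_before = sum(be < bl),
                 n_same_frame = sum(be == bl), n_after = sum(be > bl),
                 fraction_strict = if (n > 0) sum(be < bl) / n else NA_real_),
            class = "ordering_fraction")
}

#' @export
print.ordering_fraction <- function(x, ...) {
  cat(sprintf("strict before: %d/%d (%.2f%%), same frame: %d, after: %d\n",
              x$n_strict_before, x$n, 100 * x$fraction_strict,
              x$n_same_frame, x$n_after))
  invisible(x)
}

#' Ordinary least-squares fit with R-squared
#'
#' Simple linear regression y ~ x with \eqn{R^2 = 1 - SS_{res}/SS_{tot}}
#' (unadjusted). Constant x is rejected; constant y returns
#' \code{r_squared = 0} with a flag.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class \code{regression_result}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n}, \code{flag}.
#' @examples
#' linear_fit(1:3, c(1, 2, 2))  # slope 0.5, R^2 0.75
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: slope undefined", call. = FALSE)
  flag <- ""
  if (stats::sd(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          n = length(x), flag = "constant response"),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x), flag = flag),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f, R^2 = %.3f, n = %d%s\n", x$slope,
              x$intercept, x$r_squared, x$n,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' ATP-loss versus mitochondrial-stalling analysis
#'
#' Per axon, pairs the percent PercevalHR decline at 3.5 h post-axotomy with
#' (a) the percent drop in the fraction of mobile mitochondria at 3.5 h and
#' (b) the time from 3.5 h until complete arrest, then regresses each
#' against the ATP decline. Also counts axons violating the expectation that
#' the ATP drop is at least as large as the motility drop. Axons with no
#' observed arrest are excluded from the time-to-arrest fit and flagged.
#'
#' @param axons data frame with one row per axon and columns
#'   \code{perceval_decline_pct}, \code{motility_drop_pct},
#'   \code{time_to_arrest_h} (as produced by \code{\link{analyze_cohort}}
#'   on an ATP/motility cohort).
#' @return list of class \code{atp_motility_result}: \code{table} (the
#'   paired per-axon values), \code{fit_stall}, \code{fit_time_to_arrest}
#'   (\code{\link{linear_fit}} results), \code{n_violation},
#'   \code{n_no_arrest}.
#' @export
atp_motility_analysis <- function(axons) {
  need <- c("perceval_decline_pct", "motility_drop_pct", "time_to_arrest_h")
  miss <- setdiff(need, names(axons))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ok <- is.finite(axons$perceval_decline_pct) & is.finite(axons$motility_drop_pct)
  tab <- axons[ok, , drop = FALSE]
  viol <- sum(tab$motility_drop_pct > tab$perceval_decline_pct)
  no_arrest <- sum(!is.finite(tab$time_to_arrest_h))
  structure(list(table = tab,
                 fit_stall = linear_fit(tab$perceval_decline_pct,
                                        tab$motility_drop_pct),
                 fit_time_to_arrest = linear_fit(tab$perceval_decline_pct,
                                                 tab$time_to_arrest_h),
                 n_violation = viol, n_no_arrest = no_arrest),
            class = "atp_motility_result")
}

#' Cohort-level summary report
#'
#' Assembles the temporal-ordering statistics of a cohort: the four cascade
#' \eqn{\Delta T} summaries (mitochondrial arrest to calcium, TMRM drop to
#' calcium, calcium to phosphatidylserine exposure, calcium to
#' degeneration), the TMRM-before-calcium frame-ordering fraction, and --
#' when second-peak columns are present -- the correlations of second-peak
#' initiation, duration and intensity with fragmentation time. Statistics
#' whose events were never called in the cohort (e.g. an event-free control)
#' are reported as not applicable rather than zero. Deterministic given the
#' calls.
#'
#' @param calls cohort calls data frame.
#' @param frame_interval_min frame interval for the ordering fraction
#'   (default 10 min).
#' @return list of class \code{cohort_summary} with elements
#'   \code{delta_t} (named list of \code{delta_t_summary} or \code{NULL}),
#'   \code{ordering}, \code{second_peak}, \code{n_axons}.
#' @export
cohort_report <- function(calls, frame_interval_min = 10) {
  if (nrow(calls) == 0) stop("empty cohort", call. = FALSE)
  pairs <- list(mito_stop_to_ca = c("mito_stop", "ca_onset"),
                tmrm_to_ca = c("tmrm_drop", "ca_onset"),
                ca_to_ps = c("ca_onset", "ps_exposure"),
                ca_to_degeneration = c("ca_onset", "degeneration"))
  dts <- lapply(pairs, function(pr) {
    tryCatch(delta_t(calls, pr[1], pr[2]), error = function(e) NULL)
  })
  ordering <- tryCatch(
    ordering_fraction(calls, "tmrm_drop", "ca_onset", frame_interval_min),
    error = function(e) NULL)
  if (!is.null(ordering) && ordering$n == 0) ordering <- NULL
  sp <- NULL
  spc <- c("sp_initiation", "sp_duration", "sp_intensity", "t_fragmentation")
  if (all(spc %in% names(calls))) {
    okf <- stats::complete.cases(calls[, spc])
    if (sum(okf) >= 3) {
      fr <- calls$t_fragmentation[okf]
      sp <- list(
        cor_initiation = stats::cor(calls$sp_initiation[okf], fr),
        cor_duration = stats::cor(calls$sp_duration[okf], fr),
        cor_intensity = stats::cor(calls$sp_intensity[okf], fr))
    }
  }
  structure(list(delta_t = dts, ordering = ordering, second_peak = sp,
                 n_axons = nrow(calls)), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$n_axons, " axons)\n", sep = "")
  for (nm in names(x$delta_t)) {
    cat("  ", nm, ": ", sep = "")
    if (is.null(x$delta_t[[nm]])) cat("not applicable\n")
    else print(x$delta_t[[nm]])
  }
  if (!is.null(x$ordering)) { cat("  TMRM before Ca: "); print(x$ordering) }
  invisible(x)
}
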