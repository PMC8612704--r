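.canonical_channels <- c(gcamp6 = "GCaMP6", gcamp = "GCaMP6", tmrm = "TMRM",
                         percevalhr = "PercevalHR", perceval = "PercevalHR",
                         mruby3 = "mRuby3", mruby = "mRuby3",
                         annexinv = "AnnexinV", annexin = "AnnexinV",
                         "annexin-v" = "AnnexinV")

#' Write / read a cohort trace table
#'
#' Tidy tab-separated text with columns \code{axon_id}, \code{channel},
#' \code{time_h}, \code{intensity} (UTF-8, "." decimal separator). Reading
#' validates the table: required columns, canonical channel names,
#' non-negative intensities and strictly increasing times within each
#' axon/channel series; malformed rows are reported with their line
#' numbers.
#'
#' @param traces trace data frame.
#' @param path file path.
#' @return \code{read_traces} returns the validated, time-sorted data frame.
#' @export
write_traces <- function(traces, path) {
  utils::write.table(traces[, c("axon_id", "channel", "time_h", "intensity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("axon_id", "channel", "time_h", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("trace table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  canon <- .canonical_channels[tolower(x$channel)]
  bad <- which(is.na(canon))
  if (length(bad) > 0)
    stop("unknown channel name(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  x$channel <- unname(canon)
  bad <- which(!is.finite(x$intensity) | x$intensity < 0)
  if (length(bad) > 0)
    stop("negative or non-finite intensity at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  for (id in unique(x$axon_id)) for (ch in unique(x$channel[x$axon_id == id])) {
    i <- which(x$axon_id == id & x$channel == ch)
    if (is.unsorted(x$time_h[i], strictly = TRUE)) {
      k <- i[which(diff(x$time_h[i]) <= 0)[1] + 1L]
      stop(sprintf("non-increasing time for %s/%s at line %d", id, ch, k + 1L),
           call. = FALSE)
    }
  }
  class(x) <- c("axon_traces", "data.frame")
  attr(x, "baseline_window") <- c(-0.5, 0)
  x
}

#' Write / read per-axon event-time tables
#'
#' One row per axon, one column per event time; a missing event is an empty
#' field. Used for both ground-truth schedules and detected event calls.
#'
#' @param x schedules or calls data frame.
#' @param path file path.
#' @export
write_event_table <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) if (is.numeric(y[[j]]))
    y[[j]][!is.finite(y[[j]])] <- NA
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write / read kymograph track tables
#'
#' Long tab-separated format: \code{axon_id}, \code{bout_start_h},
#' \code{track_id}, \code{frame}, \code{position_um}.
#'
#' @param bouts named list (per axon) of \code{kymo_bout} lists.
#' @param path file path.
#' @return \code{read_track_table} returns the long data frame.
#' @export
write_track_table <- function(bouts, path) {
  rows <- list()
  for (id in names(bouts)) for (b in bouts[[id]]) {
    if (nrow(b$tracks) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(axon_id = id,
      bout_start_h = b$bout_start, b$tracks)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(axon_id = character(), bout_start_h = numeric(),
               track_id = integer(), frame = integer(), position_um = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("axon_id", "bout_start_h", "track_id", "frame", "position_um")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("track table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' Write / read axon morphology images
#'
#' Images are stored as 8-bit grayscale PNG files named
#' \code{<axon_id>_t<time>h.png}; reading parses the time token from the
#' filename and returns a time-sorted series.
#'
#' @param images list of \code{axon_image} objects.
#' @param dir output directory (created if needed).
#' @param axon_id identifier used in the filenames.
#' @return \code{read_images} returns a list of \code{axon_image} objects.
#' @export
write_images <- function(images, dir, axon_id = "axon001") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (im in images) {
    f <- file.path(dir, sprintf("%s_t%gh.png", axon_id, im$time))
    png::writePNG(im$pixels, f)
  }
  invisible(dir)
}

#' @rdname write_images
#' @param pixel_size_um pixel size to attach on read (um/px).
#' @export
read_images <- function(dir, pixel_size_um = 0.3) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no PNG images in ", dir, call. = FALSE)
  tm <- suppressWarnings(as.numeric(sub(".*_t([0-9.eE+-]+)h\\.png$", "\\1",
                                        basename(files))))
  if (any(is.na(tm)))
    stop("cannot parse a time token from: ",
         paste(basename(files)[is.na(tm)], collapse = ", "), call. = FALSE)
  o <- order(tm)
  dims <- NULL
  out <- lapply(o, function(i) {
    px <- png::readPNG(files[i])
    if (length(dim(px)) == 3) px <- px[, , 1]
    if (is.null(dims)) dims <<- dim(px)
    if (!identical(dim(px), dims))
      stop("inconsistent image dimensions: ", basename(files[i]), call. = FALSE)
    structure(list(time = tm[i], pixels = px, pixel_size_um = pixel_size_um,
                   morphology_state = NA_character_), class = "axon_image")
  })
  out
}

#' Write a generated cohort to disk
#'
#' Writes the trace table, ground-truth schedules, kymograph track tables
#' and morphology images of an \code{axon_cohort} into a directory, using
#' the package's standard plain-text formats.
#'
#' @param cohort an \code{axon_cohort} from \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_traces(cohort$traces, file.path(dir, "traces.tsv"))
  write_event_table(cohort$schedules, file.path(dir, "schedules.tsv"))
  if (!is.null(cohort$bouts))
    write_track_table(cohort$bouts, file.path(dir, "tracks.tsv"))
  if (!is.null(cohort$images))
    for (id in names(cohort$images))
      write_images(cohort$images[[id]], file.path(dir, "images"), axon_id = id)
  invisible(dir)
}

#' Read and validate a pipeline configuration
#'
#' JSON mirroring \code{\link{cascade_params}} and
#' \code{\link{detection_config}} plus run settings (\code{n}, \code{seed},
#' \code{protocol}, \code{out_dir}). Unknown keys are rejected so that typos
#' do not silently fall back to defaults.
#'
#' @param path JSON file, or a list with the same structure.
#' @return list of class \code{pipeline_config} with elements \code{n},
#'   \code{seed}, \code{protocol}, \code{out_dir}, \code{params},
#'   \code{detection}.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  known <- c("n", "seed", "protocol", "out_dir", "params", "detection")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$n) || cfg$n < 1)
    stop("configuration must set n >= 1", call. = FALSE)
  if (is.null(cfg$seed)) stop("configuration must set a seed", call. = FALSE)
  pdef <- cascade_params()
  pargs <- cfg$params
  if (!is.null(pargs)) {
    unknown <- setdiff(names(pargs), names(unclass(pdef)))
    if (length(unknown) > 0)
      stop("unknown params key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    params <- unclass(pdef)
    for (nm in names(pargs)) {
      v <- pargs[[nm]]
      if (is.list(params[[nm]]) && !is.list(v)) v <- as.list(v)
      if (!is.null(names(params[[nm]])) && is.null(names(v)) &&
          length(v) == length(params[[nm]])) names(v) <- names(params[[nm]])
      params[[nm]] <- v
    }
    class(params) <- "cascade_params"
    validate_cascade_params(params)
  } else params <- pdef
  ddef <- detection_config()
  dargs <- cfg$detection
  if (!is.null(dargs)) {
    unknown <- setdiff(names(dargs), names(unclass(ddef)))
    if (length(unknown) > 0)
      stop("unknown detection key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    detection <- do.call(detection_config, utils::modifyList(
      as.list(unclass(ddef))[setdiff(names(unclass(ddef)), "")], dargs))
  } else detection <- ddef
  structure(list(n = as.integer(cfg$n), seed = as.integer(cfg$seed),
                 protocol = if (is.null(cfg$protocol)) "calcium_annexin"
                            else cfg$protocol,
                 out_dir = cfg$out_dir, params = params,
                 detection = detection),
            class = "pipeline_config")
}

#' Run the full simulate / detect / order pipeline
#'
#' Generates (or loads) a cohort, runs the event detectors and motility
#' analysis, assembles the cohort report and -- when an output directory is
#' configured -- writes the trace table, event-call table and report (TSV +
#' JSON) to disk. Rerunning with the same configuration reproduces the
#' outputs.
#'
#' @param config a \code{\link{pipeline_config}}, a path to a JSON
#'   configuration, or a plain list with the same fields.
#' @return list: \code{cohort}, \code{calls}, \code{report},
#'   \code{report_json} (the serialised report).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cohort <- generate_cohort(config$n, config$params, seed = config$seed,
                            protocol = config$protocol)
  calls <- analyze_cohort(cohort, config$detection)
  report <- cohort_report(calls)
  js <- jsonlite::toJSON(.report_as_list(report), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_traces(cohort$traces, file.path(config$out_dir, "traces.tsv"))
    write_event_table(cohort$schedules,
                      file.path(config$out_dir, "schedules.tsv"))
    write_event_table(calls, file.path(config$out_dir, "calls.tsv"))
    writeLines(js, file.path(config$out_dir, "report.json"))
    .write_report_tsv(report, file.path(config$out_dir, "report.tsv"))
  }
  list(cohort = cohort, calls = calls, report = report, report_json = js)
}

.report_as_list <- function(report) {
  dts <- lapply(report$delta_t, function(d) {
    if (is.null(d)) return("not applicable")
    list(n = d$n, mean_h = d$mean, sem_h = d$sem, n_excluded = d$n_excluded)
  })
  ord <- if (is.null(report$ordering)) "not applicable" else
    report$ordering[c("n", "n_strict_before", "n_same_frame", "n_after",
                      "fraction_strict")]
  list(n_axons = report$n_axons, delta_t = dts, ordering = ord,
       second_peak = if (is.null(report$second_peak)) "not applicable"
                     else report$second_peak)
}

.write_report_tsv <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report$delta_t), function(nm) {
    d <- report$delta_t[[nm]]
    data.frame(statistic = nm,
               n = if (is.null(d)) NA_integer_ else d$n,
               mean_h = if (is.null(d)) NA_real_ else d$mean,
               sem_h = if (is.null(d)) NA_real_ else d$sem)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
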