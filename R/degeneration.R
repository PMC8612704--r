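#' Axon degeneration index (DI)
#'
#' Quantifies fragmentation from axon morphology: the image is binarized
#' (global Otsu threshold unless one is given), connected foreground
#' components are extracted, components smaller than \code{min_particle_px}
#' pixels are ignored, and a component counts as fragment-like when its
#' circularity \eqn{4\pi A / P^2} is at least \code{circularity_min}. The DI
#' is the fragment-like area divided by the total axonal area, and an axon
#' is degenerated when DI exceeds \code{di_degenerated} (0.4).
#'
#' @param img an \code{axon_image} (from \code{\link{simulate_axon_images}})
#'   or a numeric matrix with values in [0, 1].
#' @param threshold optional fixed binarization threshold; Otsu when NULL.
#' @param config \code{\link{detection_config}} supplying
#'   \code{circularity_min}, \code{min_particle_px} and
#'   \code{di_degenerated}.
#' @return list of class \code{degeneration_score}: \code{time} (h, NA for a
#'   bare matrix), \code{di} in [0, 1], \code{degenerated} (logical),
#'   \code{n_particles}, \code{n_fragment_like}.
#' @examples
#' m <- matrix(0, 32, 128); m[15:18, ] <- 1   # intact elongated axon
#' degeneration_index(m)$di                   # ~0
#' @export
degeneration_index <- function(img, threshold = NULL,
                               config = detection_config()) {
  tm <- NA_real_
  if (inherits(img, "axon_image")) { tm <- img$time; img <- img$pixels }
  stopifnot(is.matrix(img))
  if (is.null(threshold)) threshold <- EBImage::otsu(EBImage::Image(img))
  mask <- EBImage::Image(img > threshold)
  if (sum(mask) == 0) stop("empty foreground: no axon in image", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  ft <- EBImage::computeFeatures.shape(lab)
  area <- ft[, "s.area"]; per <- ft[, "s.perimeter"]
  keep <- area >= config$min_particle_px & per > 0
  if (!any(keep)) stop("no particle at/above the minimum size", call. = FALSE)
  area <- area[keep]; per <- per[keep]
  circ <- 4 * pi * area / per^2
  frag <- circ >= config$circularity_min
  di <- sum(area[frag]) / sum(area)
  structure(list(time = tm, di = di,
                 degenerated = di > config$di_degenerated,
                 n_particles = sum(keep), n_fragment_like = sum(frag)),
            class = "degeneration_score")
}

#' @export
print.degeneration_score <- function(x, ...) {
  cat(sprintf("DI = %.3f (%d particles, %d fragment-like)%s\n", x$di,
              x$n_particles, x$n_fragment_like,
              if (x$degenerated) " -- degenerated" else ""))
  invisible(x)
}

#' Baseline morphology quality control
#'
#' An axon qualifies for analysis only if its baseline (t = 0) degeneration
#' index is strictly below \code{config$di_baseline_max} (0.2); axons at or
#' above it are excluded.
#'
#' @param img baseline \code{axon_image} or matrix.
#' @param threshold,config passed to \code{\link{degeneration_index}}.
#' @return list: \code{pass} (logical), \code{di}, \code{reason} (\code{""}
#'   when passing).
#' @export
qc_baseline_axon <- function(img, threshold = NULL,
                             config = detection_config()) {
  sc <- degeneration_index(img, threshold = threshold, config = config)
  pass <- sc$di < config$di_baseline_max
  list(pass = pass, di = sc$di,
       reason = if (pass) "" else
         sprintf("baseline DI %.3f >= %.2f", sc$di, config$di_baseline_max))
}
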