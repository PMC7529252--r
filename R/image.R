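# Spermatid DNA-content quantification from fluorescence images:
# max projection -> ROI histogram reset -> local-mean threshold -> watershed
# -> size/circularity particle filter -> integrated intensities,
# plus the time-lapse dot-intensity normalization.

#' Configuration of the nucleus quantification chain
#'
#' Defaults reproduce the published analysis settings: a local mean threshold
#' of radius 15 pixels, particles of 1-25 square micrometers with circularity
#' 0.70-1.00, and a 10% missed-nucleus tolerance before an image is
#' discarded. The threshold offset (the constant subtracted from the local
#' mean) and the pixel calibration are not fixed by those settings and are
#' explicit here: offset 0, and 0.16 micrometer per pixel as typical for a
#' 40x/1.4 oil objective.
#'
#' @param pixel_size_um Micrometers per pixel (> 0).
#' @param local_radius_px Radius of the circular local-mean neighbourhood in
#'   pixels.
#' @param local_offset Constant subtracted from the local mean; a pixel is
#'   foreground when `intensity > local_mean - local_offset` (on the
#'   histogram-reset 0..1 scale).
#' @param min_area_um2,max_area_um2 Retained particle area bounds, inclusive.
#' @param min_circularity,max_circularity Retained circularity bounds
#'   (`4 * pi * area / perimeter^2`, clamped to 1), inclusive.
#' @param qc_missed_fraction Maximal tolerated fraction of expected nuclei
#'   missed by segmentation before [qc_check()] discards the image.
#' @param watershed_tolerance,watershed_ext Object-splitting parameters of
#'   the distance-transform watershed (see [EBImage::watershed()]).
#' @return List of class `quant_config`.
#' @export
quant_config <- function(pixel_size_um = 0.16,
                         local_radius_px = 15L,
                         local_offset = 0,
                         min_area_um2 = 1,
                         max_area_um2 = 25,
                         min_circularity = 0.70,
                         max_circularity = 1.00,
                         qc_missed_fraction = 0.10,
                         watershed_tolerance = 1,
                         watershed_ext = 1) {
  stopifnot(pixel_size_um > 0, local_radius_px >= 1,
            min_area_um2 > 0, min_area_um2 < max_area_um2,
            min_circularity >= 0, min_circularity <= max_circularity,
            max_circularity <= 1, qc_missed_fraction >= 0,
            qc_missed_fraction <= 1)
  structure(
    list(pixel_size_um = pixel_size_um,
         local_radius_px = as.integer(local_radius_px),
         local_offset = local_offset,
         min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         min_circularity = min_circularity,
         max_circularity = max_circularity,
         qc_missed_fraction = qc_missed_fraction,
         watershed_tolerance = watershed_tolerance,
         watershed_ext = watershed_ext),
    class = "quant_config"
  )
}

#' Segment spermatid nuclei in a cyst image
#'
#' Implements the quantification chain: maximum-intensity projection of a
#' stack, min-max intensity rescale within the ROI (the "histogram reset"),
#' local-mean thresholding (circular neighbourhood of `local_radius_px`),
#' watershed splitting of touching nuclei on the distance transform, and
#' measurement of area, circularity and integrated intensity per label.
#' Integrated intensities are summed over the *original* (unrescaled)
#' pixels. The size/circularity particle filter is applied via
#' [particle_filter()]; both all and retained measurements are returned.
#'
#' @param image Numeric matrix (one plane) or 3-D array (stack, projected
#'   internally), or the list returned by [gen_cyst_image()].
#' @param config A [quant_config()]; its `pixel_size_um` calibrates areas.
#' @param roi Optional logical matrix, same size as one plane; analysis is
#'   restricted to `TRUE` pixels.
#' @param exclusion Optional logical matrix; labels whose pixels touch the
#'   mask are dropped (stands in for manual deletion of cyst-cell nuclei).
#' @return List of class `nucleus_segmentation`: `labels` (integer label
#'   matrix), `measurements` (data.frame: `label`, `area_um2`, `circularity`,
#'   `integrated_intensity`, `retained`), `retained` (the filtered subset)
#'   and `config`.
#' @section Errors: an all-`FALSE` ROI is a validation error; an image with
#'   zero dynamic range inside the ROI yields an empty result with a warning.
#' @examples
#' syn <- gen_cyst_image(n_nuclei = 12, seed = 1)
#' seg <- segment_nuclei(syn$image, quant_config())
#' nrow(seg$retained)
#' @export
segment_nuclei <- function(image, config = quant_config(), roi = NULL,
                           exclusion = NULL) {
  stopifnot(inherits(config, "quant_config"))
  if (is.list(image) && !is.null(image$image)) image <- image$image
  img <- as_plane(image)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(is.logical(roi), all(dim(roi) == dim(img)))
  if (!any(roi)) {
    stop_meioconj("ROI is empty", "meioconj_invalid_input")
  }
  rng <- range(img[roi])
  empty <- function() {
    m <- data.frame(label = integer(0), area_um2 = numeric(0),
                    circularity = numeric(0),
                    integrated_intensity = numeric(0), retained = logical(0))
    structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                   measurements = m, retained = m[0, , drop = FALSE],
                   config = config),
              class = "nucleus_segmentation")
  }
  if (rng[2] <= rng[1]) {
    warning("image has zero dynamic range within the ROI; no nuclei segmented")
    return(empty())
  }
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  brush <- EBImage::makeBrush(2L * config$local_radius_px + 1L, shape = "disc")
  brush <- brush / sum(brush)
  local_mean <- EBImage::filter2(scaled, brush)
  # 1e-9 tolerance absorbs FFT round-off on flat background
  fg <- (scaled - (local_mean - config$local_offset)) > 1e-9
  fg <- fg & roi
  if (!any(fg)) return(empty())
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  labels <- EBImage::watershed(dm, tolerance = config$watershed_tolerance,
                               ext = config$watershed_ext)
  lab <- EBImage::imageData(labels)
  if (!is.null(exclusion)) {
    stopifnot(is.logical(exclusion), all(dim(exclusion) == dim(img)))
    drop <- unique(lab[exclusion & lab > 0])
    lab[lab %in% drop] <- 0L
  }
  ids_raw <- sort(unique(lab[lab > 0]))
  if (length(ids_raw) == 0L) return(empty())
  # relabel sequentially so feature rows align with label values
  lab <- array(match(lab, c(0L, ids_raw)) - 1L, dim = dim(lab))
  ids <- seq_along(ids_raw)
  shp <- EBImage::computeFeatures.shape(lab)
  area_px <- shp[, "s.area"]
  perim_px <- shp[, "s.perimeter"]
  circ <- pmin(1, 4 * pi * area_px / pmax(perim_px, 1)^2)
  integ <- vapply(ids, function(id) sum(img[lab == id]), numeric(1))
  meas <- data.frame(
    label = as.integer(ids),
    area_um2 = area_px[ids] * config$pixel_size_um^2,
    circularity = circ[ids],
    integrated_intensity = integ,
    stringsAsFactors = FALSE
  )
  keep <- particle_filter(meas, config)
  meas$retained <- meas$label %in% keep$label
  structure(
    list(labels = lab, measurements = meas,
         retained = meas[meas$retained, , drop = FALSE],
         config = config),
    class = "nucleus_segmentation"
  )
}

as_plane <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L) {
    return(apply(image, c(1, 2), max))  # maximum-intensity projection
  }
  stop_meioconj("image must be a numeric matrix or a 3-D stack",
                "meioconj_invalid_input")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf("Nucleus segmentation: %d object(s), %d retained by the %g-%g um^2 / %.2f-%.2f circularity filter\n",
              nrow(x$measurements), nrow(x$retained),
              x$config$min_area_um2, x$config$max_area_um2,
              x$config$min_circularity, x$config$max_circularity))
  invisible(x)
}

#' Size and circularity particle filter
#'
#' Retains measurements whose area lies in
#' `[min_area_um2, max_area_um2]` and circularity in
#' `[min_circularity, max_circularity]`, bounds inclusive.
#'
#' @param measurements Data frame with columns `area_um2` and `circularity`.
#' @param config A [quant_config()].
#' @return The retained subset of `measurements`.
#' @export
particle_filter <- function(measurements, config = quant_config()) {
  stopifnot(is.data.frame(measurements),
            all(c("area_um2", "circularity") %in% names(measurements)),
            inherits(config, "quant_config"))
  keep <- measurements$area_um2 >= config$min_area_um2 &
    measurements$area_um2 <= config$max_area_um2 &
    measurements$circularity >= config$min_circularity &
    measurements$circularity <= config$max_circularity
  measurements[keep, , drop = FALSE]
}

#' Image quality control on detection completeness
#'
#' An image is discarded when the fraction of expected nuclei missed by
#' automatic selection exceeds `qc_missed_fraction` (10% by default).
#'
#' @param n_expected Expected nucleus count (> 0), e.g. the cyst size.
#' @param n_detected Number of retained nuclei.
#' @param config A [quant_config()].
#' @return List with `pass` (logical; `FALSE` means discard) and
#'   `missed_fraction`.
#' @examples
#' qc_check(64, 60)  # 6.25% missed: pass
#' qc_check(64, 56)  # 12.5% missed: discard
#' @export
qc_check <- function(n_expected, n_detected, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  if (!is_count(n_expected, min = 1L)) {
    stop_meioconj("`n_expected` must be a positive count", "meioconj_invalid_input")
  }
  if (!is_count(n_detected, min = 0L)) {
    stop_meioconj("`n_detected` must be a nonnegative count", "meioconj_invalid_input")
  }
  missed <- max(0, (n_expected - n_detected) / n_expected)
  list(pass = missed <= config$qc_missed_fraction, missed_fraction = missed)
}

#' DNA-content variability of one cyst
#'
#' Divides each nucleus's integrated intensity by the cyst mean and returns
#' the standard deviation of the normalized values — the per-cyst
#' variability statistic. Invariant under global intensity scaling.
#'
#' @param x Numeric vector of integrated intensities, or a data.frame with
#'   an `integrated_intensity` column (e.g. `segment_nuclei()$retained`), or
#'   a `nucleus_segmentation`.
#' @return List of class `cyst_variability`: `n_nuclei`,
#'   `normalized_contents` (mean 1), `sd_normalized` (sample s.d.).
#' @section Errors: fewer than 2 nuclei, or a zero cyst mean, are errors.
#' @examples
#' cyst_variability(c(1, 3))$sd_normalized   # sd of {0.5, 1.5} = 0.7071
#' @export
cyst_variability <- function(x) {
  if (inherits(x, "nucleus_segmentation")) x <- x$retained
  if (is.data.frame(x)) {
    stopifnot("integrated_intensity" %in% names(x))
    x <- x$integrated_intensity
  }
  if (!is.numeric(x) || length(x) < 2L) {
    stop_meioconj("need >= 2 nucleus intensities", "meioconj_invalid_input")
  }
  mu <- mean(x)
  if (mu == 0) {
    stop_meioconj("cyst mean intensity is 0; normalization undefined",
                  "meioconj_degenerate_input")
  }
  z <- x / mu
  structure(
    list(n_nuclei = length(x), normalized_contents = z,
         sd_normalized = stats::sd(z)),
    class = "cyst_variability"
  )
}

#' @export
print.cyst_variability <- function(x, ...) {
  cat(sprintf("Cyst DNA-content variability: n = %d nuclei, normalized s.d. = %.4f\n",
              x$n_nuclei, x$sd_normalized))
  invisible(x)
}

#' Normalize a single-dot intensity time course
#'
#' Identifies the ten time points of maximal intensity and rescales the
#' trace so that their mean equals 100 arbitrary units. Optionally shifts
#' the time axis so that a caller-supplied alignment frame (the last time
#' point before nuclear envelope breakdown) becomes t = 0.
#'
#' @param time Numeric vector of time points in minutes, strictly
#'   increasing (>= 10 points).
#' @param intensity Numeric vector of raw intensities, same length.
#' @param nebd_index Optional index of the alignment frame.
#' @return Data.frame of class `intensity_trace` with columns `time` and
#'   `intensity_au`; the applied scale factor is kept in attribute
#'   `scale_factor`.
#' @section Errors: fewer than 10 points, a non-increasing time axis, or a
#'   trace whose top-ten mean is 0 (an all-zero trace) are errors.
#' @examples
#' tr <- gen_intensity_trace(seed = 1)
#' normalize_trace(tr$time, tr$intensity)
#' @export
normalize_trace <- function(time, intensity, nebd_index = NULL) {
  if (is.data.frame(time) && is.null(dim(intensity)) && missing(intensity)) {
    intensity <- time$intensity; time <- time$time
  }
  stopifnot(is.numeric(time), is.numeric(intensity),
            length(time) == length(intensity))
  if (length(time) < 10L) {
    stop_meioconj("trace needs at least 10 time points", "meioconj_invalid_input")
  }
  if (any(diff(time) <= 0)) {
    stop_meioconj("time points must be strictly increasing", "meioconj_invalid_input")
  }
  top10 <- mean(sort(intensity, decreasing = TRUE)[1:10])
  if (top10 == 0) {
    stop_meioconj("top-ten mean intensity is 0; normalization undefined",
                  "meioconj_degenerate_input")
  }
  if (!is.null(nebd_index)) {
    stopifnot(is_count(nebd_index), nebd_index <= length(time))
    time <- time - time[nebd_index]
  }
  out <- data.frame(time = time, intensity_au = intensity * 100 / top10)
  attr(out, "scale_factor") <- 100 / top10
  class(out) <- c("intensity_trace", class(out))
  out
}
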