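# Fluorescence-image gradient profiling.
#
# Intensity-vs-distance profiles are extracted from embryo images by
# binning a rectangular ROI adjacent to the source clone, subtracting
# scalar background autofluorescence, normalising to the bin closest to
# the source, and fitting an exponential decay with offset.

#' Embryo fluorescence image
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x),
#'   all values >= 0.
#' @param pixel_size Pixel edge length (\eqn{\mu m}/pixel, default 1.4).
#' @param source_boundary Column index of the source-clone edge; profiling
#'   proceeds to the right of this column.
#' @param background_level Scalar autofluorescence estimate (intensity
#'   units), e.g. from images of uninjected embryos.
#' @return An object of class `"embryo_image"`.
#' @export
embryo_image <- function(pixels, pixel_size = 1.4, source_boundary = 1L,
                         background_level = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_invalid("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_invalid("'pixels' must be finite and non-negative")
  check_scalar(pixel_size, "pixel_size", lower = 0, open_lower = TRUE)
  check_scalar(background_level, "background_level", lower = 0)
  source_boundary <- as.integer(source_boundary)
  if (source_boundary < 1L || source_boundary > ncol(pixels))
    stop_invalid("'source_boundary' must be a column index of the image")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 source_boundary = source_boundary,
                 background_level = background_level),
            class = "embryo_image")
}

#' Read a grayscale TIFF as an embryo image
#'
#' Reads a (16-bit) grayscale TIFF with [tiff::readTIFF()]; multi-channel
#' images require an explicit `channel` index.
#'
#' @param path TIFF file path.
#' @param channel Channel index for multi-channel images.
#' @inheritParams embryo_image
#' @return An [embryo_image()].
#' @export
read_embryo_tiff <- function(path, pixel_size = 1.4, source_boundary = 1L,
                             background_level = 0, channel = NULL) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (is.null(channel))
      stop_invalid("multi-channel TIFF: supply a 'channel' index")
    px <- px[, , channel]
  }
  embryo_image(px, pixel_size = pixel_size,
               source_boundary = source_boundary,
               background_level = background_level)
}

#' Intensity profile
#'
#' @param distance Bin-centre distances from the source (\eqn{\mu m}).
#' @param intensity Mean intensity per bin.
#' @param sem Optional per-bin standard error (across embryos).
#' @return An object of class `"intensity_profile"`.
#' @export
intensity_profile <- function(distance, intensity, sem = NULL) {
  if (length(distance) != length(intensity))
    stop_invalid("'distance' and 'intensity' must have the same length")
  if (any(!is.finite(distance)) || any(diff(distance) <= 0))
    stop_invalid("'distance' must be finite and strictly increasing")
  structure(list(distance = distance, intensity = intensity, sem = sem),
            class = "intensity_profile")
}

#' Extract a binned intensity profile from an embryo image
#'
#' A rectangular ROI of height `roi_height_px` rows starts at the source
#' boundary column; consecutive windows of `bin_width_px` columns are
#' averaged.  With the 1.4 \eqn{\mu m} pixel edge the defaults give
#' 7 x 50.4 \eqn{\mu m} windows.  Distances are bin centres, measured
#' from the source boundary (first bin centre at half a bin width).
#'
#' @param image An [embryo_image()].
#' @param roi_height_px ROI height in pixels (default 36).
#' @param bin_width_px Bin width in pixels (default 5).
#' @param roi_top First ROI row; default centres the ROI vertically.
#' @return An [intensity_profile()].
#' @export
extract_binned_profile <- function(image, roi_height_px = 36L,
                                   bin_width_px = 5L, roi_top = NULL) {
  stopifnot(inherits(image, "embryo_image"))
  px <- image$pixels
  roi_height_px <- as.integer(roi_height_px)
  bin_width_px <- as.integer(bin_width_px)
  roi_top <- as.integer(roi_top %||%
                          max(1L, (nrow(px) - roi_height_px) %/% 2L + 1L))
  if (roi_top < 1L || roi_top + roi_height_px - 1L > nrow(px))
    stop_invalid("ROI rows fall outside the image")
  n_cols <- ncol(px) - image$source_boundary + 1L
  n_bins <- n_cols %/% bin_width_px
  if (n_bins < 1L)
    stop_invalid("ROI columns fall outside the image")
  rows <- roi_top:(roi_top + roi_height_px - 1L)
  intensity <- vapply(seq_len(n_bins), function(b) {
    c0 <- image$source_boundary + (b - 1L) * bin_width_px
    mean(px[rows, c0:(c0 + bin_width_px - 1L)])
  }, numeric(1))
  distance <- (seq_len(n_bins) - 0.5) * bin_width_px * image$pixel_size
  intensity_profile(distance, intensity)
}

#' Subtract scalar background from a profile
#'
#' Reduces every bin by `background_level`, clipping at zero.
#'
#' @param profile An [intensity_profile()].
#' @param background_level Scalar background (>= 0).
#' @return An [intensity_profile()].
#' @export
subtract_background <- function(profile, background_level) {
  stopifnot(inherits(profile, "intensity_profile"))
  check_scalar(background_level, "background_level", lower = 0)
  intensity_profile(profile$distance,
                    pmax(profile$intensity - background_level, 0),
                    sem = profile$sem)
}

#' Normalise a profile to its first bin
#'
#' Divides all intensities by the value closest to the source boundary.
#'
#' @param profile An [intensity_profile()] whose first bin is positive.
#' @return An [intensity_profile()] with `intensity[1] == 1`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  ref <- profile$intensity[1]
  if (!is.finite(ref) || ref <= 0)
    stop_invalid("cannot normalise: first-bin intensity is not positive")
  intensity_profile(profile$distance, profile$intensity / ref,
                    sem = if (!is.null(profile$sem)) profile$sem / ref)
}

#' Fit the exponential decay model to an intensity profile
#'
#' Least-squares fit of \eqn{C(x) = A e^{-x/\lambda} + C} (amplitude,
#' decay length and offset all free).
#'
#' @param profile An [intensity_profile()] with at least 5 bins.
#' @return A `"gradient_fit"` (see [fit_exponential_gradient()]).
#' @examples
#' x <- seq(3.5, 350, by = 7)
#' fit_profile(intensity_profile(x, exp(-x / 29.5)))$lambda_
#' @export
fit_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (length(profile$distance) < 5L)
    stop_invalid("need at least 5 bins to fit the gradient")
  fit_exponential_gradient(profile, with_offset = TRUE)
}

#' Aggregate gradient fits over several embryos
#'
#' `"pooled"` concatenates all profiles and performs one fit; the
#' gradient length is then the pooled \eqn{\lambda}.  `"individual"` fits
#' each profile and reports the mean \eqn{\lambda} with its standard
#' error.  Profiles must share a common distance grid.
#'
#' @param profiles List of [intensity_profile()]s (>= 2) on identical
#'   distance grids.
#' @param mode `"pooled"` or `"individual"`.
#' @return A list with `lambda_`, `lambda_se` (NA for pooled), `mode`,
#'   `n_profiles`, and `fits` (the underlying fit object(s)).
#' @export
aggregate_profiles <- function(profiles, mode = c("pooled", "individual")) {
  mode <- match.arg(mode)
  if (!is.list(profiles) || length(profiles) < 2L ||
      !all(vapply(profiles, inherits, logical(1), "intensity_profile")))
    stop_invalid("'profiles' must be a list of >= 2 intensity profiles")
  grid <- profiles[[1]]$distance
  same <- vapply(profiles, function(p)
    length(p$distance) == length(grid) &&
      all(abs(p$distance - grid) < 1e-9), logical(1))
  if (!all(same))
    stop_invalid("profiles are on incompatible distance grids")
  if (mode == "pooled") {
    pooled <- list(distance = rep(grid, length(profiles)),
                   intensity = unlist(lapply(profiles, `[[`, "intensity")))
    ord <- order(pooled$distance)
    # fit on the concatenated (x, y) cloud; grid order is irrelevant to LSQ
    fit <- fit_exponential_gradient(
      structure(list(x_centers = NULL, density = NULL,
                     distance = pooled$distance[ord],
                     intensity = pooled$intensity[ord]),
                class = "intensity_profile_pooled"),
      with_offset = TRUE)
    list(lambda_ = fit$lambda_, lambda_se = NA_real_, mode = mode,
         n_profiles = length(profiles), fits = fit)
  } else {
    fits <- lapply(profiles, fit_profile)
    lams <- vapply(fits, `[[`, numeric(1), "lambda_")
    list(lambda_ = mean(lams),
         lambda_se = stats::sd(lams) / sqrt(length(lams)),
         mode = mode, n_profiles = length(profiles), fits = fits)
  }
}
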