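#' Construct a two-channel image pair
#'
#' @param channel_a,channel_b equal-shape numeric matrices (grayscale
#'   intensity rasters).
#' @param mask optional logical matrix of the same shape selecting the
#'   pixels to analyse.
#' @return object of class `image_pair`.
#' @export
image_pair <- function(channel_a, channel_b, mask = NULL) {
  channel_a <- as.matrix(channel_a)
  channel_b <- as.matrix(channel_b)
  if (!all(dim(channel_a) == dim(channel_b))) {
    stop_invalid("channels must have identical dimensions")
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!is.logical(mask) || !all(dim(mask) == dim(channel_a))) {
      stop_invalid("mask must be a logical matrix matching the channels")
    }
    if (sum(mask) < 2L) stop_invalid("mask must keep at least 2 pixels")
  }
  structure(list(channel_a = channel_a, channel_b = channel_b, mask = mask),
            class = "image_pair")
}

#' Pearson colocalization coefficient of an image pair
#'
#' Sample Pearson correlation of the two channels over the unmasked pixels
#' (whole image if no mask). This is plain pixelwise Pearson without any
#' automatic intensity thresholding.
#'
#' @param pair an [image_pair()].
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_coloc <- function(pair) {
  if (!inherits(pair, "image_pair")) stop_invalid("pair must be an image_pair")
  a <- pair$channel_a
  b <- pair$channel_b
  if (!is.null(pair$mask)) {
    a <- a[pair$mask]
    b <- b[pair$mask]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop(errorCondition("a channel is constant within the mask; correlation undefined",
                        class = c("gt_undefined_correlation", "gt_error")))
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Arbitrary-unit normalization of paired ROI intensities
#'
#' For each measurement the background ROI mean is subtracted from the
#' signal ROI mean individually; each background-subtracted value is then
#' divided by the mean background-subtracted value of that imaging day's
#' control measurements. The resulting arbitrary units (AU) are comparable
#' across imaging days even when laser power or staining strength differs:
#' a day-specific multiplicative gain cancels, and the control group of each
#' day averages to 1 by construction.
#'
#' @param measurements data.frame with columns `signal_mean`,
#'   `background_mean`, `day_id`.
#' @param control_flags logical vector marking the control measurements.
#' @param reference_day_control_mean optional named numeric vector giving a
#'   control divisor for days that carry no controls of their own.
#' @return the input data.frame with an added `au` column.
#' @examples
#' m <- data.frame(signal_mean = c(4, 6, 5), background_mean = c(2, 2, 2),
#'                 day_id = "d1")
#' t_antigen_au(m, control_flags = c(TRUE, TRUE, FALSE))$au  # 2/3, 4/3, 1
#' @export
t_antigen_au <- function(measurements, control_flags,
                         reference_day_control_mean = NULL) {
  need <- c("signal_mean", "background_mean", "day_id")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    stop_invalid("measurements must have columns signal_mean, background_mean, day_id")
  }
  if (length(control_flags) != nrow(measurements) ||
      !is.logical(control_flags)) {
    stop_invalid("control_flags must be a logical vector, one per measurement")
  }
  if (any(measurements$signal_mean < 0 | measurements$background_mean < 0)) {
    stop_invalid("ROI means must be non-negative")
  }
  net <- measurements$signal_mean - measurements$background_mean
  days <- unique(measurements$day_id)
  divisor <- stats::setNames(rep(NA_real_, length(days)), days)
  for (d in days) {
    ctl <- control_flags & measurements$day_id == d
    if (any(ctl)) {
      divisor[d] <- mean(net[ctl])
    } else if (!is.null(reference_day_control_mean) &&
               d %in% names(reference_day_control_mean)) {
      divisor[d] <- reference_day_control_mean[[d]]
    } else {
      stop(errorCondition(
        paste0("day '", d, "' has no control measurements and no reference divisor"),
        class = c("gt_missing_reference", "gt_error")))
    }
    if (!is.finite(divisor[d]) || divisor[d] == 0) {
      stop_degenerate(paste0("day '", d, "' control mean is zero"))
    }
  }
  measurements$au <- net / divisor[as.character(measurements$day_id)]
  measurements
}

#' Intensity line profile through a multichannel raster
#'
#' Samples each channel at `n_samples` equidistant points along the segment
#' from `p0` to `p1` (micrometre coordinates) using bilinear interpolation
#' between pixel centres. Pixel (i, j), 0-based with origin at the top-left,
#' has its centre at `x = j * pixel_size`, `y = i * pixel_size`; sampling at
#' pixel centres therefore reproduces raw pixel values exactly.
#'
#' @param image numeric matrix (one channel) or 3D array
#'   `height x width x channels`.
#' @param p0,p1 endpoints `c(x, y)` in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param n_samples number of sample points along the line.
#' @return data.frame with `distance_um` and one column per channel.
#' @export
line_profile <- function(image, p0, p1, pixel_size, n_samples = 50L) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop_invalid("image must be a matrix or a height x width x channels array")
  }
  if (length(p0) != 2L || length(p1) != 2L || any(!is.finite(c(p0, p1)))) {
    stop_invalid("p0 and p1 must be finite (x, y) pairs")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop_invalid("pixel_size must be > 0")
  }
  if (!is_count(n_samples) || n_samples < 2) {
    stop_invalid("n_samples must be an integer >= 2")
  }
  seg <- sqrt(sum((p1 - p0)^2))
  if (seg == 0) stop_invalid("p0 and p1 must differ")
  h <- dim(image)[1L]
  w <- dim(image)[2L]
  xmax <- (w - 1L) * pixel_size
  ymax <- (h - 1L) * pixel_size
  for (p in list(p0, p1)) {
    if (p[1L] < 0 || p[1L] > xmax || p[2L] < 0 || p[2L] > ymax) {
      stop(errorCondition("line endpoint outside the raster",
                          class = c("gt_out_of_bounds", "gt_error")))
    }
  }
  frac <- seq(0, 1, length.out = n_samples)
  xs <- (p0[1L] + frac * (p1[1L] - p0[1L])) / pixel_size  # 0-based column coord
  ys <- (p0[2L] + frac * (p1[2L] - p0[2L])) / pixel_size  # 0-based row coord
  out <- data.frame(distance_um = frac * seg)
  for (ch in seq_len(dim(image)[3L])) {
    out[[paste0("channel_", ch)]] <- bilinear_sample(image[, , ch], xs, ys)
  }
  out
}

# Bilinear interpolation at 0-based (x = column, y = row) coordinates.
bilinear_sample <- function(m, xs, ys) {
  h <- nrow(m)
  w <- ncol(m)
  x0 <- pmin(pmax(floor(xs), 0), w - 1L)
  y0 <- pmin(pmax(floor(ys), 0), h - 1L)
  x1 <- pmin(x0 + 1L, w - 1L)
  y1 <- pmin(y0 + 1L, h - 1L)
  fx <- xs - x0
  fy <- ys - y0
  idx <- function(r, c) m[cbind(r + 1L, c + 1L)]
  (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) +
    fx * fy * idx(y1, x1)
}

#' Border cell migration as percent of expected distance
#'
#' Scalar projection of the observed displacement onto the expected
#' migration axis (origin to target), expressed as a percentage of the full
#' expected distance. 0 means no migration, 100 means the cluster reached
#' the target; values outside `[0, 100]` are reported raw together with a
#' clamped value and a flag.
#'
#' @param current_position,origin,target coordinate vectors of equal length
#'   (2D projections or 3D).
#' @return list with `percent` (raw), `percent_clamped` and `clamped` flag.
#' @export
border_cell_migration_pct <- function(current_position, origin, target) {
  if (length(origin) != length(target) ||
      length(current_position) != length(origin) ||
      any(!is.finite(c(current_position, origin, target)))) {
    stop_invalid("positions must be finite vectors of equal length")
  }
  axis <- target - origin
  len2 <- sum(axis^2)
  if (len2 == 0) stop_invalid("target must differ from origin")
  pct <- 100 * sum((current_position - origin) * axis) / len2
  list(percent = pct,
       percent_clamped = min(max(pct, 0), 100),
       clamped = pct < 0 || pct > 100)
}
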