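# Pad localisation and color-space feature extraction.

#' Pixel region
#'
#' A rectangle in 0-based, half-open pixel coordinates (top-left origin):
#' `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 Integer corner coordinates, `x0 < x1`, `y0 < y1`.
#' @return An object of class `pixel_region`.
#' @export
pixel_region <- function(x0, y0, x1, y1) {
  if (x0 >= x1 || y0 >= y1) stop("require x0 < x1 and y0 < y1")
  if (x0 < 0 || y0 < 0) stop("region coordinates must be >= 0")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "pixel_region")
}

#' @export
print.pixel_region <- function(x, ...) {
  cat(sprintf("<pixel_region [%d,%d) x [%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Intersection-over-union of two pixel regions
#'
#' @param a,b `pixel_region` objects.
#' @return IoU in `[0, 1]`.
#' @export
region_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

# central fraction of a box, used both by the detector and to define the
# ground-truth pad interior that detections are scored against
central_subrect <- function(x0, y0, x1, y1, frac = 0.6) {
  w <- x1 - x0; h <- y1 - y0
  mx <- (1 - frac) / 2
  pixel_region(floor(x0 + mx * w), floor(y0 + mx * h),
               ceiling(x1 - mx * w), ceiling(y1 - mx * h))
}

#' Ground-truth pad interior of a synthetic image
#'
#' The central sub-rectangle of the true active-pad box recorded by the
#' generator; the region a correct detection should recover.
#'
#' @param image A `device_image` carrying truth metadata.
#' @param frac Central fraction retained (default 0.6, matching the detector).
#' @return A `pixel_region`.
#' @export
true_pad_interior <- function(image, frac = 0.6) {
  tr <- attr(image, "truth")
  if (is.null(tr)) stop("image carries no ground-truth metadata")
  b <- tr$geometry$pad_boxes[[tr$geometry$active_panel_index + 1L]]
  central_subrect(b["x0"], b["y0"], b["x1"], b["y1"], frac)
}

#' Detect the reaction-pad region of interest
#'
#' Locates the reaction pads in a device photograph and returns the central
#' sub-rectangle of the requested panel.  The detector follows a standard
#' segmentation recipe: convert to grayscale, threshold with Otsu's method
#' (pads are darker than the device body), label connected components, keep
#' components whose area is within `[0.3, 3]` times the expected pad area and
#' whose width/height aspect ratio lies in `[1.0, 1.6]`, order the survivors
#' left to right, pick the `panel_index`-th, and return its central `frac`
#' sub-rectangle (trimming pad edges and wicking artifacts).
#'
#' @param image A `device_image` (or `h x w x 3` array, 0-255).
#' @param panel_index Which pad to return, 0-2 left to right.
#' @param expected_pad_area Expected pad area in px^2 used by the area filter;
#'   defaults to the 90 x 72 default geometry.
#' @param area_bounds,aspect_bounds Multiplicative area bounds and
#'   width/height aspect bounds for candidate filtering.
#' @param frac Central fraction of the pad box returned.
#' @return A `pixel_region` (0-based, half-open).
#' @export
detect_roi <- function(image, panel_index = 2L,
                       expected_pad_area = 90 * 72,
                       area_bounds = c(0.3, 3),
                       aspect_bounds = c(1.0, 1.6),
                       frac = 0.6) {
  if (!panel_index %in% 0:2) stop("panel_index must be 0, 1 or 2")
  arr <- unclass(image)
  if (length(dim(arr)) != 3L) stop("image must be h x w x 3")
  gray <- (0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]) / 255

  if (max(gray) - min(gray) < 1 / 255) stop("pad not found: blank image")

  candidates_below <- function(thr) {
    ebi <- EBImage::Image(t(gray))          # EBImage indexes [x, y]
    labels <- EBImage::bwlabel(ebi < thr)   # pads darker than device body
    n <- max(labels)
    if (n == 0) return(list())
    lab_t <- t(EBImage::imageData(labels))  # back to [row, col]
    areas <- tabulate(as.integer(lab_t), nbins = n)
    keep <- which(areas >= area_bounds[1] * expected_pad_area &
                    areas <= area_bounds[2] * expected_pad_area)
    cand <- list()
    for (k in keep) {
      idx <- which(lab_t == k, arr.ind = TRUE)
      y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])   # half-open
      x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])
      aspect <- (x1 - x0) / (y1 - y0)
      if (aspect < aspect_bounds[1] || aspect > aspect_bounds[2]) next
      cand[[length(cand) + 1L]] <- c(x0, y0, x1, y1)
    }
    cand
  }

  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  cand <- candidates_below(thr)
  if (length(cand) < 3L) {
    # A strongly developed pad can pull the two-class Otsu threshold below
    # the blank pads.  Second-level pass: re-threshold the brighter class to
    # separate blank pads from the device body, capturing all pads.
    upper <- gray[gray >= thr]
    if (length(unique(upper)) > 1L) {
      thr2 <- EBImage::otsu(EBImage::Image(matrix(upper)), range = c(0, 1))
      cand2 <- candidates_below(thr2)
      if (length(cand2) > length(cand) && length(cand2) <= 3L) cand <- cand2
    }
  }
  if (length(cand) == 0L) stop("pad not found: no component passed filters")
  if (length(cand) > 3L) stop("ambiguous detection: more than three candidate pads")
  ord <- order(vapply(cand, `[`, numeric(1), 1L))
  cand <- cand[ord]
  if (panel_index + 1L > length(cand))
    stop("pad not found: fewer candidates than requested panel index")
  b <- cand[[panel_index + 1L]]
  central_subrect(b[1], b[2], b[3], b[4], frac)
}

#' Extract a pixel-exact sub-image
#'
#' @param image A `device_image` or `h x w x 3` array.
#' @param region A `pixel_region` inside the image.
#' @param panel_index Optional panel index recorded as provenance.
#' @return An `roi_patch`: the cropped array with attributes `source_region`
#'   and `panel_index`.
#' @export
extract_patch <- function(image, region, panel_index = NA_integer_) {
  arr <- unclass(image)
  d <- dim(arr)
  if (region$x1 > d[2] || region$y1 > d[1])
    stop("region out of image bounds")
  patch <- arr[(region$y0 + 1):region$y1, (region$x0 + 1):region$x1, ,
               drop = FALSE]
  structure(patch, source_region = region,
            panel_index = as.integer(panel_index),
            class = c("roi_patch", "array"))
}

#' Convert an sRGB patch into the four working color spaces
#'
#' Returns aligned channel planes for RGB (native 8-bit), CIE XYZ (sRGB
#' linearisation and D65 matrix, white Y = 1), CIELAB (D65 white, L* in
#' 0-100) and HSV (hue in degrees, S and V in 0-1; achromatic pixels get hue
#' 0).  XYZ and Lab come from [grDevices::convertColor()]; HSV from
#' [grDevices::rgb2hsv()].
#'
#' @param patch An `roi_patch` or `h x w x 3` array in `[0, 255]`.
#' @return Named list `RGB`, `XYZ`, `LAB`, `HSV`, each `h x w x 3`.
#' @export
convert_color_spaces <- function(patch) {
  arr <- unclass(patch)
  d <- dim(arr)
  if (length(d) != 3L || d[3] != 3L) stop("patch must be h x w x 3")
  n <- d[1] * d[2]
  rgb01 <- cbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]),
                 as.vector(arr[, , 3])) / 255
  xyz <- grDevices::convertColor(rgb01, from = "sRGB", to = "XYZ")
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  hsv <- t(grDevices::rgb2hsv(t(rgb01), maxColorValue = 1))
  hsv[, 1] <- hsv[, 1] * 360   # hue in degrees; rgb2hsv already gives 0 when achromatic
  to_planes <- function(m) array(m, dim = c(d[1], d[2], 3L))
  list(RGB = arr * 1.0, XYZ = to_planes(xyz), LAB = to_planes(lab),
       HSV = to_planes(hsv))
}

# nominal channel ranges used for histogram-mode binning; RGB bins are the
# 256 native 8-bit levels themselves
.channel_ranges <- list(
  RGB = list(c(0, 256), c(0, 256), c(0, 256)),
  XYZ = list(c(0, 0.9505), c(0, 1), c(0, 1.089)),
  LAB = list(c(0, 100), c(-128, 127), c(-128, 127)),
  HSV = list(c(0, 360), c(0, 1), c(0, 1)))

# histogram mode: 256 bins over the channel's nominal range; ties go to the
# lower bin.  For native 8-bit channels (unit-width bins) the reported value
# is the level itself; for derived continuous channels, the bin midpoint.
histogram_mode <- function(x, range, bins = 256L) {
  width <- (range[2] - range[1]) / bins
  bin <- pmin(pmax(floor((x - range[1]) / width), 0), bins - 1L)
  counts <- tabulate(bin + 1L, nbins = bins)
  best <- which.max(counts)          # which.max returns the first (lowest) tie
  if (isTRUE(all.equal(width, 1)))
    range[1] + (best - 1) * width    # native 8-bit level
  else
    range[1] + (best - 0.5) * width
}

#' The 36 color-channel statistics of an ROI patch
#'
#' Mean, median and histogram mode of each channel of each working color
#' space: 4 spaces x 3 channels x 3 statistics = 36 features.  Channels are
#' indexed 0-2 within their space and features are named
#' `<SPACE>_<channel>_<stat>`, e.g. `LAB_0_mean`.
#'
#' @param planes Output of [convert_color_spaces()], or an `roi_patch` /
#'   `h x w x 3` sRGB array (converted internally).
#' @return A named numeric vector of length 36 with class `color_features`.
#' @export
channel_statistics <- function(planes) {
  if (is.array(planes)) planes <- convert_color_spaces(planes)
  spaces <- c("RGB", "XYZ", "LAB", "HSV")
  out <- numeric(0)
  for (sp in spaces) {
    pl <- planes[[sp]]
    if (is.null(pl) || length(pl) == 0L) stop("empty patch")
    for (ch in 0:2) {
      x <- as.vector(pl[, , ch + 1])
      rng <- .channel_ranges[[sp]][[ch + 1]]
      vals <- c(mean(x), stats::median(x), histogram_mode(x, rng))
      names(vals) <- sprintf("%s_%d_%s", sp, ch, c("mean", "median", "mode"))
      out <- c(out, vals)
    }
  }
  if (any(!is.finite(out))) stop("non-finite feature value")
  structure(out, class = "color_features")
}

#' Full image-to-features pipeline
#'
#' Convenience wrapper: detect the ROI, crop, and compute the 36 statistics.
#'
#' @inheritParams detect_roi
#' @return A `color_features` vector with attribute `region`.
#' @export
extract_features <- function(image, panel_index = 2L, ...) {
  region <- detect_roi(image, panel_index = panel_index, ...)
  patch <- extract_patch(image, region, panel_index = panel_index)
  feats <- channel_statistics(patch)
  attr(feats, "region") <- region
  feats
}

#' Write a feature vector (or matrix of them) as CSV
#'
#' One row per image, columns named `<SPACE>_<channel>_<stat>`.
#'
#' @param features A `color_features` vector or a matrix/data.frame whose
#'   columns are the 36 features.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(features, path) {
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(unclass(features)))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
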