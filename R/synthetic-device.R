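# Synthetic device-image generation with known ground truth.
#
# All pixel coordinates in the package are 0-based and half-open:
# a box [x0, x1) x [y0, y1) covers columns x0..x1-1 and rows y0..y1-1 of the
# image, with the origin at the top-left corner.

#' Assay device geometry
#'
#' Describes the pixel layout of a three-panel test-strip device inside a
#' photograph: the image frame and the three rectangular reaction pads.  By
#' convention only one panel carries the reacting sample; the default is the
#' rightmost panel (index 2).
#'
#' The default layout places three 90 x 72 px pads (the 7.5:6 aspect ratio of
#' the physical cellulose pads) side by side in a 600 x 400 px frame.
#'
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param pad_boxes List of three pad rectangles, each a numeric vector
#'   `c(x0, y0, x1, y1)` in 0-based half-open pixel coordinates.
#' @param active_panel_index Which panel (0, 1 or 2, left to right) carries
#'   the sample whose concentration varies.
#'
#' @return An object of class `assay_geometry`.
#' @export
assay_geometry <- function(image_width_px = 600L,
                           image_height_px = 400L,
                           pad_boxes = NULL,
                           active_panel_index = 2L) {
  if (is.null(pad_boxes)) {
    # three 90x72 pads, evenly spaced, vertically centred
    pad_w <- 90L; pad_h <- 72L
    gap <- (image_width_px - 3L * pad_w) %/% 4L
    y0 <- (image_height_px - pad_h) %/% 2L
    pad_boxes <- lapply(0:2, function(i) {
      x0 <- gap + i * (pad_w + gap)
      c(x0 = x0, y0 = y0, x1 = x0 + pad_w, y1 = y0 + pad_h)
    })
  }
  if (length(pad_boxes) != 3L)
    stop("geometry requires exactly three pad boxes")
  for (b in pad_boxes) {
    if (length(b) != 4L || b[1] >= b[3] || b[2] >= b[4])
      stop("pad box must be c(x0, y0, x1, y1) with x0 < x1 and y0 < y1")
    if (b[1] < 0 || b[2] < 0 || b[3] > image_width_px || b[4] > image_height_px)
      stop("pad box lies outside the image frame")
  }
  if (!active_panel_index %in% 0:2)
    stop("active_panel_index must be 0, 1 or 2")
  structure(
    list(image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         pad_boxes = lapply(pad_boxes, function(b) {
           b <- as.numeric(b); names(b) <- c("x0", "y0", "x1", "y1"); b
         }),
         active_panel_index = as.integer(active_panel_index)),
    class = "assay_geometry")
}

#' Generator parameters for synthetic device images
#'
#' Controls the concentration-to-color response and the image degradations of
#' the synthetic renderer.  The pad color interpolates between `base_color`
#' (unreacted pad) and `target_color` (fully developed azo dye) along a
#' saturating response `f(c) = c / (c + K)`, so `half_saturation_K` is the
#' concentration (mg/dl) at which the color change is half complete.
#'
#' @param base_color sRGB triple (0-255) of the unreacted pad.
#' @param target_color sRGB triple of the fully developed reaction color.
#' @param background_color sRGB triple of the device body surrounding the pads.
#' @param half_saturation_K Half-saturation concentration in mg/dl (> 0).
#' @param noise_sigma Per-channel Gaussian noise SD in 8-bit units (>= 0).
#' @param vignette_strength Strength in `[0, 1]` of a radial quadratic
#'   illumination falloff centred on the frame (0 = flat lighting).
#' @param jitter_px Maximum translation, in pixels, of the device within the
#'   frame (uniform in both axes).
#'
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(base_color = c(225, 218, 200),
                             target_color = c(150, 60, 110),
                             background_color = c(250, 250, 248),
                             half_saturation_K = 4.0,
                             noise_sigma = 4.0,
                             vignette_strength = 0.05,
                             jitter_px = 10L) {
  chk_col <- function(x, nm) {
    if (length(x) != 3L || any(x < 0) || any(x > 255))
      stop(nm, " must be an sRGB triple within [0, 255]")
  }
  chk_col(base_color, "base_color")
  chk_col(target_color, "target_color")
  chk_col(background_color, "background_color")
  if (half_saturation_K <= 0) stop("half_saturation_K must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (vignette_strength < 0 || vignette_strength > 1)
    stop("vignette_strength must lie in [0, 1]")
  if (jitter_px < 0) stop("jitter_px must be >= 0")
  structure(
    list(base_color = as.numeric(base_color),
         target_color = as.numeric(target_color),
         background_color = as.numeric(background_color),
         half_saturation_K = as.numeric(half_saturation_K),
         noise_sigma = as.numeric(noise_sigma),
         vignette_strength = as.numeric(vignette_strength),
         jitter_px = as.integer(jitter_px)),
    class = "generator_params")
}

#' Ground-truth pad color at a given concentration
#'
#' The noiseless color of a reacted pad: a per-channel blend of the base and
#' target colors with saturating weight `f(c) = c / (c + K)`.  Strictly
#' monotone in concentration on every channel where base and target differ.
#'
#' @param concentration Analyte concentration in mg/dl (>= 0).
#' @param params A [generator_params()] object.
#' @return Numeric sRGB triple (not yet quantised to integers).
#' @export
true_pad_color <- function(concentration, params) {
  if (length(concentration) != 1L || is.na(concentration) || concentration < 0)
    stop("concentration must be a single value >= 0")
  f <- concentration / (concentration + params$half_saturation_K)
  params$base_color + f * (params$target_color - params$base_color)
}

#' Render a synthetic device image
#'
#' Draws the device on a uniform background, fills the three pads (only the
#' active panel's color varies with concentration; the other two stay at the
#' unreacted base color), applies an optional radial vignette, adds i.i.d.
#' Gaussian pixel noise, and clips to the 8-bit range.  The true
#' concentration, geometry (after jitter) and seed are embedded as a `truth`
#' attribute, so downstream stages can be scored against ground truth.
#'
#' Rendering is fully deterministic: identical inputs and seed give
#' byte-identical pixels.
#'
#' @param concentration True analyte concentration in mg/dl.
#' @param geometry An [assay_geometry()] object.
#' @param params A [generator_params()] object.
#' @param seed Integer seed for jitter and noise.
#' @return A `device_image`: integer array `height x width x 3` in `[0, 255]`
#'   with attribute `truth` (list of `concentration`, `geometry`, `seed`).
#' @export
render_device_image <- function(concentration, geometry, params, seed = 0L) {
  stopifnot(inherits(geometry, "assay_geometry"),
            inherits(params, "generator_params"))
  if (concentration < 0) stop("concentration must be >= 0")
  w <- geometry$image_width_px
  h <- geometry$image_height_px

  set.seed(as.integer(seed %% .Machine$integer.max))
  dx <- dy <- 0L
  if (params$jitter_px > 0) {
    dx <- sample.int(2L * params$jitter_px + 1L, 1L) - params$jitter_px - 1L
    dy <- sample.int(2L * params$jitter_px + 1L, 1L) - params$jitter_px - 1L
  }
  boxes <- lapply(geometry$pad_boxes, function(b) b + c(dx, dy, dx, dy))
  for (b in boxes)
    if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h)
      stop("pad box outside frame after jitter; reduce jitter_px")

  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- params$background_color[ch]
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    col <- if (i - 1L == geometry$active_panel_index)
      true_pad_color(concentration, params) else params$base_color
    rows <- (b[2] + 1):b[4]   # 0-based half-open -> 1-based inclusive
    cols <- (b[1] + 1):b[3]
    for (ch in 1:3) img[rows, cols, ch] <- col[ch]
  }

  if (params$vignette_strength > 0) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    xs <- (seq_len(w) - 1 - cx) / cx
    ys <- (seq_len(h) - 1 - cy) / cy
    r2 <- outer(ys^2, xs^2, `+`) / 2   # normalised squared radius, 1 at corners
    mult <- 1 - params$vignette_strength * r2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * mult
  }

  if (params$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma),
                       dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  geom_out <- geometry
  geom_out$pad_boxes <- lapply(boxes, function(b) {
    names(b) <- c("x0", "y0", "x1", "y1"); b
  })
  structure(img,
            truth = list(concentration = concentration,
                         geometry = geom_out,
                         seed = as.integer(seed)),
            class = c("device_image", "array"))
}

#' @export
print.device_image <- function(x, ...) {
  d <- dim(x)
  tr <- attr(x, "truth")
  cat(sprintf("<device_image %d x %d px>", d[2], d[1]))
  if (!is.null(tr))
    cat(sprintf(" truth: %.3g mg/dl, seed %d", tr$concentration, tr$seed))
  cat("\n")
  invisible(x)
}

#' Generate a labeled calibration image set
#'
#' Renders `length(concentrations) * replicates` device images, each with its
#' own seed spawned deterministically from the master seed, and returns them
#' with their labels.  If `out_dir` is given, the images are written as PNG
#' together with a `manifest.csv` recording filename, concentration, seed,
#' panel index, and the (jittered) active pad box.
#'
#' @param concentrations Vector of known concentrations in mg/dl.
#' @param replicates Number of images per concentration (>= 1).
#' @param geometry,params See [render_device_image()].
#' @param seed Master seed; per-image seeds are derived from it.
#' @param out_dir Optional directory to write PNGs and the manifest to.
#' @return A list with elements `images` (list of `device_image`),
#'   `manifest` (data.frame), and `out_dir`.
#' @export
generate_calibration_set <- function(concentrations, replicates,
                                     geometry = assay_geometry(),
                                     params = generator_params(),
                                     seed = 1L, out_dir = NULL) {
  if (length(concentrations) == 0L) stop("concentration list must be nonempty")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")

  grid <- expand.grid(rep = seq_len(replicates),
                      conc = as.numeric(concentrations))
  # deterministic per-image seed spawning from the master seed
  seeds <- (as.integer(seed) * 10007L + seq_len(nrow(grid)) * 7919L) %%
    .Machine$integer.max
  images <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    img <- render_device_image(grid$conc[i], geometry, params, seed = seeds[i])
    images[[i]] <- img
    tr <- attr(img, "truth")
    b <- tr$geometry$pad_boxes[[tr$geometry$active_panel_index + 1L]]
    rows[[i]] <- data.frame(
      filename = sprintf("device_%03d.png", i),
      concentration_mg_dl = grid$conc[i],
      seed = seeds[i],
      panel_index = tr$geometry$active_panel_index,
      pad_x0 = b["x0"], pad_y0 = b["y0"], pad_x1 = b["x1"], pad_y1 = b["y1"],
      row.names = NULL)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest)))
      write_device_image(images[[i]], file.path(out_dir, manifest$filename[i]))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest, out_dir = out_dir)
}

#' Write a device image as an 8-bit RGB PNG
#'
#' @param image A `device_image` or any `h x w x 3` array in `[0, 255]`.
#' @param path Output file path.
#' @export
write_device_image <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Read an 8-bit RGB image (PNG or JPEG) as a device image
#'
#' @param path Image file path.
#' @return A `device_image` (without ground-truth metadata).
#' @export
read_device_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("jpg", "jpeg")) {
    as.array(EBImage::imageData(EBImage::readImage(path)))
  } else {
    png::readPNG(path)
  }
  if (ext %in% c("jpg", "jpeg")) {
    # EBImage stores x,y[,ch]; transpose to row (y), column (x), channel
    arr <- aperm(arr, c(2, 1, 3))
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  structure(img, class = c("device_image", "array"))
}
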