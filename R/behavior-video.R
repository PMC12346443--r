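# Composite RGB frames for behavior scoring and analytical segmentation of
# the circular arena into concentric zones.

#' Arena geometry
#'
#' A circular arena described by its centre and four increasing zone radii
#' `(central, inner, middle, outer)`. The three annuli between the central
#' zone and the boundary must have equal widths, mirroring the construction
#' in which the central-to-boundary distance is divided into three equal
#' segments.
#'
#' @param center Numeric `(x, y)` centre in pixels.
#' @param zone_radii Numeric vector of 4 strictly increasing radii in px,
#'   named or in order central, inner, middle, outer.
#' @return An object of class `arena_geometry`.
#' @seealso [arena_from_circles()], [classify_zone()]
#' @export
arena_geometry <- function(center, zone_radii) {
  stopifnot(is.numeric(center), length(center) == 2)
  if (length(zone_radii) != 4 || any(!is.finite(zone_radii)))
    abort_input("`zone_radii` must be 4 finite radii")
  if (any(diff(zone_radii) <= 0) || zone_radii[1] <= 0)
    abort_input("`zone_radii` must be positive and strictly increasing")
  w <- diff(zone_radii)
  if (max(w) - min(w) > 1e-6 * zone_radii[4] + 1e-9)
    abort_input("annulus widths must be equal (three equal segments)")
  names(zone_radii) <- c("central", "inner", "middle", "outer")
  structure(list(center = as.numeric(center), zone_radii = zone_radii),
            class = "arena_geometry")
}

#' Build an arena geometry from the two detected circles
#'
#' Splits the distance between the central-marker radius and the outer
#' boundary into three equal annuli.
#'
#' @param center Numeric `(x, y)` centre, px.
#' @param r_central Central-zone radius, px.
#' @param r_outer Arena boundary radius, px (> `r_central`).
#' @return An [arena_geometry()].
#' @export
arena_from_circles <- function(center, r_central, r_outer) {
  check_scalar_num(r_central, "r_central", lower = 1e-12)
  check_scalar_num(r_outer, "r_outer", lower = 1e-12)
  if (r_outer <= r_central)
    abort_input("`r_outer` must exceed `r_central`")
  w <- (r_outer - r_central) / 3
  arena_geometry(center, r_central + w * 0:3)
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> center (%.1f, %.1f), radii %s px\n",
              x$center[1], x$center[2],
              paste(sprintf("%.1f", x$zone_radii), collapse = "/")))
  invisible(x)
}

check_rgb_frame <- function(f) {
  d <- dim(f)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || !is.numeric(f))
    abort_input("each frame must be a numeric H x W x 3 array")
  d[1:2]
}

#' Build one composite RGB frame from 21 consecutive frames
#'
#' Encodes temporal context into colour channels: the green channel is the
#' arithmetic mean of the 10 preceding frames' green channels, the red
#' channel is the centre (11th) frame's red channel, and the blue channel is
#' the mean of the 10 following frames' blue channels. Channel means are
#' computed in floating point; the stored image is quantized to 8-bit depth
#' by rounding half-up.
#'
#' @param frames List of exactly 21 numeric H x W x 3 arrays with values in
#'   \[0, 1\], all of identical dimensions.
#' @param center_index Frame index (within the source video) of the scored
#'   11th frame, recorded as metadata.
#' @return An object of class `composite_frame` with elements `image`
#'   (integer 0-255 H x W x 3), `image_float` (the un-quantized means in
#'   \[0, 1\]) and `center_index`.
#' @export
build_composite <- function(frames, center_index = 11L) {
  if (!is.list(frames) || length(frames) != 21L)
    abort_input("`frames` must be a list of exactly 21 RGB frames")
  dims <- lapply(frames, check_rgb_frame)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    abort_input("all frames must share the same dimensions")
  hw <- dims[[1]]
  g <- Reduce(`+`, lapply(frames[1:10], function(f) f[, , 2])) / 10
  r <- frames[[11]][, , 1]
  b <- Reduce(`+`, lapply(frames[12:21], function(f) f[, , 3])) / 10
  img_f <- array(c(r, g, b), c(hw, 3L))
  structure(list(image = array(as.integer(floor(255 * img_f + 0.5)),
                               dim(img_f)),
                 image_float = img_f,
                 center_index = as.integer(center_index)),
            class = "composite_frame")
}

#' Build composites along a whole video
#'
#' One composite is produced per valid centre index `11, 11 + stride, ...,
#' T - 10` (1-based). Frames whose 21-frame window would fall off either end
#' of the video are skipped; the number of skipped frames is reported via a
#' message and stored as an attribute.
#'
#' @param video_frames List of T >= 21 RGB frames.
#' @param stride Step between consecutive centre indices (>= 1).
#' @return List of `composite_frame` objects with attribute
#'   `skipped_frames`.
#' @export
composite_stream <- function(video_frames, stride = 1L) {
  if (!is.list(video_frames) || length(video_frames) < 21L)
    abort_input("video must contain at least 21 frames")
  check_scalar_num(stride, "stride", lower = 1, integer = TRUE)
  stride <- as.integer(stride)
  t_total <- length(video_frames)
  centers <- seq.int(11L, t_total - 10L, by = stride)
  out <- lapply(centers, function(ci)
    build_composite(video_frames[(ci - 10L):(ci + 10L)], center_index = ci))
  skipped <- 20L
  message(sprintf("composite_stream: %d edge frames skipped (no full window)",
                  skipped))
  attr(out, "skipped_frames") <- skipped
  attr(out, "center_indices") <- centers
  out
}

# Least-squares (Kasa) circle fit to pixel coordinates.
fit_circle <- function(x, y) {
  a <- cbind(2 * x, 2 * y, 1)
  sol <- stats::lm.fit(a, x^2 + y^2)$coefficients
  c(cx = sol[[1]], cy = sol[[2]],
    r = sqrt(sol[[3]] + sol[[1]]^2 + sol[[2]]^2))
}

#' Segment a circular arena image into zone geometry
#'
#' Detects the dominant circular arena boundary and the interior central
#' marker in a grayscale (or grayscale-convertible RGB) image, then splits
#' the annulus between them into three equal-width zones.
#'
#' Detection is contour-based: the image is binarized at mid-contrast, dark
#' connected components are labelled, the component best explained by a
#' circle of maximal radius is taken as the boundary, and the remaining
#' component whose centroid lies nearest the detected centre (within the
#' central region of interest, a box half the image size) is taken as the
#' central marker.
#'
#' @param image Numeric matrix in \[0, 1\] (row = y, column = x), or an
#'   H x W x 3 RGB array (converted by channel mean).
#' @param min_pixels Minimum component size in pixels to be considered.
#' @return An [arena_geometry()].
#' @export
segment_arena <- function(image, min_pixels = 30L) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (!is.matrix(image) || !is.numeric(image))
    abort_input("`image` must be a numeric matrix or RGB array")
  rng <- range(image)
  if (diff(rng) < 1e-6)
    abort_input("no circular boundary found: image has no contrast")
  dark <- image < (rng[1] + rng[2]) / 2
  lab <- EBImage::bwlabel(dark)
  n_comp <- max(lab)
  if (n_comp < 1L)
    abort_input("no circular boundary found")
  comps <- lapply(seq_len(n_comp), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_pixels) return(NULL)
    list(x = idx[, 2], y = idx[, 1], n = nrow(idx))
  })
  comps <- Filter(Negate(is.null), comps)
  if (!length(comps))
    abort_input("no circular boundary found")
  fits <- lapply(comps, function(cp) fit_circle(cp$x, cp$y))
  outer_i <- which.max(vapply(fits, `[[`, 0, "r"))
  ctr <- c(fits[[outer_i]][["cx"]], fits[[outer_i]][["cy"]])
  r_outer <- fits[[outer_i]][["r"]]
  # central marker: nearest remaining centroid within the central ROI box
  roi_half <- min(dim(image)) / 4
  cand <- setdiff(seq_along(comps), outer_i)
  if (!length(cand))
    abort_input("no interior contour found for the central marker")
  cents <- t(vapply(cand, function(i) c(fits[[i]][["cx"]], fits[[i]][["cy"]]),
                    numeric(2)))
  dctr <- sqrt((cents[, 1] - ctr[1])^2 + (cents[, 2] - ctr[2])^2)
  in_roi <- abs(cents[, 1] - ctr[1]) <= roi_half &
    abs(cents[, 2] - ctr[2]) <= roi_half
  if (!any(in_roi))
    abort_input("no interior contour found for the central marker")
  marker_i <- cand[in_roi][which.min(dctr[in_roi])]
  r_central <- fits[[marker_i]][["r"]]
  arena_from_circles(ctr, r_central, r_outer)
}

#' Classify points into arena zones
#'
#' Assigns each 2-D point a zone label by its radial distance from the arena
#' centre, using half-open bins `[0, r_central)`, `[r_central, r_inner)`,
#' `[r_inner, r_middle)`, `[r_middle, r_outer]`; points beyond the boundary
#' are `outside`.
#'
#' @param points Numeric `(x, y)` vector or n x 2 matrix, px.
#' @param arena An [arena_geometry()].
#' @return Character vector of zone labels in
#'   `{central, inner, middle, outer, outside}`.
#' @export
classify_zone <- function(points, arena) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  r <- sqrt((points[, 1] - arena$center[1])^2 +
              (points[, 2] - arena$center[2])^2)
  z <- arena$zone_radii
  labels <- rep("outside", length(r))
  labels[r <= z[["outer"]]] <- "outer"
  labels[r < z[["middle"]]] <- "middle"
  labels[r < z[["inner"]]] <- "inner"
  labels[r < z[["central"]]] <- "central"
  labels
}

#' Write a composite frame to PNG
#' @param composite A `composite_frame` from [build_composite()].
#' @param path Output PNG path.
#' @export
write_composite_png <- function(composite, path) {
  stopifnot(inherits(composite, "composite_frame"))
  png::writePNG(composite$image_float, path)
  invisible(path)
}
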