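#' Frame stack
#'
#' A grayscale imaging recording: a `frames x height x width` array of
#' non-negative intensities with an acquisition frame rate and an excitation
#' wavelength label (`"single"` for one-channel GCaMP recordings, `"340"` /
#' `"380"` for the two Fura-2 channels).
#'
#' @param pixels numeric array, frames x height x width.
#' @param frame_rate acquisition rate in Hz.
#' @param wavelength `"single"`, `"340"` or `"380"`.
#' @return An object of class `frame_stack` (a classed array with attributes).
#' @export
frame_stack <- function(pixels, frame_rate = 5,
                        wavelength = c("single", "340", "380")) {
  wavelength <- match.arg(as.character(wavelength), c("single", "340", "380"))
  if (length(dim(pixels)) != 3L) stop("pixels must be frames x height x width")
  if (dim(pixels)[1] < 1L) stop("stack must contain at least one frame")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0")
  structure(pixels, frame_rate = frame_rate, wavelength = wavelength,
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack %s> %d frames of %d x %d @ %g Hz, range [%g, %g]\n",
              attr(x, "wavelength"), d[1], d[2], d[3], attr(x, "frame_rate"),
              min(x), max(x)))
  invisible(x)
}

#' Read / write frame stacks as multi-page TIFF
#'
#' Stacks are stored one file per wavelength, frame-major (page i = frame i),
#' as 16-bit TIFF; 12-bit camera data (0–4095) round-trips losslessly. Reading
#' a truncated or ragged file raises a format error rather than returning a
#' partial stack.
#'
#' @param path TIFF file path.
#' @param frame_rate,wavelength metadata attached on read (TIFF carries none).
#' @return `read_stack()`: a [frame_stack()]. `write_stack()`: `path`,
#'   invisibly.
#' @export
read_stack <- function(path, frame_rate = 5, wavelength = "single") {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("not a readable TIFF stack: ", conditionMessage(e),
                           call. = FALSE))
  if (length(pages) == 0L) stop("TIFF contains no frames")
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("ragged TIFF: frames differ in shape (", paste(unique(shapes), collapse = ", "), ")")
  d <- dim(pages[[1]])
  a <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  frame_stack(a, frame_rate = frame_rate, wavelength = wavelength)
}

#' @rdname read_stack
#' @param stack a [frame_stack()] with integer-valued intensities in 0–65535.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (max(stack) > 65535) stop("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(i) stack[i, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Regions of interest
#'
#' A named set of polygonal ROIs in pixel coordinates (0-based pixel-center
#' convention, origin top-left: x runs along width, y along height). A pixel
#' (ix, iy) belongs to a polygon if its center lies inside by the even-odd
#' rule.
#'
#' @param polygons named list; each element a 2-column matrix/data.frame of
#'   (x, y) vertices.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons) {
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    stop("every ROI must be named")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each ROI polygon needs >= 3 (x, y) vertices")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  structure(list(polygons = polygons), class = "roi_set")
}

#' Rasterize ROI polygons to pixel masks
#'
#' @param rois a [roi_set()].
#' @param dim image size `c(height, width)`.
#' @param check_overlap reject ROIs sharing pixels.
#' @return Named list of logical `height x width` masks.
#' @export
roi_masks <- function(rois, dim, check_overlap = TRUE) {
  stopifnot(inherits(rois, "roi_set"), length(dim) == 2L)
  h <- dim[1]; w <- dim[2]
  xs <- rep(seq_len(w) - 1L, each = h)   # pixel centers, 0-based
  ys <- rep(seq_len(h) - 1L, times = w)
  masks <- lapply(rois$polygons, function(p) {
    inside <- point_in_polygon(xs, ys, p[, 1], p[, 2])
    matrix(inside, nrow = h, ncol = w)
  })
  for (nm in names(masks)) {
    if (!any(masks[[nm]]))
      stop(sprintf("ROI '%s' covers no pixel inside the %d x %d image", nm, h, w))
  }
  if (check_overlap && length(masks) > 1L) {
    cover <- Reduce(`+`, lapply(masks, function(m) m + 0L))
    if (any(cover > 1L)) stop("overlapping ROIs are not allowed")
  }
  masks
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read / write ROI sets as JSON polygons
#'
#' @param rois a [roi_set()]; `path` a JSON file path.
#' @return `read_rois()`: a [roi_set()]; `write_rois()`: `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  out <- lapply(rois$polygons, function(p)
    list(x = unname(p[, 1]), y = unname(p[, 2])))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(lapply(raw, function(p) cbind(x = p$x, y = p$y)))
}

#' Extract mean-fluorescence ROI traces from a stack
#'
#' For each ROI, the unweighted mean of the pixel intensities inside its mask
#' is taken at every frame — the standard reduction from an imaging recording
#' to per-region time series.
#'
#' @param stack a [frame_stack()].
#' @param rois a [roi_set()] valid for the stack's image size.
#' @return Numeric matrix, `n_frames x n_rois`, with ROI names as columns.
#' @export
extract_roi_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  masks <- roi_masks(rois, d[2:3], check_overlap = FALSE)
  flat <- matrix(unclass(stack), nrow = d[1])  # frames x (h*w), column-major
  out <- vapply(masks, function(m) {
    idx <- which(as.vector(m))
    rowMeans(flat[, idx, drop = FALSE])
  }, numeric(d[1]))
  colnames(out) <- names(masks)
  out
}

#' Read / write long-format trace and amplitude tables
#'
#' Traces: columns `animal, receptor, stimulus, frame, value`. Amplitudes:
#' columns `animal, receptor, stimulus, amplitude` plus optional `dose`.
#' Plain CSV so tables interoperate with spreadsheet-based workflows.
#'
#' @param x a data.frame with the documented columns; `path` a CSV path.
#' @param required columns that must be present on read.
#' @return `read_table_csv()`: a data.frame. `write_table_csv()`: `path`.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("table not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("table lacks required column(s): ", paste(missing, collapse = ", "))
  x
}
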