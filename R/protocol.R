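#' Acquisition and quantification protocol
#'
#' Bundles the frame-rate and the 1-based inclusive frame windows that drive
#' every downstream quantification step: the pre-stimulus baseline used for
#' F0/R0, the stimulus interval, the response window over which amplitudes are
#' averaged, the pre-stimulus window subtracted from bee-convention amplitudes,
#' and the frames excluded from the photobleaching fit.
#'
#' Two presets reproduce the standard designs of insect olfactory imaging:
#'
#' * `"bee"` — ratiometric Fura-2 antennal-lobe imaging: 100 frames at 5 Hz,
#'   stimulus frames 15–20 (1 s), baseline frames 10–14, response frames 17–19,
#'   pre-stimulus frames 9–11, bleach-fit exclusion frames 15–40 (stimulus
#'   onset through 5 s after onset).
#' * `"fly"` — single-wavelength GCaMP transcuticular antennal imaging: same
#'   acquisition, response window frames 17–31 (15 frames after stimulation),
#'   amplitude referenced to the F0 baseline window.
#'
#' @param preset `"bee"`, `"fly"`, or `"custom"` (windows supplied by hand).
#' @param frame_rate acquisition rate in Hz.
#' @param n_frames number of frames per recording.
#' @param baseline_window 1-based inclusive frame interval defining F0/R0.
#' @param stimulus_window frames during which the odorant is presented.
#' @param response_window frames averaged for the response amplitude.
#' @param prestim_window frames averaged and subtracted in the bee convention.
#' @param bleach_exclusion frames excluded from the photobleaching fit
#'   (`NULL` to exclude nothing beyond the fit's own design).
#' @return An object of class `acq_protocol`.
#' @examples
#' acq_protocol("bee")
#' acq_protocol("fly")$response_window
#' @export
acq_protocol <- function(preset = c("bee", "fly", "custom"),
                         frame_rate = 5,
                         n_frames = 100L,
                         baseline_window = c(10L, 14L),
                         stimulus_window = c(15L, 20L),
                         response_window = NULL,
                         prestim_window = NULL,
                         bleach_exclusion = NULL) {
  preset <- match.arg(preset)
  if (preset == "bee") {
    response_window  <- response_window  %||% c(17L, 19L)
    prestim_window   <- prestim_window   %||% c(9L, 11L)
    # onset frame 15 through 5 s (25 frames at 5 Hz) after onset
    bleach_exclusion <- bleach_exclusion %||%
      c(stimulus_window[1], as.integer(stimulus_window[1] + 5 * frame_rate))
  } else if (preset == "fly") {
    response_window <- response_window %||% c(17L, 31L)
    prestim_window  <- prestim_window  %||% baseline_window
  } else {
    if (is.null(response_window)) stop("custom protocol needs a response_window")
    prestim_window <- prestim_window %||% baseline_window
  }
  if (frame_rate <= 0) stop("frame_rate must be positive")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")

  p <- structure(list(
    preset           = preset,
    frame_rate       = frame_rate,
    n_frames         = n_frames,
    baseline_window  = check_window(baseline_window,  "baseline_window",  n_frames),
    stimulus_window  = check_window(stimulus_window,  "stimulus_window",  n_frames),
    response_window  = check_window(response_window,  "response_window",  n_frames),
    prestim_window   = check_window(prestim_window,   "prestim_window",   n_frames),
    bleach_exclusion = if (is.null(bleach_exclusion)) NULL else
      check_window(bleach_exclusion, "bleach_exclusion", n_frames)
  ), class = "acq_protocol")

  if (p$baseline_window[2] >= p$stimulus_window[1])
    stop("baseline_window must end before stimulus_window starts")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.acq_protocol <- function(x, ...) {
  fmt <- function(w) if (is.null(w)) "-" else sprintf("[%d, %d]", w[1], w[2])
  cat(sprintf("<acq_protocol '%s'> %d frames @ %g Hz\n", x$preset, x$n_frames, x$frame_rate))
  cat(sprintf("  baseline %s  stimulus %s  response %s  prestim %s  bleach-excl %s\n",
              fmt(x$baseline_window), fmt(x$stimulus_window), fmt(x$response_window),
              fmt(x$prestim_window), fmt(x$bleach_exclusion)))
  invisible(x)
}

.protocol_keys <- c("preset", "frame_rate", "n_frames", "baseline_window",
                    "stimulus_window", "response_window", "prestim_window",
                    "bleach_exclusion")

#' Read an acquisition protocol from a YAML file
#'
#' The file may give a `preset` ("bee" or "fly") and override any window.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return An [acq_protocol()] object.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  spec <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed protocol YAML (", conditionMessage(e), ")", call. = FALSE))
  if (!is.list(spec)) stop("protocol YAML must be a mapping")
  unknown <- setdiff(names(spec), .protocol_keys)
  if (length(unknown))
    stop("unknown protocol keys: ", paste(unknown, collapse = ", "))
  args <- spec
  args$preset <- spec$preset %||% "custom"
  do.call(acq_protocol, args)
}

#' Write an acquisition protocol to YAML
#' @param protocol an [acq_protocol()] object.
#' @param path output path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "acq_protocol"))
  x <- unclass(protocol)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}
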