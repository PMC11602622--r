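#' Fluorescence trace
#'
#' A per-ROI time series of raw fluorescence (arbitrary units) tied to an
#' acquisition protocol.
#'
#' @param values numeric vector, one fluorescence value per frame.
#' @param protocol an [acq_protocol()] describing the acquisition.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (length(values) != protocol$n_frames)
    stop(sprintf("trace has %d frames but protocol expects %d",
                 length(values), protocol$n_frames))
  structure(list(values = values, protocol = protocol),
            class = "fluorescence_trace")
}

new_delta_trace <- function(values, baseline_value, protocol) {
  structure(list(values = as.numeric(values),
                 baseline_value = baseline_value,
                 protocol = protocol),
            class = "delta_trace")
}

#' Relative fluorescence change (delta-F/F0)
#'
#' Computes `(F - F0) / F0` per frame, with F0 the mean fluorescence over the
#' protocol's baseline window (the five pre-stimulus frames 10–14 in both
#' presets). The result is dimensionless; multiply by 100 to report percent.
#' The same operation applied to a ratio series R = F340/F380 yields delta-R/R.
#'
#' @param trace a [fluorescence_trace()] or a numeric vector (with `protocol`).
#' @param protocol required when `trace` is a bare numeric vector.
#' @return A `delta_trace`: per-frame relative change plus the baseline value.
#' @export
delta_f_over_f0 <- function(trace, protocol = NULL) {
  if (inherits(trace, "fluorescence_trace")) {
    protocol <- trace$protocol
    values <- trace$values
  } else {
    if (is.null(protocol)) stop("protocol required for a bare numeric trace")
    values <- as.numeric(trace)
  }
  f0 <- window_mean(values, protocol$baseline_window)
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf("non-physical baseline: F0 = %g (must be > 0)", f0))
  new_delta_trace((values - f0) / f0, f0, protocol)
}

#' @rdname delta_f_over_f0
#' @export
delta_r_over_r <- delta_f_over_f0

#' Blank-trial photobleaching subtraction
#'
#' Subtracts, frame by frame, the relative-change trace of a stimulus-free
#' (blank) recording from a stimulated one. With a fluorescence reporter that
#' bleaches identically with and without stimulation, this removes the decay
#' while leaving the stimulus transient intact — the single-wavelength
#' correction used for GCaMP antennal recordings.
#'
#' @param delta,blank `delta_trace` objects sharing one protocol.
#' @return A corrected `delta_trace`.
#' @export
blank_subtraction <- function(delta, blank) {
  stopifnot(inherits(delta, "delta_trace"), inherits(blank, "delta_trace"))
  if (length(delta$values) != length(blank$values))
    stop("delta and blank traces differ in length")
  new_delta_trace(delta$values - blank$values, delta$baseline_value, delta$protocol)
}

#' Excitation-ratio time series (Fura-2)
#'
#' Forms R = F340/F380 per ROI trace or per pixel of a dual-wavelength frame
#' stack. Fura-2 fluorescence rises at 340 nm and falls at 380 nm as calcium
#' increases, so the ratio amplifies the signal and cancels bleaching shared
#' by the two channels. Non-positive F380 values are masked (set to `NA`) with
#' a warning; they are an error if they touch the baseline window.
#'
#' @param f340,f380 numeric vectors, `fluorescence_trace`s, or frame stacks
#'   (frames x height x width arrays) of identical dimensions.
#' @param protocol protocol used to check the baseline window (optional for
#'   bare arrays; taken from `f340` when it is a trace).
#' @return Same shape as the input: a numeric vector/array of ratios, or a
#'   `fluorescence_trace`-like ratio trace when traces were supplied.
#' @export
ratio_timeseries <- function(f340, f380, protocol = NULL) {
  is_trace <- inherits(f340, "fluorescence_trace")
  if (is_trace) {
    protocol <- f340$protocol
    f340 <- f340$values
    f380 <- if (inherits(f380, "fluorescence_trace")) f380$values else as.numeric(f380)
  }
  a340 <- unclass_stack(f340); a380 <- unclass_stack(f380)
  if (!identical(dim2(a340), dim2(a380)))
    stop("F340 and F380 inputs differ in dimensions")
  bad <- a380 <= 0
  if (any(bad)) {
    if (!is.null(protocol)) {
      bw <- window_idx(protocol$baseline_window)
      bad_frames <- if (is.null(dim(a380))) which(bad) else
        unique(arrayInd(which(bad), dim(a380))[, 1])
      if (any(bad_frames %in% bw))
        stop("non-positive F380 values inside the baseline window")
    }
    warning(sprintf("%d non-positive F380 value(s) masked as NA", sum(bad)))
    a380[bad] <- NA_real_
  }
  r <- a340 / a380
  if (is_trace) fluorescence_trace(ifelse(is.na(r), 0, r), protocol) else r
}

unclass_stack <- function(x) if (inherits(x, "frame_stack")) unclass_keep_dim(x) else x
unclass_keep_dim <- function(x) { a <- unclass(x); attributes(a) <- list(dim = dim(x)); a }
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Separable width-3 median filter
#'
#' De-noises imaging data with sequential width-3 running medians along the
#' x (width), y (height) and t (frame) axes, in that order, to suppress photon
#' and electronic shot noise without blurring transient edges. Edges are
#' handled by symmetric reflection (the border value is repeated), which for
#' width 3 leaves the first and last samples unchanged. Vectors are filtered
#' along time only; degenerate axes (< 3 samples) are skipped with a warning.
#'
#' @param x numeric vector, or a frames x height x width array / `frame_stack`.
#' @return The filtered object, same shape and class as the input.
#' @export
median_filter_3 <- function(x) {
  if (inherits(x, "delta_trace")) {
    x$values <- median_filter_3(x$values)
    return(x)
  }
  d <- dim(x)
  if (is.null(d)) {
    if (length(x) < 3L) { warning("axis shorter than 3: not filtered"); return(x) }
    return(med3_along_vec(x))
  }
  if (length(d) != 3L) stop("expected a vector or a frames x height x width array")
  for (ax in c(3L, 2L, 1L)) {      # x, then y, then t
    if (d[ax] < 3L) { warning("axis shorter than 3 skipped"); next }
    x <- med3_along(x, ax)
  }
  x
}

# exact elementwise median of three by selection (no arithmetic round-off)
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

med3_along_vec <- function(v) {
  n <- length(v)
  med3(v[c(1L, seq_len(n - 1L))], v, v[c(seq.int(2L, n), n)])
}

med3_along <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_prev <- c(1L, seq_len(n - 1L))
  idx_next <- c(seq.int(2L, n), n)
  sel <- function(idx) {
    args <- rep(list(quote(expr = )), 3L)
    args[[axis]] <- idx
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  m <- med3(sel(idx_prev), a, sel(idx_next))
  dim(m) <- d
  m
}

#' Logarithmic photobleaching correction
#'
#' Fits `f(t) = a + b * log(t - t1 + 1)` (t in frames) by least squares to the
#' trace restricted to frames *outside* the exclusion window — by default the
#' stimulus onset through 5 s after onset — and subtracts the fitted curve
#' from every frame. This removes the slow monotone brightness decay of the
#' dye while leaving the stimulus-locked transient, which lies inside the
#' excluded frames, untouched.
#'
#' @param delta a `delta_trace` (or numeric vector) to correct.
#' @param exclusion 1-based inclusive frame interval excluded from the fit;
#'   defaults to the protocol's `bleach_exclusion`.
#' @param model `"log"` (default) or `"exp"` (`a + b * exp(-t / tau)`), the
#'   latter provided for sensitivity checks against the assumed decay family.
#' @return The corrected object, same class as the input.
#' @export
log_bleach_correction <- function(delta, exclusion = NULL,
                                  model = c("log", "exp")) {
  model <- match.arg(model)
  is_delta <- inherits(delta, "delta_trace")
  values <- if (is_delta) delta$values else as.numeric(delta)
  n <- length(values)
  if (is_delta && is.null(exclusion)) exclusion <- delta$protocol$bleach_exclusion
  keep <- rep(TRUE, n)
  if (!is.null(exclusion)) {
    exclusion <- check_window(exclusion, "exclusion", n)
    keep[window_idx(exclusion)] <- FALSE
  }
  if (sum(keep) < 5L) stop("fewer than 5 frames outside the exclusion window")
  t <- seq_len(n)
  if (stats::sd(values[keep]) == 0) {
    warning("constant input: returning input minus its mean")
    fitted <- rep(mean(values[keep]), n)
  } else if (model == "log") {
    lt <- log(t)                       # t - t1 + 1 with t1 = 1
    fit <- stats::lm.fit(cbind(1, lt[keep]), values[keep])
    fitted <- fit$coefficients[1] + fit$coefficients[2] * lt
  } else {
    df <- data.frame(y = values[keep], t = t[keep])
    fit <- tryCatch(
      stats::nls(y ~ a + b * exp(-t / tau), data = df,
                 start = list(a = mean(df$y), b = df$y[1] - mean(df$y),
                              tau = n / 3)),
      error = function(e) stop("exponential bleach fit failed: ",
                               conditionMessage(e), call. = FALSE))
    fitted <- stats::predict(fit, newdata = data.frame(t = t))
  }
  out <- values - fitted
  if (is_delta) new_delta_trace(out, delta$baseline_value, delta$protocol) else out
}

#' Response amplitude of a processed trace
#'
#' Quantifies a stimulus response from a relative-change trace:
#'
#' * `"bee"` convention — mean over the response window (frames 17–19, during
#'   the stimulus) minus mean over the pre-stimulus window (frames 9–11).
#' * `"fly"` convention — mean over the response window (frames 17–31, the 15
#'   frames after stimulation) minus the mean over the F0 baseline window
#'   (zero by construction of the delta trace; retained for robustness when a
#'   correction step has shifted the baseline).
#'
#' Values are dimensionless fractions; multiply by 100 for percent.
#'
#' @param delta a `delta_trace`.
#' @param convention `"bee"` or `"fly"`; defaults to the protocol preset when
#'   it is one of the two.
#' @return Numeric scalar amplitude.
#' @export
response_amplitude <- function(delta, convention = NULL) {
  stopifnot(inherits(delta, "delta_trace"))
  p <- delta$protocol
  convention <- convention %||% p$preset
  if (!convention %in% c("bee", "fly"))
    stop("unknown amplitude convention: ", convention)
  ref_window <- if (convention == "bee") p$prestim_window else p$baseline_window
  window_mean(delta$values, p$response_window) - window_mean(delta$values, ref_window)
}

#' @export
print.delta_trace <- function(x, ...) {
  cat(sprintf("<delta_trace> %d frames, baseline value %.4g, range [%.3g%%, %.3g%%]\n",
              length(x$values), x$baseline_value,
              100 * min(x$values), 100 * max(x$values)))
  invisible(x)
}
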