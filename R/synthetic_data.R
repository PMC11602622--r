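#' Simulation configuration for synthetic recordings
#'
#' Describes one synthetic imaging recording: acquisition geometry (100 frames
#' at 5 Hz with a 1 s stimulus at frames 15–20, the standard design emulated
#' throughout), a monotone photobleaching model, the stimulus-locked transient
#' kernel, and the noise level. A single integer seed fixes all randomness;
#' replicates draw from counter-based substreams so increasing the replicate
#' count never reshuffles earlier replicates.
#'
#' @param n_frames frames per recording.
#' @param frame_rate acquisition rate, Hz.
#' @param stim_window 1-based inclusive stimulus frames.
#' @param preset protocol preset (`"bee"` or `"fly"`) controlling the
#'   quantification windows the transient is calibrated against.
#' @param bleach photobleaching model: `list(model = "none")`,
#'   `list(model = "log", a, b)` for `a + b*log(t)` (t = 1-based frame), or
#'   `list(model = "exp", a, tau)` for `a*exp(-(t-1)/tau)`.
#' @param transient kernel shape: `list(rise_frames, decay_frames)` of the
#'   difference-of-exponentials transient starting at stimulus onset.
#' @param noise_sd additive noise SD in fluorescence units (>= 0).
#' @param noise_model `"gaussian"` (additive) or `"poisson"` (shot noise;
#'   intensities drawn as Poisson counts around the clean trace).
#' @param baseline resting fluorescence level, a.u.
#' @param n_replicates default replicate count for panel-style simulations.
#' @param seed master integer seed.
#' @return An object of class `sim_config` (includes the derived
#'   [acq_protocol()] as `$protocol`).
#' @export
sim_config <- function(n_frames = 100L, frame_rate = 5, stim_window = c(15L, 20L),
                       preset = c("bee", "fly"),
                       bleach = list(model = "none"),
                       transient = list(rise_frames = 2, decay_frames = 12),
                       noise_sd = 0, noise_model = c("gaussian", "poisson"),
                       baseline = 100, n_replicates = 1L, seed = 1L) {
  preset <- match.arg(preset)
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!bleach$model %in% c("none", "log", "exp"))
    stop("bleach model must be one of none/log/exp")
  if (baseline <= 0) stop("baseline fluorescence must be positive")
  protocol <- acq_protocol(preset, frame_rate = frame_rate, n_frames = n_frames,
                           stimulus_window = stim_window)
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 stim_window = check_window(stim_window, "stim_window", n_frames),
                 preset = preset, bleach = bleach, transient = transient,
                 noise_sd = noise_sd, noise_model = noise_model,
                 baseline = baseline, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), protocol = protocol),
            class = "sim_config")
}

# multiplicative bleach factor per frame (1-based t)
bleach_curve <- function(config) {
  t <- seq_len(config$n_frames)
  b <- config$bleach
  switch(b$model,
         none = rep(1, config$n_frames),
         log  = b$a + b$b * log(t),
         exp  = b$a * exp(-(t - 1) / b$tau))
}

#' Stimulus-locked transient kernel
#'
#' Difference-of-exponentials response shape starting at stimulus onset,
#' scaled so that the protocol's window-based amplitude measure of the kernel
#' is exactly 1 — i.e. a noiseless, bleach-free trace planted with amplitude
#' `a` yields a measured response amplitude of exactly `a`.
#'
#' @param config a [sim_config()].
#' @return Numeric vector of length `n_frames`.
#' @export
transient_kernel <- function(config) {
  onset <- config$stim_window[1]
  t <- seq_len(config$n_frames)
  u <- pmax(t - onset + 1, 0)
  s <- ifelse(u > 0,
              (1 - exp(-u / config$transient$rise_frames)) *
                exp(-u / config$transient$decay_frames),
              0)
  scale <- window_mean(s, config$protocol$response_window)
  if (scale <= 0) stop("transient kernel has no mass in the response window")
  s / scale
}

#' Simulate a single-wavelength fluorescence trace
#'
#' Raw fluorescence is `baseline * bleach(t) * (1 + a * kernel(t)) + noise`,
#' with the transient zero before stimulus onset. The planted amplitude `a`
#' is the value the full delta-F/F0 + amplitude pipeline recovers on
#' noiseless, bleach-free data.
#'
#' @param config a [sim_config()].
#' @param true_amplitude planted response amplitude (delta-F/F0 fraction;
#'   must be > -1 so fluorescence stays positive).
#' @param replicate substream index (see [sim_config()] seed semantics).
#' @return List with `trace` (a [fluorescence_trace()]) and `ground_truth`
#'   (`amplitude`, `bleach`, `kernel`).
#' @export
simulate_trace <- function(config, true_amplitude, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (true_amplitude < -1)
    stop("true_amplitude < -1 would make fluorescence negative")
  s <- transient_kernel(config)
  clean <- config$baseline * bleach_curve(config) * (1 + true_amplitude * s)
  if (any(clean <= 0)) stop("bleach/transient combination drives fluorescence <= 0")
  values <- with_seed(substream_seed(config$seed, replicate), {
    if (config$noise_model == "poisson") {
      stats::rpois(config$n_frames, clean)
    } else if (config$noise_sd > 0) {
      clean + stats::rnorm(config$n_frames, 0, config$noise_sd)
    } else clean
  })
  list(trace = fluorescence_trace(pmax(values, 0), config$protocol),
       ground_truth = list(amplitude = true_amplitude,
                           bleach = config$bleach, kernel = s))
}

#' Simulate a dual-wavelength (Fura-2) ratiometric stack
#'
#' Builds F340/F380 frame stacks in which, inside each ROI, F340 rises and
#' F380 falls symmetrically during the transient so that the pixel ratio
#' change is exactly `delta-R/R = a * kernel(t)` for the planted amplitude
#' `a`. Both channels share the same photobleaching curve, as for a single
#' dye imaged at two excitation wavelengths.
#'
#' @param config a [sim_config()] (preset `"bee"`).
#' @param rois a [roi_set()]; overlapping or out-of-image ROIs are rejected.
#' @param true_amplitudes named numeric, planted delta-R/R per ROI.
#' @param image_dim image size `c(height, width)`.
#' @param base_340,base_380 resting intensities of the two channels, a.u.
#' @param replicate substream index.
#' @return List with `f340`, `f380` ([frame_stack()]s), `rois`, and
#'   `ground_truth` (per-ROI amplitudes).
#' @export
simulate_ratiometric_stack <- function(config, rois, true_amplitudes,
                                       image_dim = c(32L, 32L),
                                       base_340 = 1000, base_380 = 2000,
                                       replicate = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(rois, "roi_set"))
  masks <- roi_masks(rois, image_dim, check_overlap = TRUE)
  if (is.null(names(true_amplitudes)) ||
      !setequal(names(true_amplitudes), names(masks)))
    stop("true_amplitudes must be named to match the ROIs")
  if (any(true_amplitudes <= -1)) stop("amplitudes must be > -1")
  s <- transient_kernel(config)
  n <- config$n_frames
  bl <- bleach_curve(config)
  amp_img <- matrix(0, image_dim[1], image_dim[2])
  for (nm in names(masks)) amp_img[masks[[nm]]] <- true_amplitudes[[nm]]

  # per pixel/frame: u = a s / (2 + a s)  =>  (1+u)/(1-u) = 1 + a s exactly
  as_tf <- outer(s, as.vector(amp_img))            # frames x pixels
  u <- as_tf / (2 + as_tf)
  f340 <- base_340 * bl * (1 + u)
  f380 <- base_380 * bl * (1 - u)
  if (config$noise_sd > 0) {
    noise <- with_seed(substream_seed(config$seed, replicate),
                       stats::rnorm(2 * length(f340), 0, config$noise_sd))
    f340 <- f340 + noise[seq_along(f340)]
    f380 <- f380 + noise[length(f340) + seq_along(f380)]
  }
  shape <- c(n, image_dim[1], image_dim[2])
  list(f340 = frame_stack(array(pmax(f340, 0), shape), config$frame_rate, "340"),
       f380 = frame_stack(array(pmax(f380, 0), shape), config$frame_rate, "380"),
       rois = rois,
       ground_truth = list(amplitudes = true_amplitudes, kernel = s))
}

#' Simulate a receptor x odorant response panel
#'
#' Draws per-animal response amplitudes around planted mean spectra, plus a
#' solvent control column with mean zero, emulating a deorphanization screen
#' in which each animal is tested with the full odorant panel.
#'
#' @param planted_spectra nonnegative matrix, receptors (rows, named) x
#'   stimuli (columns, named), of true mean amplitudes.
#' @param noise_sd between-trial SD added to every measurement.
#' @param n_animals animals per receptor (>= 2).
#' @param seed integer seed.
#' @param add_solvent append a `"solvent"` column with true mean 0.
#' @param cluster_labels optional planted group label per receptor, carried
#'   into the ground truth for cluster-recovery tests.
#' @return List with `responses` (long data.frame: animal, receptor,
#'   stimulus, amplitude) and `ground_truth`.
#' @export
simulate_response_panel <- function(planted_spectra, noise_sd = 0,
                                    n_animals = 12L, seed = 1L,
                                    add_solvent = TRUE, cluster_labels = NULL) {
  planted_spectra <- as.matrix(planted_spectra)
  if (any(planted_spectra < 0)) stop("planted spectra must be nonnegative")
  if (n_animals < 2L) stop("n_animals must be >= 2 for any statistics")
  if (is.null(rownames(planted_spectra)))
    rownames(planted_spectra) <- paste0("R", seq_len(nrow(planted_spectra)))
  if (is.null(colnames(planted_spectra)))
    colnames(planted_spectra) <- paste0("S", seq_len(ncol(planted_spectra)))
  if (add_solvent)
    planted_spectra <- cbind(planted_spectra,
                             solvent = rep(0, nrow(planted_spectra)))
  recs <- rownames(planted_spectra); stims <- colnames(planted_spectra)
  rows <- vector("list", length(recs))
  for (ri in seq_along(recs)) {
    draws <- with_seed(substream_seed(seed, ri), {
      m <- matrix(rep(planted_spectra[ri, ], each = n_animals),
                  nrow = n_animals)
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      m
    })
    rows[[ri]] <- data.frame(
      animal = rep(paste0(recs[ri], "_a", seq_len(n_animals)), times = length(stims)),
      receptor = recs[ri],
      stimulus = rep(stims, each = n_animals),
      amplitude = as.vector(draws))
  }
  list(responses = do.call(rbind, rows),
       ground_truth = list(spectra = planted_spectra,
                           cluster_labels = cluster_labels,
                           noise_sd = noise_sd, n_animals = n_animals))
}

#' Paper-scale OR11 dose-response presets
#'
#' Published half-maximal doses (EC50, micrograms on filter paper, mean +/-
#' SEM over animals) and Hill coefficients of the 9-ODA dose-response curves
#' of the four honeybee OR11 orthologs, with the study's per-receptor sample
#' sizes. Used as realistic defaults for simulation and recovery analyses.
#' @format data.frame with columns receptor, ec50, ec50_sem, hill, hill_sem, n.
#' @export
or11_dose_presets <- data.frame(
  receptor = c("AcerOR11", "AdorOR11", "AmelOR11", "AflorOR11"),
  ec50     = c(174.8, 173.4, 160.5, 175.8),
  ec50_sem = c(26.05, 22.22, 28.46, 29.59),
  hill     = c(4.71, 6.98, 2.31, 13.04),
  hill_sem = c(1.76, 2.83, 0.24, 8.02),
  n        = c(12L, 12L, 12L, 12L))

#' The standard 9-point dose ladder (micrograms on filter paper)
#' @export
dose_ladder <- c(0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000)

#' Simulate replicate dose-response series
#'
#' Hill-model responses at the given doses plus a 0-dose solvent point equal
#' to `bottom` + noise, per animal.
#'
#' @param doses positive doses (micrograms); defaults to [dose_ladder].
#' @param ec50 half-maximal dose; `hill` slope (> 0); `top`, `bottom`
#'   asymptotes (response units).
#' @param noise_sd per-measurement SD; `n_animals` replicate animals.
#' @param seed integer seed.
#' @param receptor,ligand labels carried into the table.
#' @param include_solvent include the 0-dose solvent point.
#' @return List with `series` (data.frame: animal, dose, amplitude, receptor,
#'   ligand) and `ground_truth`.
#' @export
simulate_dose_series <- function(doses = dose_ladder, ec50 = 174.8,
                                 hill = 4.71, top = 1, bottom = 0,
                                 noise_sd = 0, n_animals = 12L, seed = 1L,
                                 receptor = "OR11", ligand = "9-ODA",
                                 include_solvent = TRUE) {
  if (any(doses <= 0)) stop("doses must be positive (solvent is added separately)")
  if (hill <= 0) stop("Hill coefficient must be > 0")
  if (ec50 <= 0) stop("ec50 must be > 0")
  doses <- sort(doses)
  all_doses <- if (include_solvent) c(0, doses) else doses
  mu <- hill_model(all_doses, bottom, top, ec50, hill)
  rows <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    y <- with_seed(substream_seed(seed, a), {
      if (noise_sd > 0) mu + stats::rnorm(length(mu), 0, noise_sd) else mu
    })
    rows[[a]] <- data.frame(animal = paste0("a", a), dose = all_doses,
                            amplitude = y, receptor = receptor, ligand = ligand)
  }
  list(series = do.call(rbind, rows),
       ground_truth = list(ec50 = ec50, hill = hill, top = top,
                           bottom = bottom, noise_sd = noise_sd))
}

#' Simulate a stimulus-driven spike train
#'
#' Inhomogeneous-Poisson spike times with a piecewise-constant rate: the
#' baseline rate outside the stimulus interval and the stimulus rate inside
#' it. A `regular` mode emits evenly spaced (non-Poisson) spikes at the same
#' piecewise rates, for detector and rate-estimator identities.
#'
#' @param baseline_rate,stim_rate rates in spikes/s (>= 0).
#' @param stim_interval stimulus interval `c(start, end)` in seconds.
#' @param duration recording length in seconds (> 0).
#' @param seed integer seed.
#' @param regular emit regular instead of Poisson spikes.
#' @return List with `train` (a [spike_train()]) and `ground_truth`.
#' @export
simulate_spike_train <- function(baseline_rate, stim_rate,
                                 stim_interval = c(3, 4), duration = 20,
                                 seed = 1L, regular = FALSE) {
  if (baseline_rate < 0 || stim_rate < 0) stop("rates must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (stim_interval[1] < 0 || stim_interval[2] > duration ||
      stim_interval[2] <= stim_interval[1])
    stop("stim_interval must lie within [0, duration]")
  segs <- data.frame(start = c(0, stim_interval[1], stim_interval[2]),
                     end   = c(stim_interval[1], stim_interval[2], duration),
                     rate  = c(baseline_rate, stim_rate, baseline_rate))
  segs <- segs[segs$end > segs$start, ]
  times <- with_seed(substream_seed(seed, 1L), {
    unlist(lapply(seq_len(nrow(segs)), function(i) {
      len <- segs$end[i] - segs$start[i]; r <- segs$rate[i]
      if (r <= 0) return(numeric(0))
      if (regular) {
        seq(segs$start[i] + 1 / (2 * r), segs$end[i], by = 1 / r)
      } else {
        k <- stats::rpois(1, r * len)
        sort(stats::runif(k, segs$start[i], segs$end[i]))
      }
    }))
  })
  times <- sort(times[times >= 0 & times <= duration])
  list(train = spike_train(times, duration, stim_interval),
       ground_truth = list(baseline_rate = baseline_rate,
                           stim_rate = stim_rate,
                           stim_interval = stim_interval))
}

#' Render a spike train as a sampled voltage-like trace
#'
#' Places a fixed biphasic spike waveform (~2 ms) at each spike time on a
#' Gaussian-noise background, for spike-detector testing.
#'
#' @param train a [spike_train()].
#' @param sample_rate sampling rate, Hz.
#' @param noise_sd background noise SD (waveform peak is ~`amplitude`).
#' @param amplitude waveform peak amplitude.
#' @param seed integer seed for the noise.
#' @return List with `trace` (numeric vector) and `sample_rate`.
#' @export
render_spike_train <- function(train, sample_rate = 10000, noise_sd = 0,
                               amplitude = 1, seed = 1L) {
  stopifnot(inherits(train, "spike_train"))
  n <- ceiling(train$duration * sample_rate)
  tm <- seq(0, 0.002, by = 1 / sample_rate)
  waveform <- amplitude * (exp(-((tm - 0.0005) / 2e-4)^2) -
                             0.6 * exp(-((tm - 0.0012) / 4e-4)^2))
  trace <- if (noise_sd > 0)
    with_seed(substream_seed(seed, 1L), stats::rnorm(n, 0, noise_sd))
  else numeric(n)
  for (t in train$times) {
    i0 <- floor(t * sample_rate) + 1L
    idx <- i0:min(i0 + length(waveform) - 1L, n)
    trace[idx] <- trace[idx] + waveform[seq_along(idx)]
  }
  list(trace = trace, sample_rate = sample_rate)
}
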