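#' Four-parameter Hill (log-logistic) model
#'
#' `y(d) = bottom + (top - bottom) / (1 + (ec50 / d)^hill)`, the
#' variable-slope sigmoid on log-dose standard for agonist dose-response
#' curves. At `d = 0` the response is the bottom asymptote.
#'
#' @param dose doses (>= 0).
#' @param bottom,top asymptotes; `ec50` half-maximal dose; `hill` slope.
#' @return Predicted responses.
#' @export
hill_model <- function(dose, bottom, top, ec50, hill) {
  y <- rep(bottom, length(dose))
  pos <- dose > 0
  y[pos] <- bottom + (top - bottom) / (1 + (ec50 / dose[pos])^hill)
  y
}

# single-curve bounded LM fit with multi-start; returns coef, se, rss
fit_hill_curve <- function(dose, y) {
  if (length(dose) != length(y)) stop("dose and response lengths differ")
  pos <- dose > 0
  if (sum(pos) < 4L || length(unique(dose[pos])) < 4L)
    stop("need >= 4 distinct nonzero doses to fit a Hill curve")
  if (diff(range(y)) == 0) stop("flat dose-response data: Hill fit undefined")
  per_dose <- tapply(y, dose, mean)
  dvals <- as.numeric(names(per_dose))
  scale_y <- diff(range(per_dose))
  if (scale_y < 1e-12 * max(abs(y), 1))
    stop("flat dose-response data: Hill fit undefined")

  b0 <- if (any(dose == 0)) mean(y[dose == 0]) else per_dose[[1]]
  t0 <- per_dose[[length(per_dose)]]
  # EC50 start: dose at which the mean curve crosses halfway between b0 and t0
  half <- (b0 + t0) / 2
  crossing <- {
    pm <- per_dose[dvals > 0]; pd <- dvals[dvals > 0]
    i <- which(diff(sign(pm - half)) != 0)
    if (length(i)) sqrt(pd[i[1]] * pd[i[1] + 1]) else stats::median(pd)
  }
  # EC50 constrained to one decade beyond the tested dose range: outside it
  # the data cannot identify a half-maximal dose anyway
  ld_lo <- log10(min(dose[pos])) - 1; ld_hi <- log10(max(dose[pos])) + 1

  df <- data.frame(dose = dose, y = y)
  try_start <- function(h0, l0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ hill_model(dose, bottom, top, 10^logec50, hill), data = df,
        start = list(bottom = b0, top = t0,
                     logec50 = min(max(l0, ld_lo), ld_hi), hill = h0),
        lower = c(-Inf, -Inf, ld_lo, 1e-3),
        upper = c(Inf, Inf, ld_hi, 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, rss = sum(stats::residuals(fit)^2))
  }
  best <- NULL
  starts <- expand.grid(h0 = c(0.5, 2, 5), l0 = log10(crossing))
  for (i in seq_len(nrow(starts))) {
    cand <- try_start(starts$h0[i], starts$l0[i])
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss - 1e-12))
      best <- cand
  }
  if (is.null(best)) {     # wider deterministic grid as a fallback
    starts <- expand.grid(h0 = c(0.25, 1, 3, 10),
                          l0 = log10(crossing) + c(-1, -0.5, 0.5, 1))
    for (i in seq_len(nrow(starts))) {
      cand <- try_start(starts$h0[i], starts$l0[i])
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss - 1e-12))
        best <- cand
    }
  }
  if (is.null(best)) stop("Hill fit did not converge for any start")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ec50 <- 10^cf[["logec50"]]
  if (abs(cf[["top"]] - cf[["bottom"]]) < 1e-9 * max(scale_y, 1))
    stop("flat dose-response data: fitted top equals bottom")
  warn <- character(0)
  if (ec50 < min(dose[pos]) || ec50 > max(dose[pos]))
    warn <- "EC50 outside the tested dose range (extrapolated)"
  # delta method: SE(ec50) = ln(10) * ec50 * SE(logec50)
  list(ec50 = ec50, ec50_se = log(10) * ec50 * unname(se["logec50"]),
       hill = cf[["hill"]], hill_se = unname(se["hill"]),
       top = cf[["top"]], bottom = cf[["bottom"]],
       rss = best$rss, converged = TRUE, warnings = warn)
}

#' Fit a Hill dose-response curve (EC50, Hill coefficient)
#'
#' Least-squares fit of the four-parameter Hill model on log-dose, with
#' 0-dose (solvent) replicates entering the loss as observations of the
#' bottom asymptote rather than at a fake log-dose. The optimizer is bounded
#' Levenberg-Marquardt with a deterministic multi-start over slope and EC50
#' initializations (EC50 started at the half-maximum crossing dose).
#'
#' Two modes:
#' * `"per_animal"` (default) — fit each animal's curve separately; EC50 and
#'   Hill are reported as mean +/- SEM across animals, the form needed to
#'   compare parameters between receptors with rank tests.
#' * `"pooled"` — one fit to all points; SEs come from the fit covariance.
#'
#' @param series data.frame with columns `dose`, `amplitude`, and (for
#'   per-animal mode) `animal`; dose 0 rows are the solvent.
#' @param mode `"per_animal"` or `"pooled"`.
#' @return List of class `dose_response_fit`: `ec50`, `ec50_se`, `hill`,
#'   `hill_se`, `top`, `bottom`, `mode`, `n`, `rss`, `per_animal` (table of
#'   per-animal parameters in per-animal mode), `warnings`.
#' @export
fit_hill <- function(series, mode = c("per_animal", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(c("dose", "amplitude") %in% names(series)))
  if (any(series$dose < 0)) stop("doses must be >= 0")
  if (mode == "pooled" || !"animal" %in% names(series)) {
    f <- fit_hill_curve(series$dose, series$amplitude)
    res <- c(f, list(mode = "pooled", n = length(unique(series$dose)),
                     per_animal = NULL))
  } else {
    animals <- unique(series$animal)
    fits <- lapply(animals, function(a) {
      s <- series[series$animal == a, ]
      tryCatch(fit_hill_curve(s$dose, s$amplitude), error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (sum(ok) < max(2L, length(animals) / 2))
      stop("Hill fit failed for more than half the animals")
    if (any(!ok))
      warning(sprintf("Hill fit failed for %d of %d animals; dropped",
                      sum(!ok), length(animals)))
    tab <- do.call(rbind, lapply(which(ok), function(i)
      data.frame(animal = animals[i], ec50 = fits[[i]]$ec50,
                 hill = fits[[i]]$hill, top = fits[[i]]$top,
                 bottom = fits[[i]]$bottom, rss = fits[[i]]$rss)))
    m <- nrow(tab)
    res <- list(ec50 = mean(tab$ec50), ec50_se = stats::sd(tab$ec50) / sqrt(m),
                hill = mean(tab$hill), hill_se = stats::sd(tab$hill) / sqrt(m),
                top = mean(tab$top), bottom = mean(tab$bottom),
                rss = sum(tab$rss), converged = TRUE, mode = "per_animal",
                n = m, per_animal = tab,
                warnings = unique(unlist(lapply(fits[ok], `[[`, "warnings"))))
  }
  structure(res, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit, %s mode, n = %d>\n", x$mode, x$n))
  cat(sprintf("  EC50 = %.4g +/- %.3g   Hill = %.3g +/- %.3g   top = %.3g  bottom = %.3g\n",
              x$ec50, x$ec50_se, x$hill, x$hill_se, x$top, x$bottom))
  if (length(x$warnings)) cat("  warning:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Normalize a dose-response series to its own curve
#'
#' Affine rescale of a receptor's dose-response data so the solvent (0-dose)
#' mean maps to 0% and the mean at the highest dose to 100%; replicate
#' scatter is rescaled identically. Curves of receptors with equal EC50 but
#' different maximal responses overlap after this normalization.
#'
#' @param series data.frame with `dose` and `amplitude` (dose 0 = solvent).
#' @return The series with `amplitude` in percent of own maximum; attributes
#'   `solvent_mean` and `top_mean` record the anchors.
#' @export
normalize_dose_curve <- function(series) {
  stopifnot(all(c("dose", "amplitude") %in% names(series)))
  if (!any(series$dose == 0)) stop("series has no solvent (0-dose) rows")
  s <- mean(series$amplitude[series$dose == 0])
  top_dose <- max(series$dose)
  t <- mean(series$amplitude[series$dose == top_dose])
  if (t <= s)
    stop(sprintf("top-dose mean (%g) must exceed solvent mean (%g)", t, s))
  series$amplitude <- 100 * (series$amplitude - s) / (t - s)
  attr(series, "solvent_mean") <- s
  attr(series, "top_mean") <- t
  series
}

#' Normalize a secondary-ligand series to the 9-ODA maximum
#'
#' Expresses a secondary ligand's responses as a percentage of the same
#' receptor's mean response to the reference ligand (9-ODA) at its maximum
#' dose, so efficacies of weaker ligands can be compared across receptors.
#'
#' @param secondary dose series of the secondary ligand.
#' @param reference dose series of the reference ligand (same receptor).
#' @return `secondary` with `amplitude` in percent of the reference maximum.
#' @export
cross_ligand_normalization <- function(secondary, reference) {
  stopifnot(all(c("dose", "amplitude") %in% names(secondary)),
            all(c("dose", "amplitude") %in% names(reference)))
  ref_pos <- reference[reference$dose > 0, ]
  if (nrow(ref_pos) == 0) stop("reference series has no nonzero doses")
  top_dose <- max(ref_pos$dose)
  m <- mean(ref_pos$amplitude[ref_pos$dose == top_dose])
  if (!is.finite(m) || m <= 0)
    stop("reference top-dose mean response must be positive")
  secondary$amplitude <- 100 * secondary$amplitude / m
  attr(secondary, "reference_max") <- m
  secondary
}
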