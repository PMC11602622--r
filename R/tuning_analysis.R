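#' Aggregate a long response table to mean response spectra
#'
#' Averages amplitudes across animals within receptor x stimulus, yielding
#' one mean response spectrum per receptor.
#'
#' @param responses long data.frame with columns `receptor`, `stimulus`,
#'   `amplitude` (and typically `animal`).
#' @return Numeric matrix, receptors x stimuli, of mean amplitudes.
#' @export
response_spectra <- function(responses) {
  stopifnot(all(c("receptor", "stimulus", "amplitude") %in% names(responses)))
  tab <- tapply(responses$amplitude,
                list(responses$receptor, responses$stimulus), mean)
  # keep first-appearance order rather than alphabetical
  tab[unique(responses$receptor), unique(responses$stimulus), drop = FALSE]
}

#' Lifetime sparseness (tuning breadth)
#'
#' Quantifies how narrowly a receptor is tuned across a stimulus panel using
#' the lifetime-sparseness statistic of a response distribution:
#'
#' \deqn{S = \frac{1}{1 - 1/n}\left(1 -
#'   \frac{(\sum_i r_i / n)^2}{\sum_i r_i^2 / n}\right)}
#'
#' with \eqn{r_i} the response amplitude to stimulus i among n stimuli.
#' S is bounded in \[0, 1\]: 0 for a perfectly uniform (generalist) spectrum
#' and 1 for a receptor responding to a single stimulus (specialist). The
#' formula cannot accommodate negative responses, so negatives are clamped to
#' zero before evaluation and the clamp count is reported.
#'
#' @param spectrum numeric vector of response amplitudes (n >= 2).
#' @return List of class `sparseness_result`: `S`, `n`, `n_clamped`.
#' @examples
#' sparseness(c(1, 1, 1, 1))$S   # 0: uniform
#' sparseness(c(0, 0, 0, 5))$S   # 1: specialist
#' @export
sparseness <- function(spectrum) {
  r <- as.numeric(spectrum)
  n <- length(r)
  if (n < 2L) stop("sparseness needs at least 2 stimuli")
  if (any(!is.finite(r))) stop("spectrum must be finite")
  n_clamped <- sum(r < 0)
  r[r < 0] <- 0
  if (all(r == 0))
    stop("sparseness undefined for an all-zero (or all-negative) spectrum")
  S <- (1 / (1 - 1 / n)) * (1 - (sum(r) / n)^2 / (sum(r^2) / n))
  structure(list(S = S, n = n, n_clamped = n_clamped),
            class = "sparseness_result")
}

#' @export
print.sparseness_result <- function(x, ...) {
  cat(sprintf("Lifetime sparseness S = %.4f (n = %d stimuli, %d negative response(s) clamped)\n",
              x$S, x$n, x$n_clamped))
  invisible(x)
}

#' Min-max normalize a response spectrum to reference stimuli
#'
#' Rescales a spectrum so that the response to a reference maximum stimulus
#' (the principal ligand, 9-ODA by default) maps to 100% and the solvent
#' response to 0%. Values falling outside \[0, 100\] are flagged and can be
#' clipped.
#'
#' @param spectrum named numeric vector of responses.
#' @param max_stimulus,min_stimulus names of the reference stimuli.
#' @param clip clip out-of-range values into \[0, 100\].
#' @return Numeric vector in percent, with attribute `flagged` naming any
#'   out-of-range stimuli (before clipping).
#' @export
normalize_spectrum <- function(spectrum, max_stimulus = "9-ODA",
                               min_stimulus = "solvent", clip = FALSE) {
  if (is.null(names(spectrum))) stop("spectrum must be named by stimulus")
  for (ref in c(max_stimulus, min_stimulus))
    if (!ref %in% names(spectrum))
      stop("reference stimulus not in spectrum: ", ref)
  hi <- spectrum[[max_stimulus]]; lo <- spectrum[[min_stimulus]]
  if (hi <= lo)
    stop(sprintf("reference maximum (%g) must exceed reference minimum (%g)", hi, lo))
  out <- 100 * (spectrum - lo) / (hi - lo)
  flagged <- names(out)[out < 0 | out > 100]
  if (clip) out <- pmin(pmax(out, 0), 100)
  attr(out, "flagged") <- flagged
  out
}

#' Hierarchical clustering of receptor response spectra
#'
#' Assesses similarity among response patterns by agglomerative clustering of
#' the receptors' (typically normalized) spectra: Euclidean distance with
#' average (UPGMA) linkage by default. The metric and linkage actually used
#' are recorded in the result so downstream reports are self-describing.
#'
#' @param spectra numeric matrix, receptors (rows, named) x stimuli (columns);
#'   all receptors must share one stimulus set (no NAs).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return List of class `dendrogram_result`: the `hclust` tree, merge
#'   `heights`, `labels`, `metric`, `linkage`.
#' @export
cluster_receptors <- function(spectra, metric = "euclidean",
                              linkage = "average") {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2L) stop("clustering needs >= 2 receptors")
  if (any(is.na(spectra)))
    stop("mismatched stimulus sets: spectra contain missing values")
  hc <- stats::hclust(stats::dist(spectra, method = metric), method = linkage)
  structure(list(hclust = hc, heights = hc$height, labels = hc$labels,
                 metric = metric, linkage = linkage),
            class = "dendrogram_result")
}

#' Leaf partition at the first (deepest) split of a dendrogram
#'
#' @param dres a [cluster_receptors()] result.
#' @return List of two character vectors of receptor labels.
#' @export
first_split <- function(dres) {
  stopifnot(inherits(dres, "dendrogram_result"))
  k2 <- stats::cutree(dres$hclust, k = 2)
  split(names(k2), k2)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from merge heights (ultrametric tree).
#'
#' @param dres a [cluster_receptors()] result.
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(dres, path) {
  stopifnot(inherits(dres, "dendrogram_result"))
  ape::write.tree(ape::as.phylo(dres$hclust), file = path)
  invisible(path)
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("<dendrogram_result> %d receptors, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  cat("  merge heights:", paste(signif(x$heights, 4), collapse = ", "), "\n")
  invisible(x)
}
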