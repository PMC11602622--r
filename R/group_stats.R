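# Hypothesis-testing layer, implemented from the standard formulas so every
# statistic the pipeline reports is auditable: tie-corrected Friedman and
# Kruskal-Wallis rank tests with Dunn's post hoc z-comparisons, and one-way
# repeated-measures ANOVA with Greenhouse-Geisser sphericity correction and
# Dunnett many-to-one comparisons. Exact permutation p-values are available
# for small designs.

new_test_result <- function(...) structure(list(...), class = "test_result")

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(unlist(x$df), 4), collapse = ", "),
              x$p))
  if (!is.null(x$epsilon))
    cat(sprintf("  Greenhouse-Geisser epsilon = %.4f\n", x$epsilon))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (", x$posthoc_method, "):\n", sep = "")
    print(format(x$posthoc, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

adjust_p <- function(p, method) {
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "holm")
}

# ---- Friedman -------------------------------------------------------------

friedman_statistic <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  Rj <- colSums(ranks)
  chi0 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(ranks, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C <= 0) return(0)       # all values tied within every row
  chi0 / C
}

#' Friedman test with Dunn's post hoc comparisons
#'
#' Within-animal rank test for differences among stimuli in a complete
#' repeated-measures design (each animal receives every stimulus). The
#' chi-square statistic uses within-row ranking with tie correction. Post hoc
#' Dunn rank-sum z-comparisons are run against a control stimulus (or all
#' pairs), with Bonferroni (default) or Holm multiplicity adjustment.
#' For small designs an exact permutation p-value can be computed by
#' enumerating all (k!)^n within-row orderings.
#'
#' @param mat numeric matrix, animals (rows) x stimuli (columns, named);
#'   missing cells are an error (no imputation).
#' @param control column name or index of the control stimulus for Dunn
#'   comparisons; `NULL` for all pairwise comparisons.
#' @param p_adjust `"bonferroni"` (default) or `"holm"`.
#' @param method `"asymptotic"` chi-square p, or `"exact"` permutation p.
#' @param max_perm guard on the number of enumerated orderings for `"exact"`.
#' @return A `test_result` with `statistic`, `df`, `p`, and a `posthoc` table
#'   (comparison, z, p_raw, p_adj).
#' @export
friedman_with_dunn <- function(mat, control = NULL,
                               p_adjust = c("bonferroni", "holm"),
                               method = c("asymptotic", "exact"),
                               max_perm = 2e6) {
  p_adjust <- match.arg(p_adjust); method <- match.arg(method)
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("missing cells are not allowed (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 3L) stop("Friedman test needs >= 3 stimuli")
  if (n < 2L) stop("Friedman test needs >= 2 animals")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(k))

  ranks <- t(apply(mat, 1, rank))
  stat <- friedman_statistic(ranks)
  p <- if (method == "asymptotic") {
    stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    perms <- permutations_of(k)
    if (nrow(perms)^n > max_perm)
      stop("exact enumeration too large; use method = 'asymptotic'")
    count_ge_friedman(ranks, perms, stat)
  }

  Rj <- colSums(ranks)
  sigma <- sqrt(n * k * (k + 1) / 6)
  pairs <- comparison_pairs(colnames(mat), control)
  z <- (Rj[pairs[, 1]] - Rj[pairs[, 2]]) / sigma
  p_raw <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(
    comparison = paste(pairs[, 1], "vs", pairs[, 2]),
    z = unname(z), p_raw = unname(p_raw),
    p_adj = pmin(unname(adjust_p(p_raw, p_adjust)), 1))
  new_test_result(method = "Friedman test (tie-corrected)",
                  statistic = stat, df = list(df = k - 1), p = p,
                  posthoc = posthoc,
                  posthoc_method = paste0("Dunn, ", p_adjust),
                  p_kind = method)
}

# all permutations of 1..k as a matrix (k! rows), by inserting k everywhere
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) for (i in seq_len(nrow(sub))) {
    out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    row <- row + 1L
  }
  out
}

# exact permutation p for the Friedman statistic: enumerate row orderings
count_ge_friedman <- function(ranks, perms, stat_obs) {
  n <- nrow(ranks); np <- nrow(perms)
  idx <- rep(1L, n)
  total <- np^n
  count <- 0
  permuted <- ranks
  repeat {
    for (r in seq_len(n)) permuted[r, ] <- ranks[r, perms[idx[r], ]]
    if (friedman_statistic(permuted) >= stat_obs - 1e-12) count <- count + 1
    # odometer increment
    pos <- 1L
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= np) break
      idx[pos] <- 1L; pos <- pos + 1L
      if (pos > n) return(count / total)
    }
  }
}

comparison_pairs <- function(labels, control) {
  if (is.null(control)) {
    cmb <- utils::combn(labels, 2)
    cbind(cmb[1, ], cmb[2, ])
  } else {
    if (is.numeric(control)) control <- labels[control]
    if (!control %in% labels) stop("control level not found: ", control)
    others <- setdiff(labels, control)
    cbind(others, rep(control, length(others)))
  }
}

# ---- Kruskal-Wallis -------------------------------------------------------

kw_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  nj <- tabulate(g)
  H0 <- 12 / (N * (N + 1)) * sum(nj * Rbar^2) - 3 * (N + 1)
  tt <- table(values)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) return(0)
  H0 / C
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank test for location differences among independent groups (e.g. EC50
#' values of different receptors), with tie-corrected H statistic and Dunn's
#' pairwise z-comparisons under Bonferroni (default) or Holm adjustment.
#' For small samples an exact permutation p-value enumerates all distinct
#' assignments of the pooled observations to the groups.
#'
#' @param groups named list of numeric vectors, one per group (each n >= 2).
#' @param control group name for many-to-one Dunn comparisons; `NULL` for all
#'   pairs.
#' @param p_adjust `"bonferroni"` or `"holm"`.
#' @param method `"asymptotic"` or `"exact"`.
#' @param max_perm guard on the number of enumerated assignments.
#' @return A `test_result` with `statistic` (H), `df`, `p`, `posthoc`.
#' @export
kruskal_wallis_dunn <- function(groups, control = NULL,
                                p_adjust = c("bonferroni", "holm"),
                                method = c("asymptotic", "exact"),
                                max_perm = 2e6) {
  p_adjust <- match.arg(p_adjust); method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 samples")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  nj <- lengths(groups)
  if (any(nj < 2L)) stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), nj))
  N <- length(values)

  H <- kw_statistic(values, g)
  p <- if (method == "asymptotic") {
    stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  } else {
    n_assign <- exp(lgamma(N + 1) - sum(lgamma(nj + 1)))
    if (n_assign > max_perm)
      stop("exact enumeration too large; use method = 'asymptotic'")
    kw_exact_p(values, nj, H)
  }

  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  tt <- table(values)
  tie_term <- sum(tt^3 - tt) / (12 * (N - 1))
  pairs <- comparison_pairs(names(groups), control)
  i1 <- match(pairs[, 1], names(groups)); i2 <- match(pairs[, 2], names(groups))
  sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nj[i1] + 1 / nj[i2]))
  z <- (Rbar[i1] - Rbar[i2]) / sigma
  p_raw <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(
    comparison = paste(pairs[, 1], "vs", pairs[, 2]),
    z = unname(as.numeric(z)), p_raw = unname(as.numeric(p_raw)),
    p_adj = pmin(unname(adjust_p(as.numeric(p_raw), p_adjust)), 1))
  new_test_result(method = "Kruskal-Wallis test (tie-corrected)",
                  statistic = H, df = list(df = length(groups) - 1), p = p,
                  posthoc = posthoc,
                  posthoc_method = paste0("Dunn, ", p_adjust),
                  p_kind = method)
}

# enumerate all distinct group assignments of the pooled values
kw_exact_p <- function(values, nj, H_obs) {
  N <- length(values)
  count <- 0; total <- 0
  # iterate over which value-indices go to each group, via nested combn
  idx_all <- seq_len(N)
  assign_group <- function(gi, avail, labels) {
    if (gi > length(nj)) {
      glab <- integer(N)
      for (k in seq_along(labels)) glab[labels[[k]]] <- k
      total <<- total + 1
      if (kw_statistic(values, factor(glab, levels = seq_along(nj))) >=
          H_obs - 1e-12) count <<- count + 1
      return(invisible(NULL))
    }
    if (gi == length(nj)) return(assign_group(gi + 1L, integer(0),
                                              c(labels, list(avail))))
    cmb <- utils::combn(avail, nj[gi], simplify = FALSE)
    for (pick in cmb)
      assign_group(gi + 1L, setdiff(avail, pick), c(labels, list(pick)))
    invisible(NULL)
  }
  assign_group(1L, idx_all, list())
  count / total
}

# ---- Repeated-measures ANOVA with GG correction and Dunnett ---------------

#' Greenhouse-Geisser epsilon from a sample covariance of conditions
#'
#' `epsilon = tr(CSC)^2 / ((k-1) * tr((CSC)^2))` with C the centering matrix
#' `I - J/k`; equals 1 under perfect sphericity and is clamped below at
#' `1/(k-1)`.
#'
#' @param S k x k sample covariance matrix of the conditions.
#' @return Scalar epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  C <- diag(k) - matrix(1 / k, k, k)
  A <- C %*% S %*% C
  eps <- sum(diag(A))^2 / ((k - 1) * sum(A * A))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction and
#' Dunnett's many-to-one comparisons
#'
#' Classic within-subject one-way ANOVA: the F ratio compares the
#' between-condition mean square with the subject x condition interaction
#' mean square. Because within-subject designs rarely satisfy sphericity,
#' the p-value uses Greenhouse-Geisser-corrected degrees of freedom
#' (`epsilon * (k-1)`, `epsilon * (k-1)(n-1)`). Post hoc comparisons of each
#' condition against a control use Dunnett's procedure: t statistics on the
#' pooled error term, with the adjusted p from the multivariate-t
#' distribution of the maximum statistic (correlation 1/2 in a balanced
#' many-to-one family).
#'
#' @param mat numeric matrix, subjects (rows) x conditions (columns, named);
#'   complete (no NA).
#' @param control column name or index of the control condition.
#' @param gg apply the Greenhouse-Geisser correction (default `TRUE`).
#' @return A `test_result` with `statistic` (F), `df` (corrected), `epsilon`,
#'   `p`, and a Dunnett `posthoc` table (comparison, estimate, t, p_adj).
#' @export
rm_anova_gg_dunnett <- function(mat, control = 1L, gg = TRUE) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("missing cells are not allowed")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 3L) stop("repeated-measures ANOVA needs >= 3 conditions")
  if (n < 2L) stop("needs >= 2 subjects")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("C", seq_len(k))

  grand <- mean(mat)
  cond_means <- colMeans(mat)
  subj_means <- rowMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  if (ms_err <= .Machine$double.eps * max(ss_tot, 1)) {
    # no subject x condition variability left: either the conditions are
    # identical up to per-animal offsets (null by construction) or the data
    # are too degenerate to form an F ratio
    if (ss_cond <= .Machine$double.eps * max(ss_tot, 1)) {
      others <- setdiff(colnames(mat),
                        if (is.numeric(control)) colnames(mat)[control] else control)
      return(new_test_result(
        method = "Repeated-measures ANOVA (Greenhouse-Geisser corrected)",
        statistic = 0, df = list(df1 = df1, df2 = df2), epsilon = 1, p = 1,
        posthoc = data.frame(comparison = paste(others, "vs",
                                                setdiff(colnames(mat), others)[1]),
                             estimate = 0, t = 0, p_adj = 1),
        posthoc_method = "Dunnett (multivariate t)", p_kind = "asymptotic"))
    }
    stop("degenerate within-animal variance: error mean square is zero")
  }
  Fstat <- (ss_cond / df1) / ms_err

  eps <- if (gg) gg_epsilon(stats::cov(mat)) else 1
  p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)

  if (is.numeric(control)) control <- colnames(mat)[control]
  if (!control %in% colnames(mat)) stop("control condition not found: ", control)
  others <- setdiff(colnames(mat), control)
  est <- cond_means[others] - cond_means[[control]]
  se <- sqrt(2 * ms_err / n)
  tstat <- est / se
  m <- length(others)
  corr <- matrix(0.5, m, m); diag(corr) <- 1
  p_adj <- vapply(abs(tstat), function(tq) {
    if (m == 1L) return(2 * stats::pt(-tq, df2))
    pr <- with_seed(20240101, mvtnorm::pmvt(
      lower = rep(-tq, m), upper = rep(tq, m), df = as.integer(df2),
      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                  maxpts = 100000)))
    max(1 - as.numeric(pr), 0)
  }, numeric(1))
  posthoc <- data.frame(comparison = paste(others, "vs", control),
                        estimate = unname(est), t = unname(tstat),
                        p_adj = unname(pmin(p_adj, 1)))
  new_test_result(method = if (gg)
    "Repeated-measures ANOVA (Greenhouse-Geisser corrected)"
    else "Repeated-measures ANOVA",
    statistic = Fstat,
    df = list(df1 = eps * df1, df2 = eps * df2),
    epsilon = if (gg) eps else NULL, p = p,
    posthoc = posthoc, posthoc_method = "Dunnett (multivariate t)",
    p_kind = "asymptotic")
}
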