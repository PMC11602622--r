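# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (loops instead of vectorized pmin/pmax,
# base-R tests instead of the package statistics) so agreement is evidence,
# not tautology.

# width-3 median along one axis of a 3D array, symmetric edge padding
brute_med3_axis <- function(a, axis) {
  d <- dim(a)
  out <- a
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    lo <- idx; hi <- idx
    lo[axis] <- max(1, idx[axis] - 1)
    hi[axis] <- min(d[axis], idx[axis] + 1)
    mid <- a[i, j, k]
    out[i, j, k] <- median(c(a[lo[1], lo[2], lo[3]], mid, a[hi[1], hi[2], hi[3]]))
  }
  out
}

brute_median_filter_3 <- function(a) {
  a <- brute_med3_axis(a, 3)  # x
  a <- brute_med3_axis(a, 2)  # y
  brute_med3_axis(a, 1)       # t
}

# all permutations of a vector, plain recursion
brute_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in brute_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# exact Friedman permutation p using base R's friedman.test statistic
brute_friedman_exact_p <- function(mat) {
  obs <- suppressWarnings(friedman.test(mat)$statistic)
  perms <- brute_perms(seq_len(ncol(mat)))
  idx <- rep(1L, nrow(mat))
  np <- length(perms)
  count <- 0; total <- 0
  repeat {
    m <- mat
    for (r in seq_len(nrow(mat))) m[r, ] <- mat[r, perms[[idx[r]]]]
    stat <- suppressWarnings(friedman.test(m)$statistic)
    total <- total + 1
    if (stat >= obs - 1e-12) count <- count + 1
    pos <- 1L
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= np) break
      idx[pos] <- 1L; pos <- pos + 1L
      if (pos > nrow(mat)) return(count / total)
    }
  }
}

# exact Kruskal-Wallis permutation p using base R's kruskal.test statistic
brute_kw_exact_p <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  nj <- lengths(groups)
  g_obs <- rep(seq_along(nj), nj)
  obs <- suppressWarnings(kruskal.test(values, factor(g_obs))$statistic)
  count <- 0; total <- 0
  recurse <- function(avail, gi, labels) {
    if (gi == length(nj)) {
      glab <- integer(length(values))
      for (k in seq_along(labels)) glab[labels[[k]]] <- k
      glab[avail] <- gi
      stat <- suppressWarnings(kruskal.test(values, factor(glab))$statistic)
      total <<- total + 1
      if (stat >= obs - 1e-12) count <<- count + 1
      return(invisible(NULL))
    }
    for (pick in combn(avail, nj[gi], simplify = FALSE))
      recurse(setdiff(avail, pick), gi + 1L, c(labels, list(pick)))
  }
  recurse(seq_along(values), 1L, list())
  count / total
}

# hand-computed UPGMA merge heights for exactly 3 leaves
brute_upgma3_heights <- function(d12, d13, d23) {
  dd <- c(d12, d13, d23)
  first <- min(dd)
  rest <- switch(which.min(dd),
                 mean(c(d13, d23)),   # 1+2 merged first
                 mean(c(d12, d23)),   # 1+3 merged first
                 mean(c(d12, d13)))   # 2+3 merged first
  c(first, rest)
}

# standard-design bee protocol used in many fixtures
bee_protocol <- function() acq_protocol("bee")

# build a delta_trace directly from relative-change values
new_delta_trace_for_test <- function(values, protocol)
  calcitune:::new_delta_trace(values, 1, protocol)
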