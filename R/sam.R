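# Significance Analysis of Microarrays: moderated d statistics, the s0
# exchangeability constant, label-permutation nulls, delta-based calling at
# a target FDR, q-values and pairwise permutation p-values.

# Per-gene numerator and scatter for the d statistic.
# Two groups: num = mean(level2) - mean(level1) (level1 = reference),
#             s   = sqrt((1/n1 + 1/n2) * pooled within-group variance).
# K >= 3:     num = sqrt(SSB / (K - 1)), s = sqrt(SSW / (N - K)),
# so that (num/s)^2 is the classical one-way F statistic.
.d_parts <- function(x, groups) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  groups <- droplevels(factor(groups))
  K <- nlevels(groups)
  nk <- tabulate(groups)
  N <- ncol(x)
  if (K < 2) stop("need at least two groups", call. = FALSE)
  if (any(nk < 2)) {
    stop("group with fewer than 2 samples: ",
         paste(levels(groups)[nk < 2], collapse = ", "), call. = FALSE)
  }
  G <- stats::model.matrix(~ 0 + groups)           # N x K indicator
  S <- x %*% G                                     # group sums
  M <- sweep(S, 2, nk, "/")                        # group means
  Q <- rowSums(x^2)
  ssw <- Q - as.vector(S^2 %*% (1 / nk))
  ssw <- pmax(ssw, 0)
  if (K == 2) {
    num <- M[, 2] - M[, 1]
    s <- sqrt((1 / nk[1] + 1 / nk[2]) * ssw / (N - 2))
  } else {
    xbar <- rowSums(x) / N
    ssb <- pmax(as.vector(S^2 %*% (1 / nk)) - N * xbar^2, 0)
    num <- sqrt(ssb / (K - 1))
    s <- sqrt(ssw / (N - K))
  }
  list(num = num, s = s, means = M, groups = groups, nk = nk)
}

#' Two-class SAM d statistic
#'
#' \eqn{d = (\bar{x}_2 - \bar{x}_1) / (s + s_0)} with \eqn{s} the pooled
#' standard error of the mean difference and \eqn{s_0} the exchangeability
#' constant. The first factor level is the reference: positive d means the
#' second (test) group is higher.
#'
#' @param x numeric matrix (genes x samples) or a single sample vector.
#' @param groups two-level factor over the columns, ordered
#'   (reference, test); each level needs at least 2 samples.
#' @param s0 non-negative exchangeability constant added to the scatter.
#' @return numeric vector of d values, one per gene.
#' @export
two_class_d <- function(x, groups, s0 = 0) {
  p <- .d_parts(x, groups)
  if (nlevels(p$groups) != 2) stop("two_class_d needs exactly two groups", call. = FALSE)
  unname(p$num / (p$s + s0))
}

#' Multiclass SAM d statistic
#'
#' \eqn{d = \sqrt{SSB/(K-1)} / (s_i + s_0)} with
#' \eqn{SSB = \sum_k n_k (\bar{x}_k - \bar{x})^2} and
#' \eqn{s_i = \sqrt{SSW/(N-K)}}. At \eqn{s_0 = 0}, \eqn{d^2} equals the
#' classical one-way F statistic.
#'
#' @inheritParams two_class_d
#' @param groups factor with K >= 2 levels over the columns.
#' @return numeric vector of non-negative d values, one per gene.
#' @export
multiclass_d <- function(x, groups, s0 = 0) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) == 2) return(abs(two_class_d(x, groups, s0)))
  p <- .d_parts(x, groups)
  unname(p$num / (p$s + s0))
}

#' Estimate the SAM exchangeability constant s0
#'
#' Searches the percentiles of the per-gene scatters \code{s} (0 to 100 in
#' steps of 5) for the candidate s0 that minimizes the coefficient of
#' variation of the median absolute deviation of \code{d = num/(s + s0)}
#' across s-quantile windows, stabilizing d for low-variance genes.
#'
#' @param s per-gene scatters (denominator of d before adding s0).
#' @param num per-gene raw numerators of d.
#' @param n_windows number of s-quantile windows for the spread criterion.
#' @return the chosen s0 (a percentile of \code{s}), always >= 0.
#' @export
estimate_s0 <- function(s, num, n_windows = 10) {
  stopifnot(length(s) == length(num))
  if (all(s == 0)) {
    warning("all per-gene scatters are zero; using floor s0 = 1e-8")
    return(1e-8)
  }
  if (length(s) < 20) warning("fewer than 20 genes: s0 estimate is unstable")
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  if (length(cand) == 1) return(cand)
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = n_windows + 1),
                                   names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- num / (s + a)
    v <- tapply(d, win, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

# Distinct arrangements of the label multiset: choose(N,n1)*choose(N-n1,n2)*...
.n_arrangements <- function(nk) {
  N <- sum(nk)
  out <- 1
  for (k in seq_along(nk)) {
    out <- out * choose(N, nk[k])
    N <- N - nk[k]
  }
  out
}

# Enumerate all distinct assignments of labels 1..K with sizes nk to N slots.
# Returns a matrix, one arrangement per row, entries = group index per sample.
.enumerate_arrangements <- function(nk) {
  N <- sum(nk)
  recurse <- function(slots, k) {
    if (k == length(nk)) {
      m <- matrix(0L, 1, N)
      m[1, slots] <- as.integer(k)
      return(m)
    }
    picks <- utils::combn(slots, nk[k])
    do.call(rbind, lapply(seq_len(ncol(picks)), function(j) {
      sub <- recurse(setdiff(slots, picks[, j]), k + 1)
      sub[, picks[, j]] <- k
      sub
    }))
  }
  recurse(seq_len(N), 1)
}

#' Permutation null distribution of the SAM d statistic
#'
#' Recomputes the d statistic under label permutations with the same s0 as
#' the observed statistic. When the number of distinct label arrangements
#' is at most \code{B}, all of them are enumerated (the observed labeling
#' is then one arrangement, flagged in the result); otherwise \code{B}
#' unique arrangements are sampled uniformly.
#'
#' @inheritParams two_class_d
#' @param B maximum number of permutations.
#' @param seed integer seed for the sampled case.
#' @return object of class \code{"sam_null"}: list with \code{d}
#'   (arrangements x genes matrix), \code{enumerated} (logical),
#'   \code{identity_row} (row index of the observed labeling under full
#'   enumeration, otherwise \code{NA}), and \code{B} (number of rows).
#' @export
permutation_null <- function(x, groups, B = 1000, seed = 1, s0 = 0) {
  stopifnot(B >= 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  groups <- droplevels(factor(groups))
  K <- nlevels(groups)
  nk <- tabulate(groups)
  N <- ncol(x)
  n_arr <- .n_arrangements(nk)
  obs <- as.integer(groups)
  if (n_arr <= B) {
    assign <- .enumerate_arrangements(nk)
    identity_row <- which(apply(assign, 1, function(r) all(r == obs)))[1]
    enumerated <- TRUE
  } else {
    set.seed(seed)
    keys <- character(0)
    assign <- matrix(0L, 0, N)
    while (nrow(assign) < B) {
      draw <- t(vapply(seq_len(B - nrow(assign)),
                       function(i) obs[sample.int(N)], integer(N)))
      assign <- rbind(assign, draw)
      keys <- apply(assign, 1, paste, collapse = ",")
      assign <- assign[!duplicated(keys), , drop = FALSE]
    }
    identity_row <- NA_integer_
    enumerated <- FALSE
  }
  nb <- nrow(assign)
  # group sums for every arrangement at once: S_k = x %*% I_k (N x nb)
  Sk <- lapply(seq_len(K), function(k) x %*% t(assign == k))
  Q <- rowSums(x^2)
  ssw <- Q - Reduce(`+`, Map(function(S, n) S^2 / n, Sk, nk))
  ssw <- pmax(ssw, 0)
  if (K == 2) {
    num <- Sk[[2]] / nk[2] - Sk[[1]] / nk[1]
    s <- sqrt((1 / nk[1] + 1 / nk[2]) * ssw / (N - 2))
  } else {
    xbar <- rowSums(x) / N
    ssb <- pmax(Reduce(`+`, Map(function(S, n) S^2 / n, Sk, nk)) - N * xbar^2, 0)
    num <- sqrt(ssb / (K - 1))
    s <- sqrt(ssw / (N - K))
  }
  d <- t(num / (s + s0))                      # arrangements x genes
  structure(list(d = d, enumerated = enumerated, identity_row = identity_row,
                 B = nb, s0 = s0),
            class = "sam_null")
}

#' Delta-threshold gene calling at a target FDR
#'
#' Ranks observed d values against the expected order statistics of the
#' permutation null (the mean of the sorted null d across permutations) and
#' scans a delta grid: at each delta, genes whose sorted d exceeds its
#' expected value by at least delta (and, for signed statistics, falls
#' below it by at least delta) are called, data-derived cut points are
#' taken, and the FDR is estimated as pi0 times the median permutation
#' count of null d beyond the cuts, divided by the number of calls. pi0 is
#' the fraction of observed d inside the interquartile band of the null,
#' divided by 0.5 and capped at 1. The reported delta is the smallest grid
#' value whose estimated FDR meets the target; a gene's q-value is the
#' minimum estimated FDR over the deltas at which it is called.
#'
#' @param d observed per-gene d values.
#' @param null a \code{"sam_null"} object (or its d matrix).
#' @param target_fdr target false discovery rate in (0, 1).
#' @param sided \code{"both"} for signed (two-class) d, \code{"up"} for
#'   non-negative multiclass d.
#' @param n_delta number of grid points between 0 and the largest
#'   |d - expected| gap.
#' @return list with \code{delta} (chosen threshold, \code{Inf} when
#'   nothing is callable at the target), \code{called} (integer gene
#'   indices), \code{fdr} (estimated FDR at the chosen delta), \code{q}
#'   (per-gene q-values), \code{pi0}, and the full \code{grid} data.frame
#'   (delta, n_called, fdr).
#' @export
call_genes_fdr <- function(d, null, target_fdr = 0.05,
                           sided = c("both", "up"), n_delta = 101) {
  sided <- match.arg(sided)
  dn <- if (inherits(null, "sam_null")) null$d else null
  m <- length(d)
  stopifnot(ncol(dn) == m)
  ord <- order(d)
  ds <- d[ord]
  sorted_null <- apply(dn, 1, sort)            # genes x arrangements
  dbar <- rowMeans(sorted_null)                # expected order statistics
  gap <- ds - dbar
  qn <- stats::quantile(dn, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d >= qn[1] & d <= qn[2]) / 0.5)
  deltas <- seq(0, max(abs(gap)), length.out = n_delta)

  call_at <- function(delta) {
    below <- which(gap < delta)
    up <- if (length(below)) {
      t <- max(below)
      if (t < m) seq(t + 1, m) else integer(0)
    } else seq_len(m)
    down <- integer(0)
    if (sided == "both") {
      above <- which(gap > -delta)
      down <- if (length(above)) {
        t <- min(above)
        if (t > 1) seq_len(t - 1) else integer(0)
      } else seq_len(m)
    }
    list(up = up, down = down)
  }

  calls <- lapply(deltas, call_at)
  cutup <- vapply(calls, function(cl) if (length(cl$up)) min(ds[cl$up]) else Inf,
                  numeric(1))
  cutlow <- vapply(calls, function(cl) if (length(cl$down)) max(ds[cl$down]) else -Inf,
                   numeric(1))
  n_called <- vapply(calls, function(cl) length(cl$up) + length(cl$down), numeric(1))
  # per permutation, #{null d >= cutup} + #{null d <= cutlow} for every delta
  # at once via binary search in the already-sorted null rows
  false_counts <- vapply(seq_len(ncol(sorted_null)), function(b) {
    v <- sorted_null[, b]
    (m - findInterval(cutup, v, left.open = TRUE)) + findInterval(cutlow, v)
  }, numeric(length(deltas)))
  false <- apply(false_counts, 1, stats::median)
  grid <- data.frame(delta = deltas, n_called = n_called,
                     fdr = ifelse(n_called == 0, 0,
                                  pmin(1, pi0 * false / pmax(n_called, 1))))
  called_at <- lapply(calls, function(cl) ord[c(cl$down, cl$up)])

  q <- rep(1, m)
  for (i in seq_along(deltas)) {
    idx <- called_at[[i]]
    if (length(idx)) q[idx] <- pmin(q[idx], grid$fdr[i])
  }

  ok <- which(grid$fdr <= target_fdr & grid$n_called > 0)
  if (length(ok)) {
    pick <- ok[1]
    list(delta = deltas[pick], called = sort(called_at[[pick]]),
         fdr = grid$fdr[pick], q = q, pi0 = pi0, grid = grid)
  } else {
    list(delta = Inf, called = integer(0), fdr = NA_real_, q = q,
         pi0 = pi0, grid = grid)
  }
}

#' Multiclass SAM analysis of a three-group expression matrix
#'
#' End-to-end SAM over K groups: estimates s0 from the per-gene scatters,
#' computes observed multiclass d, builds the permutation null with the
#' same s0, and calls genes at the target FDR with per-gene q-values.
#'
#' @inheritParams two_class_d
#' @inheritParams permutation_null
#' @inheritParams call_genes_fdr
#' @param s0 exchangeability constant; \code{NULL} (default) estimates it
#'   with [estimate_s0()].
#' @return object of class \code{"sam_result"}: list with \code{d},
#'   \code{s0}, \code{pi0}, \code{delta}, \code{fdr}, \code{called}
#'   (gene indices), \code{q}, \code{means} (per-group means), the delta
#'   \code{grid}, and \code{null} (the \code{"sam_null"} object).
#' @examples
#' sim <- generate_expression(synthetic_config(n_genes = 200, seed = 3))
#' res <- sam_multiclass(sim$expr, sim$samples$group, B = 100, seed = 3)
#' length(res$called)
#' @export
sam_multiclass <- function(x, groups, B = 1000, seed = 1,
                           target_fdr = 0.05, s0 = NULL) {
  groups <- droplevels(factor(groups))
  p <- .d_parts(x, groups)
  if (is.null(s0)) s0 <- estimate_s0(p$s, p$num)
  d <- unname(p$num / (p$s + s0))
  null <- permutation_null(x, groups, B = B, seed = seed, s0 = s0)
  sided <- if (nlevels(groups) == 2) "both" else "up"
  call <- call_genes_fdr(d, null, target_fdr = target_fdr, sided = sided)
  means <- p$means
  colnames(means) <- levels(groups)
  structure(list(d = d, s0 = s0, pi0 = call$pi0, delta = call$delta,
                 fdr = call$fdr, called = call$called, q = call$q,
                 means = means, grid = call$grid, null = null,
                 genes = rownames(x), target_fdr = target_fdr),
            class = "sam_result")
}

#' Pairwise SAM permutation p-values
#'
#' Two-sided permutation p-values for one pairwise comparison:
#' \eqn{p = (1 + \#\{|d_{null}| \ge |d_{obs}|\}) / (1 + B_{eff})} with the
#' add-one correction. Under full enumeration the identity arrangement is
#' excluded from the null, so \eqn{B_{eff}} is the number of distinct
#' non-identity arrangements and p-values are exact multiples of
#' \eqn{1/(B_{eff}+1)}. A Bonferroni significance flag at
#' \code{alpha/n_tests} is reported alongside the unadjusted flag.
#'
#' @inheritParams two_class_d
#' @inheritParams permutation_null
#' @param alpha significance level for the flags.
#' @param n_tests number of pairwise comparisons the Bonferroni flag
#'   corrects for (3 for the three-group design).
#' @return data.frame with one row per gene: \code{d}, \code{p},
#'   \code{significant} (p < alpha) and \code{significant_bonferroni}
#'   (p < alpha/n_tests); the s0 used is attached as an attribute.
#' @export
pairwise_p <- function(x, groups, B = 1000, seed = 1, s0 = NULL,
                       alpha = 0.05, n_tests = 3) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("pairwise_p needs exactly two groups", call. = FALSE)
  p <- .d_parts(x, groups)
  if (is.null(s0)) s0 <- suppressWarnings(estimate_s0(p$s, p$num))
  d <- unname(p$num / (p$s + s0))
  null <- permutation_null(x, groups, B = B, seed = seed, s0 = s0)
  dn <- null$d
  if (null$enumerated && !is.na(null$identity_row)) {
    dn <- dn[-null$identity_row, , drop = FALSE]
  }
  b_eff <- nrow(dn)
  # tie comparison with a relative tolerance: the observed and permuted d
  # travel different (vectorized) arithmetic paths, and exact |d| ties occur
  # by symmetry (e.g. the label-swapped arrangement)
  thresh <- abs(d) * (1 - 1e-9)
  exceed <- colSums(abs(dn) >= matrix(thresh, nrow = b_eff, ncol = length(d),
                                      byrow = TRUE))
  pv <- (1 + exceed) / (1 + b_eff)
  out <- data.frame(gene = if (is.null(rownames(x))) seq_along(d) else rownames(x),
                    d = d, p = pv,
                    significant = pv < alpha,
                    significant_bonferroni = pv < alpha / n_tests,
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "B_effective") <- b_eff
  out
}
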