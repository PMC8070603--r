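test_that("two-class d matches the pooled-SE formula and its symmetries", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  g <- two_groups(3, 3)
  # mean diff 3, pooled SE sqrt((1/3+1/3)*((2+2)/4)) = 0.8165
  expect_equal(two_class_d(x, g), 3 / 0.8164966, tolerance = 1e-6)
  expect_equal(two_class_d(x, g, s0 = 0), -two_class_d(x, factor(g, rev(levels(g)))))
  # equal group means give d = 0
  expect_equal(two_class_d(matrix(c(1, 2, 3, 3, 2, 1), 1), g), 0)
  expect_error(two_class_d(x, factor(c("A", "B", "B", "B", "B", "B"))),
               "fewer than 2")
})

test_that("multiclass d squared equals the one-way F statistic at s0 = 0", {
  for (i in 1:100) {
    set.seed(i)
    nk <- sample(2:6, 3, replace = TRUE)
    g <- factor(rep(c("a", "b", "c"), nk))
    x <- matrix(rnorm(2 * sum(nk)), 2)
    d <- multiclass_d(x, g, s0 = 0)
    f <- apply(x, 1, function(v) summary(stats::aov(v ~ g))[[1]][["F value"]][1])
    expect_equal(d^2, f, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # equal group means give d = 0; s0 strictly shrinks |d|
  xeq <- matrix(rep(c(1, 2), 6), 1)
  geq <- factor(rep(1:3, each = 4))
  expect_equal(multiclass_d(xeq, geq), 0)
  x <- matrix(rnorm(12), 1)
  expect_lt(multiclass_d(x, geq, s0 = 1), multiclass_d(x, geq, s0 = 0))
})

test_that("s0 estimation follows the CV-of-MAD percentile search", {
  # homoscedastic scatters: every percentile is the common value
  s <- rep(0.7, 100)
  num <- rnorm(100)
  expect_equal(estimate_s0(s, num), 0.7)
  expect_warning(out <- estimate_s0(rep(0, 30), rnorm(30)), "floor")
  expect_equal(out, 1e-8)
  expect_warning(estimate_s0(runif(10), rnorm(10)), "fewer than 20")
  # heterogeneous scatters: matches an exhaustive recomputation of the criterion
  set.seed(77)
  s <- sqrt(rchisq(500, 4) / 4)
  num <- rnorm(500, sd = s)
  oracle <- {
    cand <- unique(quantile(s, seq(0, 1, 0.05), names = FALSE))
    breaks <- unique(quantile(s, seq(0, 1, length.out = 11), names = FALSE))
    win <- cut(s, breaks, include.lowest = TRUE)
    cvs <- numeric(length(cand))
    for (k in seq_along(cand)) {
      d <- num / (s + cand[k])
      mads <- numeric(0)
      for (w in levels(win)) {
        dw <- d[win == w]
        if (length(dw)) mads <- c(mads, mad(dw))
      }
      cvs[k] <- sd(mads) / mean(mads)
    }
    cand[which.min(cvs)]
  }
  est <- estimate_s0(s, num)
  expect_equal(est, oracle)
  expect_gte(est, 0)
})

test_that("permutation null enumerates small designs and is seed-reproducible", {
  x <- random_matrix(5, 6, seed = 2)
  g <- two_groups(3, 3)
  null <- permutation_null(x, g, B = 1000, s0 = 0.1)
  expect_true(null$enumerated)
  expect_equal(null$B, choose(6, 3))     # 20 distinct arrangements
  expect_false(is.na(null$identity_row))
  # the identity arrangement row reproduces the observed d
  expect_equal(null$d[null$identity_row, ], two_class_d(x, g, s0 = 0.1),
               ignore_attr = TRUE)
  # sampled case: fixed seed reproduces the matrix, arrangements are unique
  y <- random_matrix(10, 20, seed = 3)
  gy <- two_groups(10, 10)
  n1 <- permutation_null(y, gy, B = 50, seed = 7, s0 = 0.2)
  n2 <- permutation_null(y, gy, B = 50, seed = 7, s0 = 0.2)
  expect_identical(n1$d, n2$d)
  expect_equal(nrow(unique(n1$d)), 50)
})

test_that("delta calling matches a brute-force implementation on a tiny instance", {
  set.seed(123)
  x <- random_matrix(8, 6, seed = 123)
  x[1:2, 4:6] <- x[1:2, 4:6] + 4        # two strong genes
  g <- two_groups(3, 3)
  s0 <- 0.2
  d <- two_class_d(x, g, s0 = s0)
  null <- permutation_null(x, g, B = 1000, s0 = s0)
  res <- call_genes_fdr(d, null, target_fdr = 0.25, sided = "both")

  # independent brute force of the same definitions, plain loops throughout
  dn <- null$d
  m <- length(d)
  ord <- order(d); ds <- d[ord]
  dbar <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(nrow(dn))
    for (b in seq_len(nrow(dn))) vals[b] <- sort(dn[b, ])[i]
    dbar[i] <- mean(vals)
  }
  qs <- quantile(as.vector(dn), c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d >= qs[1] & d <= qs[2]) / 0.5)
  gap <- ds - dbar
  deltas <- seq(0, max(abs(gap)), length.out = 101)
  best <- NULL
  for (delta in deltas) {
    up <- integer(0)
    for (i in m:1) {
      if (gap[i] >= delta) up <- c(up, i) else break
    }
    down <- integer(0)
    for (i in 1:m) {
      if (gap[i] <= -delta) down <- c(down, i) else break
    }
    ncall <- length(up) + length(down)
    cutup <- if (length(up)) min(ds[up]) else Inf
    cutlow <- if (length(down)) max(ds[down]) else -Inf
    counts <- numeric(nrow(dn))
    for (b in seq_len(nrow(dn))) {
      counts[b] <- sum(dn[b, ] >= cutup) + sum(dn[b, ] <= cutlow)
    }
    fdr <- if (ncall == 0) 0 else min(1, pi0 * median(counts) / ncall)
    if (is.null(best) && fdr <= 0.25 && ncall > 0) {
      best <- list(delta = delta, called = sort(ord[c(up, down)]), fdr = fdr)
    }
  }
  expect_equal(res$delta, best$delta)
  expect_identical(res$called, best$called)
  expect_equal(res$fdr, best$fdr)
  expect_equal(res$pi0, pi0)
})

test_that("called sets nest with increasing delta and vanish at extreme thresholds", {
  sim <- generate_expression(synthetic_config(n_genes = 300, seed = 14))
  res <- sam_multiclass(sim$expr, sim$samples$group, B = 200, seed = 14)
  runs <- lapply(c(0.5, 0.2, 0.1, 0.05, 0.01), function(t)
    call_genes_fdr(res$d, res$null, target_fdr = t, sided = "up"))
  runs <- runs[order(vapply(runs, `[[`, numeric(1), "delta"))]
  for (i in seq_len(length(runs) - 1)) {
    expect_true(all(runs[[i + 1]]$called %in% runs[[i]]$called))
  }
  # an unreachable target gives the empty set with delta = Inf
  null_only <- generate_expression(synthetic_config(n_genes = 100, de_fraction = 0,
                                                    seed = 15))
  r0 <- sam_multiclass(null_only$expr, null_only$samples$group, B = 100, seed = 15,
                       target_fdr = 1e-6)
  if (length(r0$called) == 0) expect_identical(r0$delta, Inf)
  expect_true(all(r0$q >= 0 & r0$q <= 1))
})

test_that("pairwise permutation p-values are exact on enumerable designs", {
  g <- two_groups(3, 3)
  # zero observed difference gives p = 1
  flat <- matrix(rep(c(1, 2, 3), 2), 1)
  expect_equal(pairwise_p(flat, g, B = 1000)$p, 1)
  x <- random_matrix(10, 6, seed = 31)
  pp <- pairwise_p(x, g, B = 1000, seed = 1)
  # add-one correction over the 19 non-identity arrangements: multiples of 1/20
  expect_true(all(abs(pp$p * 20 - round(pp$p * 20)) < 1e-12))
  expect_equal(attr(pp, "B_effective"), 19)
  # exhaustive enumeration oracle
  s0 <- attr(pp, "s0")
  obs <- two_class_d(x, g, s0 = s0)
  picks <- combn(6, 3)
  for (gene in 1:10) {
    dn <- numeric(0)
    for (j in seq_len(ncol(picks))) {
      lab <- rep("A", 6); lab[picks[, j]] <- "B"
      if (identical(lab, c("A", "A", "A", "B", "B", "B"))) next
      dn <- c(dn, two_class_d(x[gene, , drop = FALSE],
                              factor(lab, c("A", "B")), s0 = s0))
    }
    expect_equal(pp$p[gene],
                 (1 + sum(abs(dn) >= abs(obs[gene]) * (1 - 1e-9))) / 20)
  }
  # reproducibility in the sampled regime
  y <- random_matrix(20, 24, seed = 5)
  gy <- two_groups(12, 12)
  expect_identical(pairwise_p(y, gy, B = 200, seed = 9)$p,
                   pairwise_p(y, gy, B = 200, seed = 9)$p)
  expect_identical(pp$significant_bonferroni, pp$p < 0.05 / 3)
})

test_that("pairwise p-values are approximately uniform under the null", {
  x <- random_matrix(500, 20, seed = 55)
  pp <- pairwise_p(x, two_groups(10, 10), B = 1000, seed = 55)
  ks <- suppressWarnings(stats::ks.test(pp$p, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("SAM has high power on planted effects at the study's design", {
  sim <- generate_expression(synthetic_config(n_genes = 1000, effect_size = 1,
                                              noise_sd = 0.5, seed = 6))
  res <- sam_multiclass(sim$expr, sim$samples$group, B = 500, seed = 6,
                        target_fdr = 0.05)
  planted <- which(sim$truth$class != "null")
  expect_gte(mean(planted %in% res$called), 0.9)
})

test_that("false-call proportion stays controlled on pure-null data", {
  realized <- vapply(1:20, function(s) {
    sim <- generate_expression(synthetic_config(n_genes = 2000, de_fraction = 0,
                                                seed = s))
    res <- sam_multiclass(sim$expr, sim$samples$group, B = 300, seed = s,
                          target_fdr = 0.05)
    length(res$called) / 2000
  }, numeric(1))
  expect_lte(median(realized), 0.05)
})
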