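# Shared fixture builders for the suite.

# Small labeled matrix with named samples, fixed values under a seed.
random_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, sd = sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

two_groups <- function(n1, n2, levels = c("A", "B")) {
  factor(rep(levels, c(n1, n2)), levels = levels)
}

three_groups <- function(n = c(WM = 36, MGUS = 13, CTRL = 7)) {
  factor(rep(c("WM", "MGUS", "CTRL"), n), levels = c("WM", "MGUS", "CTRL"))
}

# Three pairwise permutation p-value columns for a matrix under the
# WM/MGUS/CTRL design, in the DEG-record schema.
pairwise_record_table <- function(x, groups, B = 1000, seed = 1) {
  cmps <- list(p_WM_MGUS = c("MGUS", "WM"), p_MGUS_CTRL = c("CTRL", "MGUS"),
               p_WM_CTRL = c("CTRL", "WM"))
  out <- data.frame(gene = rownames(x), stringsAsFactors = FALSE)
  for (nm in names(cmps)) {
    keep <- groups %in% cmps[[nm]]
    out[[nm]] <- pairwise_p(x[, keep, drop = FALSE],
                            factor(as.character(groups[keep]),
                                   levels = cmps[[nm]]),
                            B = B, seed = seed)$p
  }
  out
}

# Exhaustive minimum over all spanning trees of a complete graph (n <= 6):
# every subset of n-1 edges that connects all nodes.
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (cols in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    sub <- pairs[cols, , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (rep in seq_len(n)) {
      for (e in seq_len(nrow(sub))) {
        m <- min(comp[sub[e, 1]], comp[sub[e, 2]])
        comp[sub[e, 1]] <- m; comp[sub[e, 2]] <- m
      }
    }
    if (length(unique(comp)) == 1) {
      best <- min(best, sum(d[sub]))
    }
  }
  best
}

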