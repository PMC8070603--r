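#' Build the DEG record table for called genes
#'
#' Assembles the published-table schema for the genes called by a
#' multiclass SAM run: q-value, the three group means, the three signed
#' pairwise fold changes with their permutation p-values, and the pattern
#' label.
#'
#' @param x log2 expression matrix (genes x samples) the SAM run used.
#' @param groups factor (WM, MGUS, CTRL) over the columns.
#' @param sam a \code{"sam_result"} from [sam_multiclass()].
#' @param B,seed permutation settings for the pairwise tests.
#' @param alpha significance level recorded with the pairwise flags.
#' @return data.frame, one row per called gene, sorted by q-value:
#'   gene, pattern, q_value, mean_WM, mean_MGUS, mean_CTRL, fc/p for
#'   WM_MGUS, MGUS_CTRL and WM_CTRL, plus Bonferroni flags.
#' @export
build_deg_table <- function(x, groups, sam, B = 1000, seed = 1, alpha = 0.05) {
  groups <- droplevels(factor(groups, levels = c("WM", "MGUS", "CTRL")))
  idx <- sam$called
  if (length(idx) == 0) {
    return(data.frame(gene = character(0)))
  }
  xs <- x[idx, , drop = FALSE]
  pair <- function(a, b, seed_off) {
    keep <- groups %in% c(a, b)
    g <- factor(groups[keep], levels = c(b, a))   # reference = b, test = a
    pairwise_p(xs[, keep, drop = FALSE], g, B = B, seed = seed + seed_off,
               alpha = alpha)
  }
  wm_mgus <- pair("WM", "MGUS", 1)
  mgus_ctrl <- pair("MGUS", "CTRL", 2)
  wm_ctrl <- pair("WM", "CTRL", 3)
  m <- sam$means[idx, , drop = FALSE]
  out <- data.frame(
    gene = rownames(xs),
    pattern = assign_pattern(m[, "WM"], m[, "MGUS"], m[, "CTRL"]),
    q_value = sam$q[idx],
    mean_WM = m[, "WM"], mean_MGUS = m[, "MGUS"], mean_CTRL = m[, "CTRL"],
    fc_WM_MGUS = signed_fc(m[, "WM"], m[, "MGUS"]), p_WM_MGUS = wm_mgus$p,
    fc_MGUS_CTRL = signed_fc(m[, "MGUS"], m[, "CTRL"]), p_MGUS_CTRL = mgus_ctrl$p,
    fc_WM_CTRL = signed_fc(m[, "WM"], m[, "CTRL"]), p_WM_CTRL = wm_ctrl$p,
    bonf_WM_MGUS = wm_mgus$significant_bonferroni,
    bonf_MGUS_CTRL = mgus_ctrl$significant_bonferroni,
    bonf_WM_CTRL = wm_ctrl$significant_bonferroni,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$q_value), , drop = FALSE]
}

#' Pattern, count and signature stage on an existing DEG table
#'
#' Entry point for result tables that already carry group means and
#' pairwise p-values (e.g. the published tables): (re)assigns patterns
#' from the means, tabulates the p1--p4 counts, and applies the
#' progression-candidate filter.
#'
#' @param records DEG-record data.frame (needs means and the three
#'   pairwise p-value columns).
#' @param alpha significance level for [progression_filter()].
#' @return list: \code{records} (with a recomputed \code{pattern}
#'   column), \code{pattern_counts} (named vector over p1--p4),
#'   \code{signature} (a \code{"signature_set"}).
#' @export
run_pattern_stage <- function(records, alpha = 0.05) {
  records$pattern <- assign_pattern(records$mean_WM, records$mean_MGUS,
                                    records$mean_CTRL)
  counts <- table(factor(records$pattern, levels = c("p1", "p2", "p3", "p4")))
  list(records = records,
       pattern_counts = stats::setNames(as.integer(counts), names(counts)),
       signature = progression_filter(records, alpha = alpha))
}

#' Five-number summaries per gene per group
#'
#' Boxplot-ready statistics (min, lower hinge, median, upper hinge, max)
#' of the expression of each selected gene within each group.
#'
#' @param x log2 expression matrix.
#' @param groups group factor over the columns.
#' @param genes genes to summarize (default all rows).
#' @return data.frame: gene, group, min, q1, median, q3, max.
#' @export
boxplot_stats <- function(x, groups, genes = rownames(x)) {
  groups <- factor(groups)
  out <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(levels(groups), function(lev) {
      fn <- stats::fivenum(x[g, groups == lev])
      data.frame(gene = g, group = lev, min = fn[1], q1 = fn[2],
                 median = fn[3], q3 = fn[4], max = fn[5],
                 stringsAsFactors = FALSE)
    }))
  }))
  row.names(out) <- NULL
  out
}

#' Run the full three-group differential-expression pipeline
#'
#' Orchestrates one cell type end to end: optional quantile normalization
#' and batch adjustment, multiclass SAM at the target FDR, the DEG record
#' table with pairwise permutation p-values, pattern counts, the
#' progression-candidate signature, the sample minimum spanning tree over
#' the signature genes, and boxplot summaries. All randomness derives
#' from \code{seed}; the returned manifest records every setting needed
#' to reproduce the run bit-identically.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param samples sample sheet (data.frame: sample_id, group, optional
#'   cell_type and batch) aligned with \code{colnames(expr)}.
#' @param quantile apply [quantile_normalize()] first.
#' @param combat apply [combat_adjust()] (requires batch labels);
#'   default: only when the sheet carries more than one batch.
#' @param target_fdr SAM false discovery rate target.
#' @param B permutations for SAM and the pairwise tests.
#' @param seed integer seed.
#' @param alpha significance level for the progression filter and
#'   pairwise flags.
#' @param out_dir optional directory; when given, all tables, the MST
#'   edge list and the manifest are written there.
#' @return list of class \code{"wmsig_run"}: \code{sam}, \code{deg_table},
#'   \code{pattern_counts}, \code{signature}, \code{graph} (a
#'   \code{"sample_graph"} or NULL when fewer than one signature gene),
#'   \code{boxplots}, \code{expr} (the matrix analyzed), \code{manifest}.
#' @export
run_pipeline <- function(expr, samples, quantile = TRUE, combat = NULL,
                         target_fdr = 0.05, B = 1000, seed = 1,
                         alpha = 0.05, out_dir = NULL) {
  stopifnot(ncol(expr) == nrow(samples))
  if (!identical(colnames(expr), samples$sample_id)) {
    expr <- expr[, samples$sample_id, drop = FALSE]
  }
  groups <- factor(samples$group, levels = c("WM", "MGUS", "CTRL"))
  if (anyNA(groups)) {
    stop("unknown group label for samples: ",
         paste(samples$sample_id[is.na(groups)], collapse = ", "),
         call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("group with fewer than 2 samples: ",
         paste(names(which(table(groups) < 2)), collapse = ", "),
         call. = FALSE)
  }
  has_batch <- "batch" %in% names(samples) && !anyNA(samples$batch) &&
    length(unique(samples$batch)) > 1
  if (is.null(combat)) combat <- has_batch

  x <- expr
  if (quantile) x <- quantile_normalize(x)
  if (combat) {
    if (!has_batch) stop("combat requested but no usable batch labels", call. = FALSE)
    x <- combat_adjust(x, samples$batch, group = groups)
  }

  sam <- sam_multiclass(x, groups, B = B, seed = seed, target_fdr = target_fdr)
  deg <- build_deg_table(x, groups, sam, B = B, seed = seed, alpha = alpha)
  stage <- if (nrow(deg)) run_pattern_stage(deg, alpha = alpha) else
    list(records = deg,
         pattern_counts = stats::setNames(integer(4), c("p1", "p2", "p3", "p4")),
         signature = progression_filter(
           data.frame(gene = character(0), p_WM_MGUS = numeric(0),
                      p_MGUS_CTRL = numeric(0), p_WM_CTRL = numeric(0)),
           alpha = alpha))
  sig_genes <- stage$signature$genes
  graph <- if (length(sig_genes) >= 1) sample_graph(x, groups, genes = sig_genes)
           else NULL
  box <- if (length(sig_genes)) boxplot_stats(x, groups, sig_genes) else NULL

  manifest <- list(
    package = "wmsig",
    version = as.character(utils::packageVersion("wmsig")),
    n_genes = nrow(expr), n_samples = ncol(expr),
    group_sizes = paste(table(groups), collapse = "/"),
    quantile = quantile, combat = combat,
    target_fdr = target_fdr, B = B, seed = seed, alpha = alpha,
    s0 = sam$s0, delta = sam$delta, pi0 = sam$pi0,
    n_called = length(sam$called), n_signature = length(sig_genes)
  )
  out <- structure(list(sam = sam, deg_table = stage$records,
                        pattern_counts = stage$pattern_counts,
                        signature = stage$signature, graph = graph,
                        boxplots = box, expr = x, manifest = manifest),
                   class = "wmsig_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write a pipeline run to disk
#'
#' Emits the DEG table (2-decimal display + raw companion), the signature
#' audit, the MST edge list, the boxplot summaries and a plain-text
#' key-value manifest under \code{out_dir}.
#'
#' @param run a \code{"wmsig_run"} object.
#' @param out_dir output directory (created if needed).
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (nrow(run$deg_table)) write_deg_table(run$deg_table, p("deg_table.tsv"))
  utils::write.table(run$signature$audit, p("signature_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$graph)) {
    utils::write.table(run$graph$mst_edges, p("mst_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$boxplots)) {
    utils::write.table(run$boxplots, p("boxplot_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(paste(names(run$manifest),
                   vapply(run$manifest, function(v) paste(format(v), collapse = " "),
                          character(1)),
                   sep = "\t"),
             p("manifest.txt"))
  invisible(out_dir)
}

#' @export
print.wmsig_run <- function(x, ...) {
  m <- x$manifest
  cat("wmsig pipeline run\n")
  cat(sprintf("  %d genes x %d samples (WM/MGUS/CTRL = %s)\n",
              m$n_genes, m$n_samples, m$group_sizes))
  cat(sprintf("  SAM: s0 = %.4g, delta = %.4g, pi0 = %.3f, %d genes called at FDR <= %g\n",
              m$s0, m$delta, m$pi0, m$n_called, m$target_fdr))
  cat("  pattern counts:",
      paste(names(x$pattern_counts), x$pattern_counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  progression signature: %d gene(s)\n", m$n_signature))
  if (!is.null(x$graph)) {
    cat("  MST group coherence:",
        paste(names(x$graph$coherence), x$graph$coherence, sep = "=",
              collapse = " "), "\n")
  }
  invisible(x)
}
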