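#' Configuration for the synthetic expression generator
#'
#' Builds and validates the parameter set for [generate_expression()]. The
#' defaults emulate the CD19+ arm of the three-group study design: 36 WM
#' patients, 13 IgM MGUS subjects and 7 healthy controls, log2-scale
#' expression with Gaussian within-group noise, and differentially expressed
#' genes planted in the four fold-change patterns p1--p4 plus a
#' "progression" class whose WM and MGUS means are identical but differ
#' from CTRL.
#'
#' @param n_genes number of genes (rows) to simulate.
#' @param group_sizes named integer vector of samples per group, in the
#'   order \code{c(WM =, MGUS =, CTRL =)}.
#' @param de_fraction fraction of genes that are differentially expressed;
#'   \code{round(de_fraction * n_genes)} genes are non-null.
#' @param pattern_mix non-negative weights over patterns p1--p4 for the
#'   non-progression DE genes; normalized to sum to 1.
#' @param progression_fraction fraction of the DE genes assigned to the
#'   progression class (equal WM and MGUS means, both shifted from CTRL).
#' @param effect_size log2 shift per pattern step (log2 units).
#' @param noise_sd within-group standard deviation (log2 units).
#' @param baseline_range length-2 interval from which baseline log2 means
#'   are drawn uniformly.
#' @param gene_sd_df if non-\code{NULL}, genes get heteroscedastic SDs
#'   \code{noise_sd * sqrt(rchisq(df)/df)} with this many degrees of
#'   freedom; the default \code{NULL} keeps noise homoscedastic.
#' @param batch_assignment optional character/factor vector (one entry per
#'   sample) mapping samples to batches; carried into the sample sheet.
#' @param batch_shift,batch_scale named numeric vectors (one entry per
#'   batch) of additive log2 offsets and multiplicative SD factors applied
#'   by [inject_batch_effects()].
#' @param cell_type label recorded in the sample sheet, \code{"CD19"} or
#'   \code{"CD138"}.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical output.
#'
#' @return An object of class \code{"synthetic_config"} (a validated list).
#' @seealso [generate_expression()], [inject_batch_effects()]
#' @export
synthetic_config <- function(n_genes = 2000,
                             group_sizes = c(WM = 36, MGUS = 13, CTRL = 7),
                             de_fraction = 0.1,
                             pattern_mix = c(p1 = 1, p2 = 1, p3 = 1, p4 = 1),
                             progression_fraction = 0.2,
                             effect_size = 1.0,
                             noise_sd = 0.5,
                             baseline_range = c(3, 10),
                             gene_sd_df = NULL,
                             batch_assignment = NULL,
                             batch_shift = NULL,
                             batch_scale = NULL,
                             cell_type = "CD19",
                             seed = 1L) {
  stop_field <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  }
  stop_field(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1,
             "n_genes", "must be a positive count")
  stop_field(is.numeric(group_sizes) && length(group_sizes) == 3 &&
               all(group_sizes >= 1),
             "group_sizes", "must be three positive counts (WM, MGUS, CTRL)")
  if (is.null(names(group_sizes))) names(group_sizes) <- c("WM", "MGUS", "CTRL")
  stop_field(is.numeric(de_fraction) && de_fraction >= 0 && de_fraction <= 1,
             "de_fraction", "must lie in [0, 1]")
  stop_field(is.numeric(pattern_mix) && length(pattern_mix) == 4 &&
               all(pattern_mix >= 0) && sum(pattern_mix) > 0,
             "pattern_mix", "must be four non-negative weights, not all zero")
  names(pattern_mix) <- c("p1", "p2", "p3", "p4")
  stop_field(progression_fraction >= 0 && progression_fraction <= 1,
             "progression_fraction", "must lie in [0, 1]")
  stop_field(is.numeric(effect_size) && effect_size >= 0,
             "effect_size", "must be non-negative")
  stop_field(is.numeric(noise_sd) && noise_sd >= 0,
             "noise_sd", "must be a non-negative SD")
  stop_field(length(baseline_range) == 2 && diff(baseline_range) >= 0,
             "baseline_range", "must be an increasing interval")
  if (!is.null(batch_assignment)) {
    stop_field(length(batch_assignment) == sum(group_sizes),
               "batch_assignment", "must name a batch for every sample")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    de_fraction = de_fraction,
    pattern_mix = pattern_mix / sum(pattern_mix),
    progression_fraction = progression_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_range = baseline_range, gene_sd_df = gene_sd_df,
    batch_assignment = batch_assignment,
    batch_shift = batch_shift, batch_scale = batch_scale,
    cell_type = cell_type, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic integer apportionment of n among weights (largest remainder).
.apportion <- function(n, weights) {
  if (n == 0) return(rep(0L, length(weights)))
  w <- weights / sum(weights)
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- w * n - base
    extra <- order(frac, seq_along(frac), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic three-group expression matrix with ground truth
#'
#' Simulates a log2 gene-by-sample expression matrix under the WM / IgM
#' MGUS / CTRL design together with the per-gene ground truth needed to
#' score downstream calls. Non-null genes receive group-mean offsets of
#' \code{effect_size} steps according to their class:
#' \describe{
#'   \item{p1}{offsets (+2e, +e, 0) over (WM, MGUS, CTRL): WM > MGUS > CTRL.}
#'   \item{p2}{the mirror (-2e, -e, 0): WM < MGUS < CTRL.}
#'   \item{p3}{(0, -e, 0): WM > MGUS and MGUS < CTRL.}
#'   \item{p4}{(0, +e, 0): WM < MGUS and MGUS > CTRL.}
#'   \item{progression}{(s e, s e, 0) with a shared random sign s: WM and
#'     MGUS identical, both shifted from CTRL.}
#' }
#' Noise is independent Gaussian with SD \code{noise_sd} (optionally
#' gene-specific, see [synthetic_config()]). The global seed is expanded
#' into independent substreams for truth construction and noise so each
#' stage is reproducible on its own.
#'
#' @param config a [synthetic_config()] object.
#' @return A list with elements \code{expr} (numeric matrix, genes x
#'   samples), \code{samples} (data.frame: sample_id, group, cell_type,
#'   batch) and \code{truth} (data.frame: gene, class, mean_WM, mean_MGUS,
#'   mean_CTRL, sd).
#' @examples
#' sim <- generate_expression(synthetic_config(n_genes = 100, seed = 7))
#' dim(sim$expr)
#' table(sim$truth$class)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gs <- config$group_sizes
  n <- config$n_genes
  set.seed(config$seed)
  sub <- sample.int(2^30, 2)

  n_de <- round(config$de_fraction * n)
  n_prog <- round(config$progression_fraction * n_de)
  n_pat <- .apportion(n_de - n_prog, config$pattern_mix)
  classes <- c(rep("progression", n_prog),
               rep(c("p1", "p2", "p3", "p4"), n_pat),
               rep("null", n - n_de))

  set.seed(sub[1])
  baseline <- stats::runif(n, config$baseline_range[1], config$baseline_range[2])
  prog_sign <- sample(c(-1, 1), n, replace = TRUE)
  e <- config$effect_size
  off <- matrix(0, n, 3, dimnames = list(NULL, c("WM", "MGUS", "CTRL")))
  off[classes == "p1", ] <- rep(c(2 * e, e, 0), each = sum(classes == "p1"))
  off[classes == "p2", ] <- rep(c(-2 * e, -e, 0), each = sum(classes == "p2"))
  off[classes == "p3", ] <- rep(c(0, -e, 0), each = sum(classes == "p3"))
  off[classes == "p4", ] <- rep(c(0, e, 0), each = sum(classes == "p4"))
  is_prog <- classes == "progression"
  off[is_prog, c("WM", "MGUS")] <- prog_sign[is_prog] * e
  true_means <- baseline + off

  sds <- if (is.null(config$gene_sd_df)) {
    rep(config$noise_sd, n)
  } else {
    config$noise_sd * sqrt(stats::rchisq(n, config$gene_sd_df) / config$gene_sd_df)
  }

  group <- factor(rep(c("WM", "MGUS", "CTRL"), gs),
                  levels = c("WM", "MGUS", "CTRL"))
  sample_id <- paste0(rep(c("WM", "MGUS", "CTRL"), gs), "_",
                      unlist(lapply(gs, seq_len)))
  set.seed(sub[2])
  mu <- true_means[, as.character(group), drop = FALSE]
  expr <- mu + matrix(stats::rnorm(n * length(group)), n) * sds
  gene <- sprintf("gene_%0*d", nchar(n), seq_len(n))
  dimnames(expr) <- list(gene, sample_id)

  samples <- data.frame(
    sample_id = sample_id, group = group,
    cell_type = config$cell_type,
    batch = if (is.null(config$batch_assignment)) NA_character_
            else as.character(config$batch_assignment),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene = gene, class = classes,
    mean_WM = true_means[, "WM"], mean_MGUS = true_means[, "MGUS"],
    mean_CTRL = true_means[, "CTRL"], sd = sds,
    stringsAsFactors = FALSE
  )
  list(expr = expr, samples = samples, truth = truth)
}

#' Add batch effects to an expression matrix
#'
#' Applies a location-scale perturbation per batch: each value is scaled
#' around its gene mean by the batch's scale factor and shifted by the
#' batch's additive log2 offset. This is the structure an empirical-Bayes
#' batch adjustment such as [combat_adjust()] is expected to remove.
#'
#' @param x numeric matrix, genes x samples.
#' @param batch character/factor vector, one batch label per column of
#'   \code{x}.
#' @param shift named numeric vector of additive offsets, one per batch.
#' @param scale named numeric vector of multiplicative SD factors, one per
#'   batch (default 1 for batches not named).
#' @return The perturbed matrix, same dimensions and dimnames.
#' @export
inject_batch_effects <- function(x, batch, shift, scale = NULL) {
  if (length(batch) != ncol(x)) {
    stop("every sample needs a batch label; missing for samples: ",
         paste(colnames(x)[seq_len(ncol(x)) > length(batch)], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(batch)) {
    stop("samples without batch assignment: ",
         paste(colnames(x)[is.na(batch)], collapse = ", "), call. = FALSE)
  }
  batch <- as.character(batch)
  levels <- unique(batch)
  getpar <- function(v, default) {
    out <- rep(default, length(levels))
    names(out) <- levels
    if (!is.null(v)) out[names(v)] <- v
    out
  }
  sh <- getpar(shift, 0)
  sc <- getpar(scale, 1)
  gmean <- rowMeans(x)
  out <- x
  for (b in levels) {
    j <- batch == b
    out[, j] <- if (sc[b] == 1) x[, j, drop = FALSE] + sh[b]
                else gmean + (x[, j, drop = FALSE] - gmean) * sc[b] + sh[b]
  }
  out
}
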