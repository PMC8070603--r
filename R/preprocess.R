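#' Log2-transform a linear-scale expression matrix
#'
#' @param x numeric matrix of non-negative linear-scale intensities.
#' @param offset non-negative pseudo-count added before taking logs
#'   (default 1, so zero intensities map to zero).
#' @return matrix of \code{log2(x + offset)} values.
#' @export
log2_transform <- function(x, offset = 1) {
  stopifnot(is.numeric(offset), offset >= 0)
  if (any(x < 0, na.rm = TRUE)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative intensity at row %s, column %s",
                 idx[1], idx[2]), call. = FALSE)
  }
  log2(x + offset)
}

#' Quantile-normalize expression columns
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the row-wise mean of the
#' per-column sorted vectors, preserving within-column ranks. Ties are
#' averaged. This is the between-array normalization step of RMA applied
#' to an already-summarized matrix; delegation is to
#' \code{limma::normalizeQuantiles}.
#'
#' @param x numeric matrix, genes x samples, at least 2 columns.
#' @return normalized matrix with the dimnames of \code{x}.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Removes batch-specific location and scale effects with parametric
#' empirical-Bayes shrinkage across genes (ComBat), keeping the biological
#' group as a protected covariate so group differences are not absorbed
#' into the batch estimates. Delegates to \code{sva::ComBat}.
#'
#' @param x numeric matrix, genes x samples.
#' @param batch batch label per column; a single batch returns \code{x}
#'   unchanged (nothing to remove).
#' @param group optional biological group per column, retained as a model
#'   covariate.
#' @return adjusted matrix, same dimensions as \code{x}.
#' @export
combat_adjust <- function(x, batch, group = NULL) {
  stopifnot(length(batch) == ncol(x))
  batch <- factor(batch)
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("batch with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (nlevels(batch) < 2) return(x)
  mod <- if (is.null(group)) NULL else stats::model.matrix(~ factor(group))
  out <- suppressMessages(sva::ComBat(dat = x, batch = batch, mod = mod))
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse probe-sets to unique genes
#'
#' Groups annotated probe-sets by gene symbol and keeps one representative
#' probe per gene; unannotated probes are counted and excluded from the
#' gene-level matrix. The default rule keeps the probe with the highest
#' mean expression, the field's usual choice when no probe quality metric
#' is available.
#'
#' @param x numeric matrix, probes x samples, rownames = probe ids.
#' @param annotation named character vector mapping every probe id to a
#'   gene symbol, with \code{NA} or \code{""} marking unannotated probes.
#' @param rule \code{"max_mean"} (default), \code{"median"} (per-gene
#'   column-wise median over its probes) or \code{"none"} (keep all
#'   annotated probes, renamed but possibly duplicated symbols).
#' @return list with \code{expr} (gene-level matrix) and \code{counts}
#'   (named vector: probes, unique_genes, unannotated).
#' @export
collapse_probes <- function(x, annotation, rule = c("max_mean", "median", "none")) {
  rule <- match.arg(rule)
  if (length(annotation) == 0) stop("empty probe annotation", call. = FALSE)
  missing <- setdiff(rownames(x), names(annotation))
  if (length(missing)) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sym <- annotation[rownames(x)]
  unann <- is.na(sym) | sym == "" | sym == "unannotated"
  ann <- x[!unann, , drop = FALSE]
  sym <- sym[!unann]
  counts <- c(probes = nrow(x),
              unique_genes = length(unique(sym)),
              unannotated = sum(unann))
  expr <- switch(rule,
    none = {
      out <- ann
      rownames(out) <- unname(sym)
      out
    },
    max_mean = {
      keep <- vapply(split(seq_along(sym), sym), function(idx) {
        idx[which.max(rowMeans(ann[idx, , drop = FALSE]))]
      }, integer(1))
      out <- ann[keep, , drop = FALSE]
      rownames(out) <- names(keep)
      out
    },
    median = {
      out <- t(vapply(split(seq_along(sym), sym), function(idx) {
        apply(ann[idx, , drop = FALSE], 2, stats::median)
      }, numeric(ncol(ann))))
      colnames(out) <- colnames(ann)
      out
    }
  )
  list(expr = expr, counts = counts)
}
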