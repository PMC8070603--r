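#' Signed linear fold change between two log2 means
#'
#' With \eqn{\Delta = a - b}: returns \eqn{2^\Delta} when \eqn{\Delta > 0},
#' \eqn{-2^{-\Delta}} when \eqn{\Delta < 0}, and 1 when \eqn{\Delta = 0}
#' (the usual "-1/ratio for down-regulation" reporting convention, so
#' \eqn{|fc| \ge 1} always and -2 means halved expression).
#'
#' @param mean_a,mean_b log2 group means (vectorized).
#' @return signed linear fold change(s).
#' @examples
#' signed_fc(7.25, 8.79)   # -2.91: ~2.9-fold lower in the first group
#' @export
signed_fc <- function(mean_a, mean_b) {
  delta <- mean_a - mean_b
  ifelse(delta > 0, 2^delta, ifelse(delta < 0, -2^(-delta), 1))
}

.step_pattern <- function(s1, s2) {
  # s1 = sign(WM - MGUS), s2 = sign(MGUS - CTRL); a zero step inherits the
  # other step's sign so near-flat steps do not orphan a gene.
  out <- character(length(s1))
  flat <- s1 == 0 & s2 == 0
  s1[s1 == 0] <- s2[s1 == 0]
  s2[s2 == 0] <- s1[s2 == 0]
  out[s1 > 0 & s2 > 0] <- "p1"
  out[s1 < 0 & s2 < 0] <- "p2"
  out[s1 > 0 & s2 < 0] <- "p3"
  out[s1 < 0 & s2 > 0] <- "p4"
  out[flat] <- "flat"
  out
}

#' Assign the four-way differential-expression pattern
#'
#' Labels a gene by the signs of its two step-wise mean differences
#' (WM - MGUS, MGUS - CTRL): (+,+) is p1 (WM > MGUS > CTRL), (-,-) is p2
#' (WM < MGUS < CTRL), (+,-) is p3 and (-,+) is p4. An exact zero step
#' inherits the sign of the other step; a gene with both steps zero is
#' labeled \code{"flat"} and excluded from the patterns.
#'
#' @param mean_wm,mean_mgus,mean_ctrl log2 group means (vectorized).
#' @return character vector of labels in \{p1, p2, p3, p4, flat\}.
#' @examples
#' assign_pattern(6.49, 7.72, 8.83)  # p2
#' assign_pattern(8.36, 6.01, 5.12)  # p1
#' @export
assign_pattern <- function(mean_wm, mean_mgus, mean_ctrl) {
  .step_pattern(sign(mean_wm - mean_mgus), sign(mean_mgus - mean_ctrl))
}

#' Assign the pattern from printed signed fold changes
#'
#' Same taxonomy as [assign_pattern()] but driven by the two step-wise
#' signed fold changes: a fold change of magnitude exactly 1 is a zero
#' step (printed tables report a zero log2 step as 1 or -1), otherwise the
#' step sign is the fold change's sign.
#'
#' @param fc_wm_mgus,fc_mgus_ctrl signed fold changes for the two steps.
#' @return character vector of labels in \{p1, p2, p3, p4, flat\}.
#' @export
pattern_from_fc <- function(fc_wm_mgus, fc_mgus_ctrl) {
  stepsign <- function(fc) ifelse(abs(fc) == 1, 0, sign(fc))
  .step_pattern(stepsign(fc_wm_mgus), stepsign(fc_mgus_ctrl))
}

#' Progression-candidate gene filter
#'
#' Selects genes whose WM and MGUS expression is statistically
#' indistinguishable while both differ from healthy controls — the
#' candidate markers for the risk of progression from IgM MGUS to WM.
#' A gene passes when all three clauses hold:
#' \enumerate{
#'   \item \code{p_WM_MGUS >= alpha} (no WM-vs-MGUS difference),
#'   \item \code{p_MGUS_CTRL < alpha},
#'   \item \code{p_WM_CTRL < alpha}.
#' }
#'
#' @param records data.frame with columns \code{gene}, \code{p_WM_MGUS},
#'   \code{p_MGUS_CTRL}, \code{p_WM_CTRL} (additional columns are carried
#'   through).
#' @param alpha significance level for the clauses (default 0.05,
#'   unadjusted; pair it with the Bonferroni flags from [pairwise_p()] if
#'   a corrected gate is wanted).
#' @return list of class \code{"signature_set"}: \code{genes} (selected
#'   symbols), \code{audit} (per-gene clause outcomes for every input
#'   record), \code{alpha}.
#' @export
progression_filter <- function(records, alpha = 0.05) {
  need <- c("gene", "p_WM_MGUS", "p_MGUS_CTRL", "p_WM_CTRL")
  stopifnot(all(need %in% names(records)))
  pm <- records[, c("p_WM_MGUS", "p_MGUS_CTRL", "p_WM_CTRL")]
  incomplete <- !stats::complete.cases(pm)
  if (any(incomplete)) {
    warning("skipping records with missing p-values: ",
            paste(records$gene[incomplete], collapse = ", "))
  }
  audit <- data.frame(
    gene = records$gene,
    wm_mgus_similar = records$p_WM_MGUS >= alpha,
    mgus_ctrl_different = records$p_MGUS_CTRL < alpha,
    wm_ctrl_different = records$p_WM_CTRL < alpha,
    stringsAsFactors = FALSE
  )
  audit$selected <- !incomplete & audit$wm_mgus_similar &
    audit$mgus_ctrl_different & audit$wm_ctrl_different
  structure(list(genes = records$gene[audit$selected],
                 audit = audit, alpha = alpha),
            class = "signature_set")
}

#' Genes differentially expressed in both cell types
#'
#' Inner join of two cell types' result tables on gene symbol, carrying
#' both pattern labels and both fold-change triplets, sorted by
#' (first pattern, second pattern, minimum absolute fold change across the
#' six comparisons).
#'
#' @param a,b data.frames with columns \code{gene}, \code{pattern},
#'   \code{fc_WM_MGUS}, \code{fc_MGUS_CTRL}, \code{fc_WM_CTRL}.
#' @param suffixes column suffixes for the two inputs.
#' @return joined data.frame, empty when the gene sets are disjoint.
#' @export
cross_celltype_common <- function(a, b, suffixes = c("_cd19", "_cd138")) {
  need <- c("gene", "pattern", "fc_WM_MGUS", "fc_MGUS_CTRL", "fc_WM_CTRL")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  out <- merge(a[, need], b[, need], by = "gene", suffixes = suffixes)
  if (nrow(out) == 0) return(out)
  fc_cols <- grep("^fc_", names(out), value = TRUE)
  min_fc <- apply(abs(out[, fc_cols]), 1, min)
  p1 <- out[[paste0("pattern", suffixes[1])]]
  p2 <- out[[paste0("pattern", suffixes[2])]]
  out[order(p1, p2, min_fc), , drop = FALSE]
}
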