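#' Published differential-expression tables (GEO series GSE171739)
#'
#' Loads the curated result tables of the WM / IgM MGUS / CTRL
#' transcriptome study as data.frames: the CD19+ zinc-finger genes
#' (\code{cd19_znf}), the CD19+ pattern-2 high-fold-change genes
#' (\code{cd19_p2_highfc}), the nine CD19+ progression-candidate genes
#' (\code{cd19_progression}), the 29 CD138+ probe-set rows (\code{cd138};
#' TTLL7 appears twice, as two probe-sets mapped to it), and the
#' cross-cell-type common genes (\code{common}). Values are as printed:
#' group means and q-values to 2--4 decimals, fold changes to at most 2
#' decimals. The two known printing quirks are preserved: PPARGC1A's
#' zero MGUS-vs-CTRL step is printed as -1, and GBA3's CD138+ fold
#' changes differ slightly between the \code{cd138} and \code{common}
#' tables.
#'
#' @return named list of data.frames.
#' @examples
#' tabs <- published_deg_tables()
#' nrow(tabs$cd138)   # 29
#' @export
published_deg_tables <- function() {
  load1 <- function(f) {
    utils::read.delim(system.file("extdata", f, package = "wmsig"),
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  list(
    cd19_znf = load1("deg_cd19_znf.tsv"),
    cd19_p2_highfc = load1("deg_cd19_p2_highfc.tsv"),
    cd19_progression = load1("deg_cd19_progression.tsv"),
    cd138 = load1("deg_cd138.tsv"),
    common = load1("deg_common.tsv")
  )
}

#' Unique CD19+ gene records from the published tables
#'
#' Union of the three CD19+ tables keyed by gene symbol (genes occurring
#' in more than one table are kept once, first occurrence wins; the
#' printed q-values differ only in rounding).
#'
#' @return data.frame in the DEG-record schema.
#' @export
published_cd19_records <- function() {
  tabs <- published_deg_tables()
  all <- rbind(tabs$cd19_znf, tabs$cd19_p2_highfc, tabs$cd19_progression)
  all[!duplicated(all$gene), , drop = FALSE]
}
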