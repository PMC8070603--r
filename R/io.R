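# File formats: tab-separated expression matrices (genes in rows, first
# column the identifier), comma-separated sample sheets, UTF-8, '.' decimal.

#' Read a gene-by-sample expression matrix from TSV
#'
#' @param path TSV file: header row of sample ids, one row per gene with
#'   the identifier in the first column.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("expression file has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(lengths(fields) != width)
  if (length(bad)) {
    stop("ragged rows (field count != header) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids)) + 1
    stop("duplicate row identifiers at line(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  samples <- fields[[1]][-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in header", call. = FALSE)
  vals <- matrix(NA_real_, length(ids), length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(ids)) {
    row <- suppressWarnings(as.numeric(fields[[i + 1]][-1]))
    if (anyNA(row)) {
      stop(sprintf("non-numeric value at line %d", i + 1), call. = FALSE)
    }
    vals[i, ] <- row
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' Full precision (\code{format} with 15 significant digits), so
#' \code{read_expression(write_expression(x))} round-trips bit-identically.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file.
#' @param id_col name of the identifier column header.
#' @export
write_expression <- function(x, path, id_col = "gene") {
  header <- paste(c(id_col, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with columns \code{sample_id}, \code{group} (WM / MGUS / CTRL),
#' \code{cell_type} (CD19 / CD138) and optional \code{batch}.
#'
#' @param path CSV file.
#' @return data.frame with \code{group} as a factor leveled
#'   (WM, MGUS, CTRL).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$group), c("WM", "MGUS", "CTRL"))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " for samples ",
         paste(df$sample_id[df$group %in% unknown], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  df$group <- factor(df$group, levels = c("WM", "MGUS", "CTRL"))
  df
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a DEG result table
#'
#' Writes two files: \code{path} with fold changes and means rounded to 2
#' decimals (the published table style) and, alongside it, a
#' \code{*_raw.tsv} companion at full precision.
#'
#' @param records DEG-record data.frame.
#' @param path output TSV path.
#' @export
write_deg_table <- function(records, path) {
  raw_path <- sub("(\\.tsv)?$", "_raw.tsv", path)
  utils::write.table(records, raw_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  disp <- records
  num <- vapply(disp, is.numeric, logical(1)) &
    grepl("^(fc_|mean_)", names(disp))
  disp[num] <- lapply(disp[num], round, digits = 2)
  utils::write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
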