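#' Barcode-by-sample read count matrix
#'
#' Non-negative integer read counts with one row per library barcode and
#' one column per sequenced sample, plus the sample sheet as column
#' metadata and the tally of reads that could not be assigned.
#'
#' @param counts Integer matrix with rownames = barcode IDs and colnames =
#'   sample IDs.
#' @param samples A [sample_sheet()] covering every column, in order.
#' @param unassigned Number of unassigned reads (default 0).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, unassigned = 0) {
  stopifnot(is.matrix(counts), inherits(samples, "sample_sheet"))
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have barcode rownames and sample colnames")
  if (!identical(colnames(counts), samples$sample_id) &&
      !(ncol(counts) == 0 && nrow(samples) == 0))
    stop("count matrix columns must match the sample sheet, in order")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, samples = samples,
                 unassigned = as.numeric(unassigned)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " barcodes x ", ncol(x$counts),
      " samples, ", sum(x$counts), " assigned reads, ", x$unassigned,
      " unassigned\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' The TSV has a `barcode_id` column followed by one column per sample.
#' Sample metadata travels separately as a sample-sheet CSV.
#'
#' @param m A `count_matrix`.
#' @param path TSV path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(barcode_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param sheet The sample sheet for the matrix's columns.
#' @export
read_count_matrix <- function(path, sheet) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$barcode_id
  storage.mode(counts) <- "integer"
  count_matrix(counts, sheet)
}

# subset a count matrix's columns, keeping metadata aligned
subset_samples <- function(m, keep) {
  counts <- m$counts[, keep, drop = FALSE]
  samples <- m$samples[m$samples$sample_id %in% colnames(counts), ,
                       drop = FALSE]
  rownames(samples) <- NULL
  count_matrix(counts, structure(samples,
                                 class = c("sample_sheet", "data.frame")),
               unassigned = m$unassigned)
}
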