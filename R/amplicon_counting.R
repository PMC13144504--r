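#' Barcode library
#'
#' The lentiviral tag pool: a table mapping barcode IDs to their DNA
#' sequences. All sequences must be the same length, unique, shorter than
#' 100 nt, and over the {A,C,G,T} alphabet.
#'
#' @param id Character vector of barcode IDs.
#' @param sequence Character vector of barcode sequences.
#' @return A `barcode_library` data frame with attribute `barcode_length`.
#' @export
barcode_library <- function(id, sequence) {
  id <- as.character(id); sequence <- toupper(as.character(sequence))
  stopifnot(length(id) == length(sequence), length(id) >= 1)
  if (anyDuplicated(sequence)) stop("barcode sequences must be unique")
  if (anyDuplicated(id)) stop("barcode IDs must be unique")
  L <- unique(nchar(sequence))
  if (length(L) != 1) stop("all barcode sequences must share one length")
  if (L >= 100) stop("barcodes must be shorter than 100 nt")
  if (any(grepl("[^ACGT]", sequence)))
    stop("barcode sequences must contain only A, C, G, T")
  structure(data.frame(id = id, sequence = sequence,
                       stringsAsFactors = FALSE),
            barcode_length = L, class = c("barcode_library", "data.frame"))
}

#' Read / write a barcode library as TSV (columns id, sequence)
#' @param path File path.
#' @export
read_barcode_library <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  barcode_library(df$id, df$sequence)
}

#' @rdname read_barcode_library
#' @param lib A `barcode_library`.
#' @export
write_barcode_library <- function(lib, path) {
  write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Sample sheet
#'
#' One row per sequenced sample: its demultiplexing index sequence, the
#' replicate group it belongs to (PCR duplicates for tissue,
#' quintuplicates for cfDNA and lung), its class, and where in the tumor
#' it came from.
#'
#' @param sample_id,index,replicate_group Character vectors.
#' @param sample_class One of tumor_piece, needle, cfDNA, lung, CTC per
#'   sample.
#' @param tissue_location center / periphery / NA per sample.
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, index, replicate_group,
                         sample_class = "tumor_piece",
                         tissue_location = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   index = toupper(as.character(index)),
                   replicate_group = as.character(replicate_group),
                   sample_class = as.character(sample_class),
                   tissue_location = as.character(tissue_location),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("sample IDs must be unique")
  if (anyDuplicated(df$index))
    stop("duplicate index sequences in sample sheet")
  ok_class <- c("tumor_piece", "needle", "cfDNA", "lung", "CTC")
  if (!all(df$sample_class %in% ok_class))
    stop("sample_class must be one of: ", paste(ok_class, collapse = ", "))
  mixed <- tapply(df$sample_class, df$replicate_group,
                  function(x) length(unique(x)) > 1)
  if (any(mixed))
    stop("samples in a replicate group must share one sample_class")
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' @rdname sample_sheet
#' @param path CSV path with the sheet's columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$index, df$replicate_group,
               df$sample_class, df$tissue_location)
}

#' @rdname sample_sheet
#' @param sheet A `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(as.data.frame(sheet), path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Amplicon read layout
#'
#' Positional structure of each read:
#' `[sample index][anchor][barcode][filler]`, padded to `read_length`.
#' The anchor is the fixed context between index and barcode (e.g. the
#' common forward-primer tail); it is located positionally and not
#' error-checked, matching pipelines that extract by position.
#'
#' @param index_length Index width in nt.
#' @param anchor Fixed sequence between index and barcode ("" for none).
#' @param read_length Total read length after padding.
#' @return A `read_layout` object.
#' @export
read_layout <- function(index_length = 8, anchor = "ACCTGA",
                        read_length = 75) {
  stopifnot(index_length >= 1, read_length >= index_length + nchar(anchor) + 1)
  structure(list(index_length = as.integer(index_length),
                 anchor = toupper(anchor),
                 read_length = as.integer(read_length)),
            class = "read_layout")
}

# Hamming distances from one string to a pre-split character matrix
.hamming_to_all <- function(chars, mat) {
  colSums(mat != chars)
}

# resolve one query against candidates allowing `budget` mismatches;
# equal-distance ties are ambiguous -> NA
.resolve <- function(query, mat, budget) {
  d <- .hamming_to_all(strsplit(query, "")[[1]], mat)
  m <- min(d)
  if (m > budget || sum(d == m) > 1L) NA_integer_ else which.min(d)
}

#' Demultiplex barcode amplicon reads and count library matches
#'
#' Assigns each read to a (sample, barcode) cell of the count matrix iff
#' its index region matches exactly one sample-sheet index within
#' `max_mismatch_index` and its barcode region matches exactly one library
#' entry within `max_mismatch_barcode`. Equal-distance ties are treated as
#' ambiguous and left unassigned — never split or arbitrarily assigned.
#' Base qualities are ignored. Every read is accounted for:
#' `sum(counts) + unassigned == number of reads`.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param lib A [barcode_library()].
#' @param sheet A [sample_sheet()].
#' @param max_mismatch_index,max_mismatch_barcode Hamming-distance budgets
#'   (>= 0).
#' @param layout A [read_layout()] describing where index and barcode sit
#'   in the read.
#' @return A `count_matrix` (barcodes x samples) with the sheet as column
#'   metadata and an `unassigned` tally.
#' @export
demultiplex_and_count <- function(fastq, lib, sheet,
                                  max_mismatch_index = 0,
                                  max_mismatch_barcode = 0,
                                  layout = read_layout()) {
  stopifnot(inherits(lib, "barcode_library"), inherits(sheet, "sample_sheet"),
            max_mismatch_index >= 0, max_mismatch_barcode >= 0,
            inherits(layout, "read_layout"))
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e)
      stop("malformed FASTQ '", fastq, "': ", conditionMessage(e)))
  n <- length(reads)
  iL <- layout$index_length
  aL <- nchar(layout$anchor)
  bL <- attr(lib, "barcode_length")
  if (n && min(nchar(reads)) < iL + aL + bL)
    stop("reads shorter than the layout's index+anchor+barcode span")
  idx_seq <- substr(reads, 1L, iL)
  bc_seq <- substr(reads, iL + aL + 1L, iL + aL + bL)

  s_hit <- match(idx_seq, sheet$index)
  b_hit <- match(bc_seq, lib$sequence)

  if (max_mismatch_index > 0 && anyNA(s_hit)) {
    smat <- vapply(strsplit(sheet$index, ""), identity,
                   character(iL))
    todo <- which(is.na(s_hit))
    s_hit[todo] <- vapply(idx_seq[todo], .resolve, integer(1),
                          mat = smat, budget = max_mismatch_index)
  }
  if (max_mismatch_barcode > 0 && anyNA(b_hit)) {
    bmat <- vapply(strsplit(lib$sequence, ""), identity, character(bL))
    todo <- which(is.na(b_hit))
    b_hit[todo] <- vapply(bc_seq[todo], .resolve, integer(1),
                          mat = bmat, budget = max_mismatch_barcode)
  }

  ok <- !is.na(s_hit) & !is.na(b_hit)
  counts <- matrix(0L, nrow = nrow(lib), ncol = nrow(sheet),
                   dimnames = list(lib$id, sheet$sample_id))
  if (any(ok)) {
    cell <- (s_hit[ok] - 1L) * nrow(lib) + b_hit[ok]
    tab <- tabulate(cell, nbins = nrow(lib) * nrow(sheet))
    counts[] <- tab
  }
  count_matrix(counts, sheet, unassigned = sum(!ok))
}
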