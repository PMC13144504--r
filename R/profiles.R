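#' Clone frequency profile of one specimen
#'
#' A `clone_profile` records, for one specimen (tumor piece, needle core,
#' plasma draw, pooled replicate group...), the barcodes observed and their
#' relative frequencies. Zero-count barcodes are dropped, so every listed
#' frequency is positive and frequencies sum to 1 (empty profiles, e.g. a
#' needle that missed the tumor, are allowed and have no entries).
#'
#' @param counts Named non-negative numeric vector of per-barcode counts
#'   (read counts, cell counts, or fragment counts). Names are barcode IDs.
#' @param label Specimen label.
#' @param sample_class Optional class tag (`"tumor_piece"`, `"needle"`,
#'   `"cfDNA"`, `"lung"`, `"CTC"`).
#' @param tissue_location Optional `"center"` / `"periphery"` tag.
#' @return An object of class `clone_profile` with elements `label`,
#'   `count` (positive entries only) and `freq`.
#' @export
clone_profile <- function(counts, label = "specimen", sample_class = NA_character_,
                          tissue_location = NA_character_) {
  if (length(counts) && is.null(names(counts)))
    stop("`counts` must be named by barcode ID")
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  tot <- sum(counts)
  freq <- if (tot > 0) counts / tot else counts
  structure(list(label = label,
                 count = counts,
                 freq = freq,
                 total = tot,
                 sample_class = sample_class,
                 tissue_location = tissue_location),
            class = "clone_profile")
}

#' Barcodes present in a profile
#' @param p A `clone_profile`.
#' @return Character vector of barcode IDs with positive frequency.
#' @export
profile_barcodes <- function(p) {
  stopifnot(inherits(p, "clone_profile"))
  names(p$freq)
}

#' Number of distinct clones in a profile
#' @param p A `clone_profile`.
#' @export
clone_richness <- function(p) length(profile_barcodes(p))

#' Is a profile empty?
#' @param p A `clone_profile`.
#' @export
is_empty_profile <- function(p) length(p$freq) == 0L

#' Build a profile from a clone census
#' @param census A `clone_census` (named cell counts).
#' @param label Specimen label.
#' @param ... Passed to [clone_profile()].
#' @export
profile_from_census <- function(census, label = "tumor", ...) {
  clone_profile(stats::setNames(as.numeric(census), names(census)),
                label = label, ...)
}

#' @export
print.clone_profile <- function(x, ...) {
  cat("<clone_profile> '", x$label, "': ", length(x$freq), " barcodes",
      if (!is.na(x$sample_class)) paste0(", class ", x$sample_class),
      "\n", sep = "")
  if (length(x$freq)) {
    top <- sort(x$freq, decreasing = TRUE)
    top <- top[seq_len(min(5, length(top)))]
    cat("  top frequencies: ",
        paste0(names(top), "=", signif(top, 3), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write one or more profiles as a tidy TSV
#'
#' Columns: specimen, barcode_id, count, frequency.
#'
#' @param profiles A `clone_profile` or list of them.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "clone_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    if (length(p$freq))
      data.frame(specimen = p$label, barcode_id = names(p$freq),
                 count = as.numeric(p$count), frequency = as.numeric(p$freq))
    else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(specimen = character(), barcode_id = character(),
                     count = numeric(), frequency = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
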