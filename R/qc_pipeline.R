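#' Quality-control thresholds for barcode count matrices
#'
#' The four-step filter chain applied to a raw count matrix, in this fixed
#' order: (1) within each sample, read counts less than or equal to
#' `low_count_zero_threshold` are set to zero; (2) samples with fewer than
#' `min_sample_reads` total reads are excluded; (3) within each replicate
#' group, replicates whose Pearson correlation with the others falls below
#' `min_replicate_pearson` are removed — except for classes listed in
#' `corr_exempt_classes` (cfDNA by default, whose low-input replicates are
#' expected to be discordant); (4) barcodes present in fewer than
#' `min_replicates_detected` replicates of a group are discarded from that
#' group.
#'
#' @param low_count_zero_threshold Counts <= this become 0 (default 10).
#' @param min_sample_reads Minimum column total to keep a sample
#'   (default 10000).
#' @param min_replicate_pearson Replicate concordance threshold; the rule
#'   is strict (removed only when r is strictly below it). Default 0.6.
#' @param corr_exempt_classes Sample classes exempt from the concordance
#'   filter (default `"cfDNA"`).
#' @param min_replicates_detected Replicates a barcode must be present in
#'   (count > 0 after zeroing) to be kept within a group (default 2;
#'   capped at the group size so single-replicate groups are not emptied).
#' @param correlation_scale `"raw"` (default) or `"log1p"` counts for the
#'   concordance correlation.
#' @return A `filter_config` object.
#' @export
filter_config <- function(low_count_zero_threshold = 10,
                          min_sample_reads = 10000,
                          min_replicate_pearson = 0.6,
                          corr_exempt_classes = "cfDNA",
                          min_replicates_detected = 2,
                          correlation_scale = c("raw", "log1p")) {
  stopifnot(low_count_zero_threshold >= 0, min_sample_reads >= 0,
            min_replicate_pearson >= 0, min_replicate_pearson <= 1,
            min_replicates_detected >= 0)
  structure(list(low_count_zero_threshold = low_count_zero_threshold,
                 min_sample_reads = min_sample_reads,
                 min_replicate_pearson = min_replicate_pearson,
                 corr_exempt_classes = corr_exempt_classes,
                 min_replicates_detected = min_replicates_detected,
                 correlation_scale = match.arg(correlation_scale)),
            class = "filter_config")
}

new_filter_report <- function() {
  structure(list(steps = list()), class = "filter_report")
}

add_step <- function(report, name, ...) {
  report$steps[[name]] <- list(...)
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    flat <- vapply(s, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  ", nm, ": ", paste(names(flat), flat, sep = "=", collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Zero out low counts
#'
#' Sets every count less than or equal to the threshold to zero within
#' each sample; all other counts are untouched. Idempotent.
#'
#' @param m A `count_matrix`.
#' @param cfg A [filter_config()].
#' @return The filtered `count_matrix`.
#' @export
zero_low_counts <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "count_matrix"))
  m$counts[m$counts <= cfg$low_count_zero_threshold] <- 0L
  m
}

#' Drop samples with too few total reads
#'
#' Removes samples whose column total (after low-count zeroing) is
#' strictly below `min_sample_reads`.
#'
#' @inheritParams zero_low_counts
#' @return `list(counts = count_matrix, report = filter_report)`.
#' @export
drop_low_depth_samples <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- colSums(m$counts)
  keep <- tot >= cfg$min_sample_reads
  report <- add_step(new_filter_report(), "low_depth",
                     samples_dropped = colnames(m$counts)[!keep],
                     reads_dropped = sum(tot[!keep]))
  list(counts = subset_samples(m, keep), report = report)
}

# mean pairwise Pearson r of each replicate column against the others,
# computed over barcodes nonzero in at least one member of each pair
replicate_concordance <- function(cols, scale = "raw") {
  k <- ncol(cols)
  if (scale == "log1p") cols <- log1p(cols)
  r_mat <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      use <- cols[, i] > 0 | cols[, j] > 0
      r <- if (sum(use) >= 2) suppressWarnings(cor(cols[use, i], cols[use, j]))
           else NA_real_
      r_mat[i, j] <- r_mat[j, i] <- r
    }
  }
  rowMeans(r_mat, na.rm = TRUE)
}

#' Remove discordant replicates
#'
#' Within each non-exempt replicate group, computes each replicate's mean
#' pairwise Pearson correlation with the group's other replicates and
#' removes replicates whose correlation is strictly below
#' `min_replicate_pearson` (a pair at exactly the threshold is kept).
#' Correlations are computed over the barcodes nonzero in at least one
#' member of each pair. Groups in `corr_exempt_classes` are kept untouched
#' and flagged; a non-exempt group of size 1 is kept with a warning; a
#' replicate with an undefined correlation (zero variance) is removed.
#'
#' @inheritParams zero_low_counts
#' @return `list(counts = count_matrix, report = filter_report)`.
#' @export
drop_discordant_replicates <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "count_matrix"))
  sheet <- m$samples
  drop <- character(0)
  exempt_flagged <- character(0)
  for (grp in unique(sheet$replicate_group)) {
    rows <- sheet[sheet$replicate_group == grp, , drop = FALSE]
    if (rows$sample_class[1] %in% cfg$corr_exempt_classes) {
      exempt_flagged <- c(exempt_flagged, grp)
      next
    }
    if (nrow(rows) == 1) {
      warning("replicate group '", grp, "' has a single replicate; ",
              "concordance not assessable, kept")
      next
    }
    cols <- m$counts[, rows$sample_id, drop = FALSE]
    r <- replicate_concordance(cols, cfg$correlation_scale)
    bad <- is.na(r) | r < cfg$min_replicate_pearson
    drop <- c(drop, rows$sample_id[bad])
  }
  report <- add_step(new_filter_report(), "replicate_concordance",
                     replicates_dropped = drop,
                     reads_dropped = sum(m$counts[, drop, drop = FALSE]),
                     exempt_groups = exempt_flagged)
  list(counts = subset_samples(m, !colnames(m$counts) %in% drop),
       report = report)
}

#' Discard barcodes detected in too few replicates
#'
#' Within each replicate group, a barcode's counts are zeroed unless the
#' barcode is present (count > 0) in at least `min_replicates_detected`
#' replicates of that group (capped at the group size). Applies to every
#' class, including cfDNA quintuplicates.
#'
#' @inheritParams zero_low_counts
#' @return `list(counts = count_matrix, report = filter_report)`.
#' @export
drop_sporadic_barcodes <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "count_matrix"))
  sheet <- m$samples
  zeroed_cells <- 0L
  zeroed_reads <- 0
  for (grp in unique(sheet$replicate_group)) {
    ids <- sheet$sample_id[sheet$replicate_group == grp]
    need <- min(cfg$min_replicates_detected, length(ids))
    cols <- m$counts[, ids, drop = FALSE]
    present <- rowSums(cols > 0)
    kill <- present > 0 & present < need
    if (any(kill)) {
      zeroed_cells <- zeroed_cells + sum(cols[kill, , drop = FALSE] > 0)
      zeroed_reads <- zeroed_reads + sum(cols[kill, , drop = FALSE])
      m$counts[kill, ids] <- 0L
    }
  }
  report <- add_step(new_filter_report(), "sporadic_barcodes",
                     cells_zeroed = zeroed_cells, reads_zeroed = zeroed_reads)
  list(counts = m, report = report)
}

#' Run the full QC filter chain
#'
#' Applies, in order: low-count zeroing, sample depth filtering, replicate
#' concordance filtering, and sporadic-barcode removal, accumulating a
#' step-by-step [print.filter_report()] log with read-mass accounting
#' (input total = output total + zeroed + dropped).
#'
#' @inheritParams zero_low_counts
#' @return `list(counts = count_matrix, report = filter_report)`.
#' @export
qc_filter <- function(m, cfg = filter_config()) {
  input_total <- sum(m$counts)
  report <- new_filter_report()

  m1 <- zero_low_counts(m, cfg)
  report <- add_step(report, "zero_low_counts",
                     cells_zeroed = sum(m$counts > 0) - sum(m1$counts > 0),
                     reads_zeroed = input_total - sum(m1$counts))

  s2 <- drop_low_depth_samples(m1, cfg)
  report$steps <- c(report$steps, s2$report$steps)

  s3 <- drop_discordant_replicates(s2$counts, cfg)
  report$steps <- c(report$steps, s3$report$steps)

  s4 <- drop_sporadic_barcodes(s3$counts, cfg)
  report$steps <- c(report$steps, s4$report$steps)

  report <- add_step(report, "mass_accounting",
                     input_reads = input_total,
                     output_reads = sum(s4$counts$counts),
                     removed_reads = input_total - sum(s4$counts$counts))
  list(counts = s4$counts, report = report)
}

#' Pool replicates and normalize to frequencies
#'
#' Pools each replicate group by summing its columns, then normalizes the
#' pooled counts to relative frequencies — one `clone_profile` per group.
#' A group whose pooled total is zero yields an empty profile.
#'
#' @param m A filtered `count_matrix`.
#' @return Named list of `clone_profile`s (names = replicate groups).
#' @export
pool_and_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  sheet <- m$samples
  groups <- unique(sheet$replicate_group)
  out <- lapply(groups, function(grp) {
    rows <- sheet[sheet$replicate_group == grp, , drop = FALSE]
    pooled <- rowSums(m$counts[, rows$sample_id, drop = FALSE])
    clone_profile(pooled, label = grp,
                  sample_class = rows$sample_class[1],
                  tissue_location = rows$tissue_location[1])
  })
  names(out) <- groups
  out
}

#' Reconstruct the whole-tumor profile from its pieces
#'
#' Cumulatively adds each barcode's pooled counts across the tumor-piece
#' profiles and renormalizes, recreating the profile of the full tumor.
#'
#' @param pieces Non-empty list of `clone_profile`s carrying pooled
#'   counts.
#' @param label Label for the reconstructed profile.
#' @return A `clone_profile`.
#' @export
reconstruct_whole_tumor <- function(pieces, label = "tumor") {
  if (inherits(pieces, "clone_profile")) pieces <- list(pieces)
  if (length(pieces) == 0) stop("at least one piece profile is required")
  stopifnot(all(vapply(pieces, inherits, TRUE, "clone_profile")))
  ids <- unique(unlist(lapply(pieces, function(p) names(p$count))))
  tot <- stats::setNames(numeric(length(ids)), ids)
  for (p in pieces) tot[names(p$count)] <- tot[names(p$count)] + p$count
  clone_profile(tot, label = label, sample_class = "tumor_piece")
}

#' Restrict sample profiles to the tumor's barcode set
#'
#' Intersects each sample profile with the barcodes present in the
#' (reconstructed) primary-tumor profile and renormalizes, so barcodes
#' never seen in the tumor cannot inflate downstream representativeness
#' statistics. The removed frequency mass is recorded on each profile as
#' attribute `removed_mass`.
#'
#' @param samples A `clone_profile` or list of them.
#' @param tumor The tumor `clone_profile`.
#' @return List of restricted `clone_profile`s.
#' @export
restrict_to_tumor_barcodes <- function(samples, tumor) {
  stopifnot(inherits(tumor, "clone_profile"))
  single <- inherits(samples, "clone_profile")
  if (single) samples <- list(samples)
  if (is_empty_profile(tumor))
    warning("tumor profile is empty; all sample profiles will be emptied")
  keep_set <- profile_barcodes(tumor)
  out <- lapply(samples, function(p) {
    keep <- names(p$count) %in% keep_set
    removed <- sum(p$freq[!keep])
    q <- clone_profile(p$count[keep], label = p$label,
                       sample_class = p$sample_class,
                       tissue_location = p$tissue_location)
    attr(q, "removed_mass") <- removed
    q
  })
  if (single) out[[1]] else out
}
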