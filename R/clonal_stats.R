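#' Shannon diversity index of a clone profile
#'
#' H = -sum p_i log(p_i) over the barcodes present, jointly reflecting
#' clone richness and evenness. Natural logarithm (nats) by default; an
#' empty profile has H = 0 by convention.
#'
#' @param p A `clone_profile`.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Numeric diversity index.
#' @export
shannon_index <- function(p, base = exp(1)) {
  stopifnot(inherits(p, "clone_profile"))
  f <- p$freq
  if (length(f) == 0) return(0)
  -sum(f * log(f)) / log(base)
}

#' Percentage of tumor barcodes detected in a sample
#'
#' 100 x |barcodes(sample) intersect barcodes(tumor)| / |barcodes(tumor)|.
#'
#' @param sample,tumor `clone_profile`s; the tumor must be non-empty.
#' @return Percentage in [0, 100].
#' @export
pct_barcodes_detected <- function(sample, tumor) {
  stopifnot(inherits(sample, "clone_profile"), inherits(tumor, "clone_profile"))
  tb <- profile_barcodes(tumor)
  if (length(tb) == 0) stop("tumor profile is empty")
  100 * length(intersect(profile_barcodes(sample), tb)) / length(tb)
}

#' Percentage of tumor biomass captured by one or more biopsies
#'
#' The tumor biomass captured is the fraction of whole-tumor read mass
#' attributable to barcodes detected in the union of the given samples:
#' 100 x sum of tumor frequencies of barcodes detected in any of them.
#' Passing several profiles evaluates a biopsy combination (e.g. deep
#' needle + terminal-bleed cfDNA).
#'
#' @param samples A `clone_profile` or list of them.
#' @param tumor The tumor `clone_profile` (non-empty).
#' @return Percentage in [0, 100].
#' @export
biomass_captured <- function(samples, tumor) {
  stopifnot(inherits(tumor, "clone_profile"))
  if (inherits(samples, "clone_profile")) samples <- list(samples)
  if (is_empty_profile(tumor)) stop("tumor profile is empty")
  detected <- unique(unlist(lapply(samples, profile_barcodes)))
  100 * sum(tumor$freq[names(tumor$freq) %in% detected])
}

#' Dominant clones of a tumor
#'
#' A dominant clone is one whose read frequency strictly exceeds the
#' dominance threshold (1% of total tumor reads by default); a clone at
#' exactly the threshold is not dominant.
#'
#' @param tumor A `clone_profile`.
#' @param threshold Frequency threshold in (0, 1); default 0.01.
#' @return Character vector of dominant barcode IDs.
#' @export
dominant_clones <- function(tumor, threshold = 0.01) {
  stopifnot(inherits(tumor, "clone_profile"),
            threshold > 0, threshold < 1)
  names(tumor$freq)[tumor$freq > threshold]
}

#' Partition barcodes by center/periphery membership
#'
#' Classifies every barcode of the union as detected only in the
#' periphery, only in the center, or in both, and returns the three
#' percentages of the union (summing to 100).
#'
#' @param center Center-piece `clone_profile`.
#' @param periphery List of peripheral-piece `clone_profile`s (at least
#'   one).
#' @return Named numeric vector `c(periphery_only, center_only, both)`.
#' @export
partition_center_periphery <- function(center, periphery) {
  stopifnot(inherits(center, "clone_profile"))
  if (inherits(periphery, "clone_profile")) periphery <- list(periphery)
  if (length(periphery) == 0) stop("at least one periphery piece is required")
  cen <- profile_barcodes(center)
  per <- unique(unlist(lapply(periphery, profile_barcodes)))
  u <- union(cen, per)
  if (length(u) == 0) stop("no barcodes detected in center or periphery")
  both <- intersect(cen, per)
  100 * c(periphery_only = length(setdiff(per, cen)),
          center_only = length(setdiff(cen, per)),
          both = length(both)) / length(u)
}

#' Pearson correlation between a sample and the tumor profile
#'
#' Correlates paired barcode frequencies. By default the correlation is
#' taken over the union of the two barcode sets, with absent barcodes
#' entering as frequency 0 (intersection-only correlation is available
#' but inflates r). A degenerate input (zero variance on either side) is
#' flagged with a warning and returns NA rather than silently 0.
#'
#' @param sample,tumor `clone_profile`s.
#' @param over `"union"` (default) or `"intersection"`.
#' @return Pearson r, or NA for degenerate input.
#' @export
sample_tumor_correlation <- function(sample, tumor,
                                     over = c("union", "intersection")) {
  stopifnot(inherits(sample, "clone_profile"), inherits(tumor, "clone_profile"))
  over <- match.arg(over)
  ids <- if (over == "union")
    union(profile_barcodes(sample), profile_barcodes(tumor))
  else intersect(profile_barcodes(sample), profile_barcodes(tumor))
  if (length(ids) < 2)
    stop("need at least 2 barcodes in the ", over, " to correlate")
  x <- stats::setNames(numeric(length(ids)), ids)
  y <- x
  x[names(sample$freq)[names(sample$freq) %in% ids]] <-
    sample$freq[names(sample$freq) %in% ids]
  y[names(tumor$freq)[names(tumor$freq) %in% ids]] <-
    tumor$freq[names(tumor$freq) %in% ids]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Group comparisons used for biopsy and piece statistics
#'
#' Two groups: Student's unpaired t test (equal variances). More than two
#' groups: one-way ANOVA followed by Tukey's multiple-comparisons test.
#' Comparisons involving a group with fewer than 3 observations are
#' reported as not determined (NA p-value, flagged), following the
#' convention that statistics are not determined when n < 3.
#'
#' @param values Numeric vector of observations.
#' @param labels Group label per observation (>= 2 distinct groups).
#' @return A `group_comparison` list: `method`, `p_value` (t test or
#'   ANOVA F), `pairwise` data frame (for > 2 groups), `group_n`, and
#'   `not_determined`.
#' @export
group_comparison <- function(values, labels) {
  stopifnot(is.numeric(values), length(values) == length(labels))
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("at least two groups are required")
  n <- vapply(groups, function(g) sum(labels == g), integer(1))
  nd <- any(n < 3)
  if (length(groups) == 2) {
    p <- if (nd) NA_real_ else
      t.test(values[labels == groups[1]], values[labels == groups[2]],
             var.equal = TRUE)$p.value
    res <- list(method = "unpaired t test", p_value = p, pairwise = NULL,
                group_n = n, not_determined = nd)
  } else {
    fit <- aov(values ~ factor(labels))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)[[1]]
    cmp <- rownames(tk)
    pw <- data.frame(comparison = cmp, p_adj = tk[, "p adj"],
                     row.names = NULL)
    small <- groups[n < 3]
    if (length(small)) {
      parts <- strsplit(cmp, "-", fixed = TRUE)
      bad <- vapply(parts, function(pp) any(pp %in% small), logical(1))
      pw$p_adj[bad] <- NA_real_
      if (nd) p <- p  # overall F reported; flagged via not_determined
    }
    res <- list(method = "one-way ANOVA + Tukey", p_value = p, pairwise = pw,
                group_n = n, not_determined = nd)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$method, ", p = ", format.pval(x$p_value),
      if (x$not_determined) " (some groups n < 3: not determined)",
      "\n", sep = "")
  if (!is.null(x$pairwise)) print(x$pairwise, ...)
  invisible(x)
}

#' Representativeness of a biopsy against the tumor
#'
#' Bundles the headline representativeness metrics for one sample (or a
#' combination of samples): percent of tumor barcodes detected, percent
#' of tumor biomass captured, the detected and missed-dominant barcode
#' sets, and the Pearson correlation with the tumor frequency profile.
#'
#' @param samples A `clone_profile` or list (evaluated as a combination).
#' @param tumor The tumor `clone_profile`.
#' @param dominance_threshold Passed to [dominant_clones()].
#' @return A `representativeness` list.
#' @export
representativeness <- function(samples, tumor, dominance_threshold = 0.01) {
  if (inherits(samples, "clone_profile")) samples <- list(samples)
  detected <- intersect(unique(unlist(lapply(samples, profile_barcodes))),
                        profile_barcodes(tumor))
  dom <- dominant_clones(tumor, dominance_threshold)
  combined <- reconstruct_whole_tumor(samples, label = "combined")
  r <- if (clone_richness(combined) + clone_richness(tumor) >= 2 &&
           !is_empty_profile(combined))
    suppressWarnings(sample_tumor_correlation(combined, tumor)) else NA_real_
  structure(list(
    pct_barcodes_detected = 100 * length(detected) /
      length(profile_barcodes(tumor)),
    pct_biomass_captured = biomass_captured(samples, tumor),
    detected = detected,
    missed_dominant = setdiff(dom, detected),
    pearson_r = r), class = "representativeness")
}

#' @export
print.representativeness <- function(x, ...) {
  cat("<representativeness> barcodes detected: ",
      round(x$pct_barcodes_detected, 1), "%, biomass captured: ",
      round(x$pct_biomass_captured, 1), "%, r = ",
      round(x$pearson_r, 3), ", missed dominant clones: ",
      length(x$missed_dominant), "\n", sep = "")
  invisible(x)
}
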