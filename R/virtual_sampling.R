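#' Dissection plans for a simulated tumor
#'
#' A dissection plan is an ordered list of axis-aligned cuts taken from the
#' outside of the occupied bounding box inward, mimicking how a real tumor
#' is dissected: peripheral edges are cut first, leaving the center exposed
#' as the final piece. Cells are assigned to the first cut that claims
#' them, so the pieces always form a partition of the tumor.
#'
#' `five_piece_plan()` cuts the outer `margin` fraction off both faces of
#' the x and y axes (pieces A-D) and labels the remaining central box E.
#' `seven_piece_plan()` additionally cuts both z faces (pieces A-F, center
#' G), in the style of an in vivo dissection into peripheral and central
#' pieces.
#'
#' @param margin Fraction of the occupied extent cut off each face
#'   (default 0.25).
#' @return A `dissection_plan` object.
#' @export
five_piece_plan <- function(margin = 0.25) {
  stopifnot(margin > 0, margin < 0.5)
  cuts <- list(list(label = "A", axis = 1L, side = "low", frac = margin),
               list(label = "B", axis = 1L, side = "high", frac = margin),
               list(label = "C", axis = 2L, side = "low", frac = margin),
               list(label = "D", axis = 2L, side = "high", frac = margin))
  structure(list(cuts = cuts, center_label = "E"), class = "dissection_plan")
}

#' @rdname five_piece_plan
#' @export
seven_piece_plan <- function(margin = 0.25) {
  stopifnot(margin > 0, margin < 0.5)
  cuts <- list(list(label = "A", axis = 1L, side = "low", frac = margin),
               list(label = "B", axis = 1L, side = "high", frac = margin),
               list(label = "C", axis = 2L, side = "low", frac = margin),
               list(label = "D", axis = 2L, side = "high", frac = margin),
               list(label = "E", axis = 3L, side = "low", frac = margin),
               list(label = "F", axis = 3L, side = "high", frac = margin))
  structure(list(cuts = cuts, center_label = "G"), class = "dissection_plan")
}

#' Virtually dissect a tumor into pieces
#'
#' Applies the plan's cuts in order to the occupied bounding box; cut
#' thresholds are measured on the original box so the plan is a fixed
#' geometry. Every cell lands in exactly one piece.
#'
#' @param state A grown `tumor_state`.
#' @param plan A `dissection_plan` (default [five_piece_plan()]).
#' @return Named list of `clone_profile`s, one per piece, in plan order
#'   with the center piece last; each carries `tissue_location`
#'   `"center"` or `"periphery"`.
#' @export
dissect <- function(state, plan = five_piece_plan()) {
  stopifnot(inherits(state, "tumor_state"), inherits(plan, "dissection_plan"))
  n <- nrow(state$coords)
  if (n == 0) stop("cannot dissect an empty tumor")
  lo <- apply(state$coords, 2, min)
  hi <- apply(state$coords, 2, max)
  piece <- rep(NA_character_, n)
  for (cut in plan$cuts) {
    ax <- cut$axis
    v <- state$coords[, ax]
    span <- hi[ax] - lo[ax]
    inside <- if (cut$side == "low") v <= lo[ax] + cut$frac * span
              else v >= hi[ax] - cut$frac * span
    piece[is.na(piece) & inside] <- cut$label
  }
  piece[is.na(piece)] <- plan$center_label
  labels <- c(vapply(plan$cuts, `[[`, "", "label"), plan$center_label)
  out <- lapply(labels, function(lb) {
    bc <- state$barcode[piece == lb]
    tab <- tabulate(bc)
    keep <- which(tab > 0)
    clone_profile(stats::setNames(as.numeric(tab[keep]), as.character(keep)),
                  label = lb, sample_class = "tumor_piece",
                  tissue_location = if (lb == plan$center_label) "center"
                                    else "periphery")
  })
  names(out) <- labels
  out
}

#' Specify a virtual core-needle biopsy
#'
#' The needle is a cylinder of radius `radius` entering the tumor surface
#' and advancing along `direction`. Its length is `depth_fraction` of the
#' tumor's extent (chord) measured along the needle direction, so
#' `depth_fraction = 0.5` reaches the tumor center (a deep core) and
#' `0.25` covers a quarter of the diameter (a shallow core).
#'
#' @param direction Length-3 vector; needle advance direction (normalized
#'   internally). By default the needle passes through the tumor centroid.
#' @param depth_fraction Fraction of the tumor diameter penetrated,
#'   in (0, 1].
#' @param radius Core radius in lattice units (>= 1).
#' @param entry Optional length-3 entry point; `NULL` aims the axis
#'   through the centroid.
#' @return A `needle_spec` object.
#' @export
needle_spec <- function(direction = c(1, 0, 0), depth_fraction = 0.5,
                        radius = 2, entry = NULL) {
  stopifnot(length(direction) == 3, any(direction != 0),
            depth_fraction > 0, depth_fraction <= 1, radius >= 1)
  structure(list(direction = direction / sqrt(sum(direction^2)),
                 depth_fraction = depth_fraction, radius = radius,
                 entry = entry),
            class = "needle_spec")
}

#' The four canonical planar needle directions
#'
#' Needles directed toward the tumor center from four sides in the
#' mid-height plane: +x, -x, +y, -y.
#'
#' @param depth_fraction,radius Passed to [needle_spec()].
#' @return Named list of four `needle_spec`s.
#' @export
needle_directions <- function(depth_fraction = 0.5, radius = 2) {
  list(xpos = needle_spec(c(1, 0, 0), depth_fraction, radius),
       xneg = needle_spec(c(-1, 0, 0), depth_fraction, radius),
       ypos = needle_spec(c(0, 1, 0), depth_fraction, radius),
       yneg = needle_spec(c(0, -1, 0), depth_fraction, radius))
}

#' Take a virtual needle biopsy
#'
#' Collects every cell whose site lies within the needle cylinder: within
#' `radius` of the needle axis and within the first
#' `depth_fraction * chord` of the tumor's extent along the needle
#' direction, measured from where the axis enters the occupied region. An
#' empty intersection yields an empty profile, not an error.
#'
#' @param state A grown `tumor_state`.
#' @param spec A [needle_spec()].
#' @param label Specimen label.
#' @return A `clone_profile` with `sample_class = "needle"`.
#' @export
needle_biopsy <- function(state, spec, label = "needle") {
  stopifnot(inherits(state, "tumor_state"), inherits(spec, "needle_spec"))
  xyz <- state$coords
  if (nrow(xyz) == 0)
    return(clone_profile(stats::setNames(numeric(0), character(0)),
                         label = label, sample_class = "needle"))
  dir <- spec$direction
  anchor <- if (is.null(spec$entry)) colMeans(xyz) else as.numeric(spec$entry)
  rel <- sweep(xyz, 2, anchor)
  t_all <- as.numeric(rel %*% dir)
  # chord: tumor extent along the needle direction
  chord <- diff(range(t_all))
  perp2 <- rowSums(rel^2) - t_all^2
  in_cyl <- perp2 <= spec$radius^2 + 1e-9
  if (!any(in_cyl))
    return(clone_profile(stats::setNames(numeric(0), character(0)),
                         label = label, sample_class = "needle"))
  t0 <- min(t_all)
  keep <- in_cyl & t_all <= t0 + spec$depth_fraction * chord + 1e-9
  bc <- state$barcode[keep]
  tab <- tabulate(bc)
  nz <- which(tab > 0)
  clone_profile(stats::setNames(as.numeric(tab[nz]), as.character(nz)),
                label = label, sample_class = "needle")
}

#' Plasma (cfDNA) shedding model
#'
#' Fragments are drawn with probability proportional to clone size times a
#' per-cell shed weight. An optional necrotic core multiplies the weight
#' of cells within `necrotic_radius_frac` of the tumor radius from the
#' centroid (off by default). The draw size `fragments` defaults to
#' `round(k * population_size)`, making detection depend on tumor burden.
#'
#' @param shed_weight Baseline per-cell shed weight, or a named per-clone
#'   weight vector.
#' @param necrotic_boost Multiplier applied to core cells (>= 0).
#' @param necrotic_radius_frac Core radius as a fraction of tumor radius;
#'   0 disables the necrotic core.
#' @param fragments Number of fragments recovered, or `NULL` to use
#'   `round(k * population_size)`.
#' @param k Fragments recovered per tumor cell when `fragments` is `NULL`.
#' @param rng_seed Seed for the draw, or `NULL`.
#' @return A `shed_model` object.
#' @export
shed_model <- function(shed_weight = 1, necrotic_boost = 1,
                       necrotic_radius_frac = 0, fragments = NULL,
                       k = 1e-4, rng_seed = NULL) {
  stopifnot(all(shed_weight >= 0), necrotic_boost >= 0,
            necrotic_radius_frac >= 0, necrotic_radius_frac <= 1, k >= 0)
  if (!is.null(fragments)) stopifnot(fragments >= 0)
  structure(list(shed_weight = shed_weight, necrotic_boost = necrotic_boost,
                 necrotic_radius_frac = necrotic_radius_frac,
                 fragments = fragments, k = k, rng_seed = rng_seed),
            class = "shed_model")
}

# per-clone shed weights; uses geometry only when a necrotic core is active
clone_shed_weights <- function(census, model, state = NULL) {
  ids <- names(census)
  base <- if (length(model$shed_weight) > 1) {
    w <- model$shed_weight[ids]
    w[is.na(w)] <- 0
    w
  } else rep(model$shed_weight, length(census))
  w <- as.numeric(census) * base
  if (model$necrotic_radius_frac > 0 && !is.null(state)) {
    ctr <- colMeans(state$coords)
    d2 <- rowSums(sweep(state$coords, 2, ctr)^2)
    r_core2 <- (model$necrotic_radius_frac^2) * max(d2)
    core_by_clone <- tapply(d2 <= r_core2, state$barcode, sum)
    extra <- stats::setNames(rep(0, length(census)), ids)
    m <- intersect(ids, names(core_by_clone))
    extra[m] <- as.numeric(core_by_clone[m])
    w <- w + (model$necrotic_boost - 1) * extra *
      (if (length(model$shed_weight) > 1) base / pmax(as.numeric(census), 1)
       else model$shed_weight)
  }
  stats::setNames(w, ids)
}

#' Draw a plasma cfDNA sample from a clone census
#'
#' Draws `F` barcode fragments multinomially with probability proportional
#' to clone size x shed weight, splits them uniformly into
#' `n_replicates` pseudo-replicates (plasma barcode PCRs are typically run
#' in quintuplicate to increase recovery odds), and retains a clone only
#' if it appears in at least `min_replicates` of them — the same
#' replicate-detection rule the count QC chain applies. With uniform shed
#' weights the draw is an unbiased multinomial sample of the census.
#'
#' @param census A `clone_census`.
#' @param model A [shed_model()].
#' @param state Optional `tumor_state`, needed only when the necrotic core
#'   is active.
#' @param n_replicates Number of pseudo-replicates (default 5).
#' @param min_replicates Replicates a clone must appear in to be called
#'   detected (default 2).
#' @param label Specimen label.
#' @return A `clone_profile` (class `"cfDNA"`) over the detected clones;
#'   an empty profile when nothing is recovered.
#' @export
sample_cfdna <- function(census, model = shed_model(), state = NULL,
                         n_replicates = 5, min_replicates = 2,
                         label = "cfDNA") {
  stopifnot(inherits(census, "clone_census"), inherits(model, "shed_model"))
  f <- if (is.null(model$fragments))
    round(model$k * attr(census, "population_size")) else model$fragments
  empty <- clone_profile(stats::setNames(numeric(0), character(0)),
                         label = label, sample_class = "cfDNA")
  if (f < 1) return(empty)
  w <- clone_shed_weights(census, model, state)
  if (sum(w) == 0) return(empty)
  with_seed(model$rng_seed, {
    frag <- as.integer(rmultinom(1, f, w))
    reps <- vapply(frag, function(ni)
      if (ni == 0) integer(n_replicates)
      else as.integer(rmultinom(1, ni, rep(1, n_replicates))),
      integer(n_replicates))
    detected <- colSums(reps > 0) >= min_replicates
    if (!any(detected)) empty
    else clone_profile(stats::setNames(as.numeric(frag[detected]),
                                       names(census)[detected]),
                       label = label, sample_class = "cfDNA")
  })
}
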