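#' Configuration for the synthetic-data generators
#'
#' Describes a synthetic barcoding experiment with the statistical
#' structure the analysis pipeline assumes: a tag pool of ~2600 barcodes,
#' log-normal clone abundances (a few dominant clones above 1%, a long
#' minor tail), clone mass split unevenly ("patchily") across tumor
#' pieces by per-clone Dirichlet draws, tissue samples sequenced as PCR
#' duplicates and cfDNA/lung as quintuplicates, and per-replicate read
#' depths with optional Dirichlet-multinomial overdispersion.
#'
#' @param n_barcodes Size of the barcode pool (default 2600).
#' @param barcode_length Barcode length in nt (default 20).
#' @param sigma Log-normal abundance sd on the log scale (default 1.5).
#' @param abundance Optional explicit (unnormalized) abundance vector
#'   overriding the log-normal draw.
#' @param n_pieces Number of tumor pieces (default 5).
#' @param concentration Symmetric Dirichlet concentration governing how
#'   each clone spreads across pieces: small = patchy (mass in 1-2
#'   pieces), large = well mixed. Default 0.3.
#' @param replicates_tissue,replicates_cfdna PCR replicates per tissue
#'   sample (default 2) and per cfDNA/lung sample (default 5).
#' @param depth Sequencing depth per replicate (default 1e5 reads).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 is plain
#'   multinomial.
#' @param rng_seed Master seed for all generators, or `NULL`.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_barcodes = 2600, barcode_length = 20,
                         sigma = 1.5, abundance = NULL, n_pieces = 5,
                         concentration = 0.3, replicates_tissue = 2,
                         replicates_cfdna = 5, depth = 1e5,
                         overdispersion = 0, rng_seed = NULL) {
  stopifnot(n_barcodes >= 1, barcode_length >= 1, sigma >= 0,
            n_pieces >= 1, concentration > 0, replicates_tissue >= 1,
            replicates_cfdna >= 1, depth >= 0, overdispersion >= 0)
  structure(list(n_barcodes = as.integer(n_barcodes),
                 barcode_length = as.integer(barcode_length),
                 sigma = sigma, abundance = abundance,
                 n_pieces = as.integer(n_pieces),
                 concentration = concentration,
                 replicates_tissue = as.integer(replicates_tissue),
                 replicates_cfdna = as.integer(replicates_cfdna),
                 depth = depth, overdispersion = overdispersion,
                 rng_seed = rng_seed),
            class = "synth_config")
}

#' Generate a random barcode library
#'
#' Draws `n_barcodes` distinct random sequences of the configured length
#' with pairwise Hamming distance >= 2, guaranteed by rejection: a
#' candidate colliding with an accepted sequence at distance <= 1 is
#' redrawn. (Distance <= 1 is detected in O(L) per candidate by hashing
#' each accepted sequence's L single-position masks.)
#'
#' @param cfg A [synth_config()].
#' @return A [barcode_library()].
#' @export
synth_library <- function(cfg = synth_config()) {
  n <- cfg$n_barcodes
  L <- cfg$barcode_length
  if (n > 4^L / (3 * L + 1))
    stop("cannot fit ", n, " barcodes of length ", L,
         " at pairwise Hamming distance >= 2")
  with_seed(cfg$rng_seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    seqs <- character(n)
    i <- 0L
    while (i < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
      masks <- vapply(seq_len(L), function(j) {
        s <- cand; substr(s, j, j) <- "."; s
      }, character(1))
      if (any(vapply(masks, exists, TRUE, envir = seen, inherits = FALSE)))
        next
      for (msk in masks) assign(msk, TRUE, envir = seen)
      i <- i + 1L
      seqs[i] <- cand
    }
    barcode_library(sprintf("BC%04d", seq_len(n)), seqs)
  })
}

# one Dirichlet draw
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))  # numeric underflow guard
  g / sum(g)
}

#' Generate a patchy multi-piece tumor profile
#'
#' Draws global clone frequencies from the abundance law, then splits
#' each clone's mass across the pieces with an independent symmetric
#' Dirichlet draw. Small concentrations concentrate each clone's mass in
#' one or two pieces (spatial patchiness); large concentrations make all
#' pieces resemble the whole tumor. The tumor profile equals the
#' normalized sum of the pieces by construction.
#'
#' @param cfg A [synth_config()].
#' @param lib Optional [barcode_library()] supplying barcode IDs;
#'   defaults to IDs `BC0001...`.
#' @return `list(tumor = clone_profile, pieces = list of clone_profile)`;
#'   piece counts are the clone mass landed in each piece (arbitrary
#'   units summing to the tumor's abundance vector).
#' @export
synth_tumor_profiles <- function(cfg = synth_config(), lib = NULL) {
  n <- cfg$n_barcodes
  ids <- if (!is.null(lib)) lib$id[seq_len(n)] else sprintf("BC%04d", seq_len(n))
  with_seed(cfg$rng_seed, {
    ab <- if (!is.null(cfg$abundance)) {
      stopifnot(length(cfg$abundance) == n, all(cfg$abundance >= 0))
      as.numeric(cfg$abundance)
    } else rlnorm(n, meanlog = 0, sdlog = cfg$sigma)
    split <- t(vapply(seq_len(n), function(i)
      rdirichlet1(rep(cfg$concentration, cfg$n_pieces)),
      numeric(cfg$n_pieces)))
    mass <- ab * split  # n x pieces
    pieces <- lapply(seq_len(cfg$n_pieces), function(j)
      clone_profile(stats::setNames(mass[, j], ids),
                    label = paste0("piece_", LETTERS[j]),
                    sample_class = "tumor_piece"))
    tumor <- clone_profile(stats::setNames(ab, ids), label = "tumor",
                           sample_class = "tumor_piece")
    list(tumor = tumor, pieces = pieces)
  })
}

#' Simulate replicate sequencing counts for one specimen
#'
#' Each replicate is a draw of `depth` reads over the profile's
#' frequencies: plain multinomial when `overdispersion` is 0, otherwise
#' Dirichlet-multinomial with per-replicate probabilities drawn from
#' Dirichlet(freq / overdispersion), emulating PCR jackpotting noise.
#' Replicate columns share a replicate-group label.
#'
#' @param profile A `clone_profile` giving the specimen's true
#'   frequencies.
#' @param n_replicates Number of replicate columns.
#' @param depth Reads per replicate.
#' @param overdispersion Dirichlet-multinomial overdispersion (0 = none).
#' @param seed Seed or `NULL`.
#' @param all_barcodes Optional full barcode ID universe for the matrix
#'   rows (defaults to the profile's barcodes).
#' @param sample_class,tissue_location Metadata for the sheet.
#' @param group Replicate-group label (defaults to the profile label).
#' @return A `count_matrix` with `n_replicates` columns.
#' @export
simulate_counts <- function(profile, n_replicates = 2, depth = 1e5,
                            overdispersion = 0, seed = NULL,
                            all_barcodes = NULL,
                            sample_class = profile$sample_class,
                            tissue_location = profile$tissue_location,
                            group = profile$label) {
  stopifnot(inherits(profile, "clone_profile"), n_replicates >= 1, depth >= 0)
  ids <- if (is.null(all_barcodes)) names(profile$freq) else all_barcodes
  if (is.na(sample_class)) sample_class <- "tumor_piece"
  p0 <- stats::setNames(numeric(length(ids)), ids)
  p0[names(profile$freq)] <- profile$freq
  counts <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      if (depth == 0 || sum(p0) == 0) return(integer(length(ids)))
      p <- if (overdispersion > 0) {
        a <- p0 / overdispersion
        pos <- a > 0
        pr <- numeric(length(a))
        pr[pos] <- rdirichlet1(a[pos])
        pr
      } else p0
      as.integer(rmultinom(1, depth, p))
    }, integer(length(ids)))
  })
  rownames(counts) <- ids
  sample_ids <- sprintf("%s_rep%d", group, seq_len(n_replicates))
  colnames(counts) <- sample_ids
  sheet <- sample_sheet(sample_ids, make_indexes(n_replicates, prefix = group),
                        replicate_group = group, sample_class = sample_class,
                        tissue_location = tissue_location)
  count_matrix(counts, sheet)
}

#' Deterministic distinct index sequences
#'
#' Encodes integers in base 4 over {A,C,G,T}, optionally offset by a
#' hash of `prefix` so different specimens get different index blocks.
#'
#' @param n Number of indexes.
#' @param length Index length in nt (default 8).
#' @param prefix Label mixed into the encoding offset.
#' @return Character vector of `n` distinct index sequences.
#' @export
make_indexes <- function(n, length = 8, prefix = "") {
  stopifnot(n >= 1, n <= 4^length)
  offset <- if (nzchar(prefix))
    sum(utf8ToInt(prefix) * seq_along(utf8ToInt(prefix))) %% 7919 else 0
  vapply(seq_len(n), function(i) {
    v <- (i + offset * 601) %% (4^length)
    digits <- integer(length)
    for (j in seq_len(length)) {
      digits[j] <- v %% 4
      v <- v %/% 4
    }
    paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
  }, character(1))
}

#' Merge count matrices column-wise
#'
#' Binds matrices that share the same barcode universe into one
#' `count_matrix` (e.g. the piece duplicates plus cfDNA quintuplicates of
#' one synthetic experiment).
#'
#' @param ... `count_matrix` objects with identical rownames.
#' @return A combined `count_matrix`.
#' @export
cbind_count_matrices <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "count_matrix"))
    ms <- ms[[1]]
  stopifnot(length(ms) >= 1, all(vapply(ms, inherits, TRUE, "count_matrix")))
  rn <- rownames(ms[[1]]$counts)
  stopifnot(all(vapply(ms, function(m) identical(rownames(m$counts), rn), TRUE)))
  counts <- do.call(cbind, lapply(ms, function(m) m$counts))
  sheets <- do.call(rbind, lapply(ms, function(m) as.data.frame(m$samples)))
  sheet <- sample_sheet(sheets$sample_id, make_indexes(nrow(sheets)),
                        sheets$replicate_group, sheets$sample_class,
                        sheets$tissue_location)
  count_matrix(counts, sheet,
               unassigned = sum(vapply(ms, function(m) m$unassigned, 1)))
}

#' Write synthetic FASTQ reads realizing a count matrix
#'
#' Emits exactly `sum(counts)` reads, each laid out as
#' `[sample index][anchor][barcode][filler]` padded to the layout's read
#' length, deterministically shuffled by `seed`. An optional uniform
#' per-base substitution error rate corrupts reads for mismatch-tolerance
#' tests. The inverse of [demultiplex_and_count()] when `error_rate = 0`.
#'
#' @param m A `count_matrix` whose barcodes are all in `lib` and whose
#'   samples are all in its sheet.
#' @param lib The [barcode_library()].
#' @param path Output FASTQ path (`.gz` for gzip).
#' @param layout A [read_layout()].
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Seed for shuffling and errors, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(m, lib, path, layout = read_layout(),
                        error_rate = 0, seed = NULL) {
  stopifnot(inherits(m, "count_matrix"), inherits(lib, "barcode_library"),
            error_rate >= 0, error_rate < 1)
  if (!all(rownames(m$counts) %in% lib$id))
    stop("count matrix contains barcodes absent from the library")
  sheet <- m$samples
  bc_seq <- stats::setNames(lib$sequence, lib$id)
  idx_seq <- stats::setNames(sheet$index, sheet$sample_id)
  if (any(nchar(sheet$index) != layout$index_length))
    stop("sheet index length does not match the read layout")
  nz <- which(m$counts > 0, arr.ind = TRUE)
  reps <- m$counts[nz]
  bcs <- rep(rownames(m$counts)[nz[, 1]], reps)
  smp <- rep(colnames(m$counts)[nz[, 2]], reps)
  core <- paste0(idx_seq[smp], layout$anchor, bc_seq[bcs])
  pad_n <- layout$read_length - nchar(core)
  filler <- strrep(strrep("TGAC", ceiling(layout$read_length / 4)), 1)
  reads <- paste0(core, substr(rep(filler, length(core)), 1, pad_n))
  with_seed(seed, {
    reads <- reads[sample.int(length(reads))]
    if (error_rate > 0 && length(reads)) {
      mat <- do.call(rbind, strsplit(reads, ""))
      hit <- matrix(runif(length(mat)) < error_rate, nrow(mat))
      if (any(hit)) {
        cur <- mat[hit]
        alt <- vapply(cur, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        mat[hit] <- alt
        reads <- apply(mat, 1, paste, collapse = "")
      }
    }
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(reads)) {
      qual <- strrep("I", layout$read_length)
      writeLines(paste0("@read_", seq_along(reads), "\n", reads, "\n+\n", qual),
                 con)
    }
    invisible(path)
  })
}
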