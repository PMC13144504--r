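test_that("low-count zeroing is exact at the threshold and idempotent", {
  counts <- matrix(c(0L, 9L, 10L, 11L, 500L, 10000L), ncol = 1,
                   dimnames = list(paste0("b", 1:6), "s_rep1"))
  m <- make_cm(counts, groups = "s")
  z <- zero_low_counts(m)
  expect_equal(unname(z$counts[, 1]), c(0L, 0L, 0L, 11L, 500L, 10000L))
  expect_identical(zero_low_counts(z)$counts, z$counts)
  # all-zero matrix unchanged
  m0 <- make_cm(matrix(0L, 3, 1, dimnames = list(paste0("b", 1:3),
                                                 "s_rep1")), groups = "s")
  expect_identical(zero_low_counts(m0)$counts, m0$counts)
})

test_that("sample depth filter is strict at 10000 reads", {
  counts <- cbind(a_rep1 = c(9999L, 0L), b_rep1 = c(10000L, 0L),
                  c_rep1 = c(20000L, 5L))
  rownames(counts) <- c("b1", "b2")
  m <- make_cm(counts, groups = c("a", "b", "c"))
  out <- drop_low_depth_samples(m)
  expect_equal(colnames(out$counts$counts), c("b_rep1", "c_rep1"))
  expect_equal(out$report$steps$low_depth$samples_dropped, "a_rep1")
  expect_equal(out$report$steps$low_depth$reads_dropped, 9999)
  # all samples passing leaves the matrix identical
  ok <- drop_low_depth_samples(out$counts)
  expect_identical(ok$counts$counts, out$counts$counts)
  # empty matrix in, empty matrix out
  e <- make_cm(matrix(integer(0), 0, 1,
                      dimnames = list(NULL, "x_rep1")), groups = "x")
  expect_equal(ncol(drop_low_depth_samples(e)$counts$counts), 0)
})

test_that("replicate concordance removal is strictly below 0.6", {
  pair_in <- concordant_pair_r060()   # r = 0.6 exactly
  pair_out <- discordant_pair_r059()  # r = 0.58999... < 0.6
  expect_equal(cor(pair_in[, 1], pair_in[, 2]), 0.6)
  expect_lt(cor(pair_out[, 1], pair_out[, 2]), 0.6)

  mk <- function(pair, cls) {
    counts <- cbind(pair, pair_in)
    colnames(counts) <- c("g_rep1", "g_rep2", "h_rep1", "h_rep2")
    rownames(counts) <- paste0("b", seq_len(nrow(counts)))
    make_cm(counts, groups = c("g", "g", "h", "h"),
            sample_class = c(cls, cls, "tumor_piece", "tumor_piece"))
  }

  kept <- drop_discordant_replicates(mk(pair_in, "tumor_piece"))
  expect_equal(ncol(kept$counts$counts), 4)  # r = 0.60 kept: rule is strict

  removed <- drop_discordant_replicates(mk(pair_out, "tumor_piece"))
  expect_equal(colnames(removed$counts$counts), c("h_rep1", "h_rep2"))
  expect_setequal(removed$report$steps$replicate_concordance$replicates_dropped,
                  c("g_rep1", "g_rep2"))

  # identical replicate columns (r = 1) are kept
  ident <- make_cm(cbind(i_rep1 = c(100L, 200L, 300L),
                         i_rep2 = c(100L, 200L, 300L)) |>
                     (\(x) {rownames(x) <- paste0("b", 1:3); x})(),
                   groups = c("i", "i"))
  expect_equal(ncol(drop_discordant_replicates(ident)$counts$counts), 2)

  # cfDNA groups are exempt however discordant, and flagged in the report
  cf <- drop_discordant_replicates(mk(pair_out, "cfDNA"))
  expect_equal(ncol(cf$counts$counts), 4)
  expect_true("g" %in% cf$report$steps$replicate_concordance$exempt_groups)
})

test_that("a single-replicate non-exempt group warns and is kept", {
  counts <- cbind(solo_rep1 = c(100L, 50L))
  rownames(counts) <- c("b1", "b2")
  m <- make_cm(counts, groups = "solo")
  expect_warning(out <- drop_discordant_replicates(m), "single replicate")
  expect_equal(ncol(out$counts$counts), 1)
})

test_that("sporadic barcodes need detection in two replicates per group", {
  counts <- cbind(d_rep1 = c(50L, 40L, 0L), d_rep2 = c(60L, 0L, 0L),
                  q_rep1 = c(9L, 11L, 0L), q_rep2 = c(12L, 13L, 0L),
                  q_rep3 = c(0L, 0L, 0L), q_rep4 = c(0L, 0L, 0L),
                  q_rep5 = c(0L, 0L, 0L))
  rownames(counts) <- c("b1", "b2", "b3")
  m <- make_cm(counts, groups = c("d", "d", rep("q", 5)),
               sample_class = c("tumor_piece", "tumor_piece", rep("cfDNA", 5)))
  out <- drop_sporadic_barcodes(m)$counts$counts
  # b1: in 2 of 2 duplicates -> kept; 2 of 5 quintuplicates -> kept
  expect_equal(unname(out["b1", c("d_rep1", "d_rep2")]), c(50L, 60L))
  expect_equal(unname(out["b1", "q_rep1"]), 9L)
  # b2: 1 of 2 duplicates -> zeroed in that group; 2 of 5 -> kept in q
  expect_equal(unname(out["b2", c("d_rep1", "d_rep2")]), c(0L, 0L))
  expect_equal(unname(out["b2", c("q_rep1", "q_rep2")]), c(11L, 13L))
  # barcode present everywhere is unchanged (idempotence on kept rows)
  again <- drop_sporadic_barcodes(
    count_matrix(out, m$samples))$counts$counts
  expect_identical(again, out)
})

test_that("pooling sums replicates and normalizes to frequencies", {
  counts <- cbind(g_rep1 = c(5L, 30L), g_rep2 = c(7L, 30L),
                  solo_rep1 = c(30L, 10L))
  rownames(counts) <- c("B", "C")
  m <- make_cm(counts, groups = c("g", "g", "solo"))
  profs <- pool_and_normalize(m)
  expect_equal(unname(profs$g$count["B"]), 12)
  expect_equal(sum(profs$g$freq), 1)
  expect_equal(unname(profs$solo$freq), c(0.75, 0.25))
  # pooled counts {A:60, B:40} -> frequencies 0.6 / 0.4
  m2 <- make_cm(cbind(x_rep1 = c(60L, 40L)) |>
                  (\(x) {rownames(x) <- c("A", "B"); x})(), groups = "x")
  expect_equal(unname(pool_and_normalize(m2)$x$freq), c(0.6, 0.4))
  # a group pooling to zero gives an empty profile
  m3 <- make_cm(cbind(z_rep1 = c(0L, 0L)) |>
                  (\(x) {rownames(x) <- c("A", "B"); x})(), groups = "z")
  expect_true(is_empty_profile(pool_and_normalize(m3)$z))
})

test_that("whole-tumor reconstruction adds pieces and renormalizes", {
  p1 <- make_profile(A = 100)
  p2 <- make_profile(A = 100, B = 200)
  tum <- reconstruct_whole_tumor(list(p1, p2))
  expect_equal(unname(tum$freq[c("A", "B")]), c(0.5, 0.5))
  expect_equal(sum(tum$freq), 1)
  # single piece: reconstruction is that piece
  expect_equal(reconstruct_whole_tumor(list(p2))$freq, p2$freq)
  expect_error(reconstruct_whole_tumor(list()), "at least one piece")
})

test_that("restricting to tumor barcodes intersects and renormalizes", {
  tumor <- make_profile(A = 0.5, B = 0.5)
  s1 <- make_profile(A = 10, B = 10)           # subset: unchanged
  s2 <- make_profile(A = 30, X = 10)           # X absent from tumor
  out <- restrict_to_tumor_barcodes(list(s1, s2), tumor)
  expect_equal(out[[1]]$freq, s1$freq)
  expect_equal(unname(out[[2]]$freq), 1)
  expect_equal(profile_barcodes(out[[2]]), "A")
  expect_equal(attr(out[[2]], "removed_mass"), 0.25)
  # empty tumor empties everything, with a warning
  empty_tumor <- clone_profile(stats::setNames(numeric(0), character(0)))
  expect_warning(out2 <- restrict_to_tumor_barcodes(list(s1), empty_tumor),
                 "empty")
  expect_true(is_empty_profile(out2[[1]]))
})

test_that("the full chain runs in order, accounts for mass, never raises a count", {
  set.seed(71)
  base <- matrix(rpois(40 * 4, 800), 40, 4)
  base[, 2] <- base[, 1] + rpois(40, 5)        # concordant with col 1
  base[base < 0] <- 0
  counts <- base
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("b", 1:40),
                           c("g_rep1", "g_rep2", "h_rep1", "h_rep2"))
  m <- make_cm(counts, groups = c("g", "g", "h", "h"))
  out <- qc_filter(m)
  expect_equal(names(out$report$steps),
               c("zero_low_counts", "low_depth", "replicate_concordance",
                 "sporadic_barcodes", "mass_accounting"))
  acc <- out$report$steps$mass_accounting
  expect_equal(acc$input_reads, sum(m$counts))
  expect_equal(acc$input_reads, acc$output_reads + acc$removed_reads)
  # no surviving cell exceeds its input count
  common <- colnames(out$counts$counts)
  expect_true(all(out$counts$counts <= m$counts[, common]))
  # idempotence of the full chain on its own output
  twice <- qc_filter(out$counts)
  expect_identical(twice$counts$counts, out$counts$counts)
})
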