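test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(make_profile(a = 1, b = 1, c = 1, d = 1)),
               log(4))
  expect_equal(shannon_index(make_profile(a = 5)), 0)
  expect_equal(shannon_index(make_profile(a = 0.5, b = 0.25, c = 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  # base switch: bits
  expect_equal(shannon_index(make_profile(a = 1, b = 1), base = 2), 1)
})

test_that("Shannon index is bounded by log richness, equality at uniformity", {
  set.seed(81)
  for (i in 1:20) {
    k <- sample(2:50, 1)
    f <- rgamma(k, 1)
    p <- clone_profile(stats::setNames(f, paste0("b", 1:k)))
    h <- shannon_index(p)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
})

test_that("percent barcodes detected counts set overlap", {
  tumor <- make_profile(A = 0.5, B = 0.3, C = 0.2)
  expect_equal(pct_barcodes_detected(tumor, tumor), 100)
  empty <- clone_profile(stats::setNames(numeric(0), character(0)))
  expect_equal(pct_barcodes_detected(empty, tumor), 0)
  sample <- make_profile(A = 0.7, C = 0.3)
  expect_equal(pct_barcodes_detected(sample, tumor), 100 * 2 / 3)
  expect_error(pct_barcodes_detected(sample, empty), "empty")
})

test_that("biomass captured sums tumor mass over detected barcodes", {
  tumor <- make_profile(A = 0.7, B = 0.2, C = 0.1)
  s_ac <- make_profile(A = 1, C = 1)
  expect_equal(biomass_captured(s_ac, tumor), 80)
  expect_equal(biomass_captured(tumor, tumor), 100)
  # monotone under union: combining biopsies never loses biomass
  s_b <- make_profile(B = 1)
  expect_gte(biomass_captured(list(s_ac, s_b), tumor),
             max(biomass_captured(s_ac, tumor), biomass_captured(s_b, tumor)))
  expect_equal(biomass_captured(list(s_ac, s_b), tumor), 100)
})

test_that("dominant-clone calls are strict at the 1% threshold", {
  # 100 / 10000 reads = exactly 1%: not dominant; 101 / 10000 is
  tum <- clone_profile(c(a = 100, b = 101, c = 9799))
  expect_setequal(dominant_clones(tum), c("b", "c"))
  # uniform 200-clone tumor: every clone at 0.5%, none dominant
  u <- clone_profile(stats::setNames(rep(1, 200), paste0("b", 1:200)))
  expect_length(dominant_clones(u), 0)
  expect_setequal(dominant_clones(make_profile(A = 0.98, B = 0.02)),
                  c("A", "B"))
  # dominant set is a subset of the tumor's barcodes, bounded by 1/threshold
  set.seed(82)
  for (i in 1:10) {
    k <- sample(5:300, 1)
    pr <- clone_profile(stats::setNames(rgamma(k, 0.3), paste0("b", 1:k)))
    dom <- dominant_clones(pr)
    expect_true(all(dom %in% profile_barcodes(pr)))
    expect_lte(length(dom), floor(1 / 0.01))
  }
})

test_that("center/periphery partition percentages sum to 100", {
  cen <- make_profile(A = 1, B = 1)
  per <- make_profile(A = 1, B = 1)
  expect_equal(unname(partition_center_periphery(cen, per)), c(0, 0, 100))
  cen2 <- make_profile(A = 1, B = 1, C = 1)
  per2 <- make_profile(D = 1)
  expect_equal(partition_center_periphery(cen2, per2),
               c(periphery_only = 25, center_only = 75, both = 0))
  set.seed(83)
  for (i in 1:10) {
    ids <- paste0("b", 1:30)
    c_p <- clone_profile(stats::setNames(runif(30) * rbinom(30, 1, 0.5),
                                         ids))
    p_p <- clone_profile(stats::setNames(runif(30) * rbinom(30, 1, 0.5),
                                         ids))
    if (clone_richness(c_p) + clone_richness(p_p) == 0) next
    expect_equal(sum(partition_center_periphery(c_p, list(p_p))), 100)
  }
})

test_that("sample-tumor correlation matches the covariance formula", {
  tumor <- make_profile(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  expect_equal(sample_tumor_correlation(tumor, tumor), 1)
  two <- make_profile(A = 0.7, B = 0.3)
  rev2 <- make_profile(A = 0.3, B = 0.7)
  expect_equal(sample_tumor_correlation(rev2, two), -1)
  # hand-built 4-barcode pair vs brute-force covariance computation
  s <- make_profile(A = 0.1, B = 0.2, C = 0.3, E = 0.4)
  ids <- c("A", "B", "C", "D", "E")
  x <- c(0.1, 0.2, 0.3, 0, 0.4)
  y <- c(0.4, 0.3, 0.2, 0.1, 0)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sample_tumor_correlation(s, tumor), brute)
  # degenerate profiles are flagged, not silently zero
  flat_t <- make_profile(A = 0.5, B = 0.5)
  flat_s <- make_profile(A = 0.5, B = 0.5)
  expect_warning(r <- sample_tumor_correlation(flat_s, flat_t),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("group comparisons reproduce direct test formulas", {
  # two identical groups: no difference
  gc <- group_comparison(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gc$p_value, 1)
  # extreme separation
  gc2 <- group_comparison(c(0, 0, 0, 5.001, 5.002, 5.003),
                          rep(c("lo", "hi"), each = 3))
  expect_lt(gc2$p_value, 1e-3)
  # cross-check the t test against the closed-form pooled-variance formula
  x <- c(3.1, 4.2, 2.8, 5.0); y <- c(6.3, 5.9, 7.4)
  gc3 <- group_comparison(c(x, y), rep(c("x", "y"), c(4, 3)))
  sp2 <- ((4 - 1) * var(x) + (3 - 1) * var(y)) / (4 + 3 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  p_manual <- 2 * pt(-abs(tstat), df = 5)
  expect_equal(gc3$p_value, p_manual, tolerance = 1e-6)
  # three groups: ANOVA F and Tukey match closed forms
  vals <- c(1.1, 1.9, 1.5, 3.2, 3.8, 3.4, 6.1, 6.6, 5.9)
  labs <- rep(c("a", "b", "c"), each = 3)
  gc4 <- group_comparison(vals, labs)
  expect_equal(gc4$method, "one-way ANOVA + Tukey")
  # independent oracle: F from group/residual sums of squares
  gm <- mean(vals)
  ss_b <- sum(3 * (tapply(vals, labs, mean) - gm)^2)
  ss_w <- sum((vals - rep(tapply(vals, labs, mean), each = 3))^2)
  fstat <- (ss_b / 2) / (ss_w / 6)
  expect_equal(gc4$p_value, pf(fstat, 2, 6, lower.tail = FALSE),
               tolerance = 1e-6)
  # Tukey a-b adjusted p via the studentized range distribution
  se <- sqrt((ss_w / 6) / 3)
  q_ab <- abs(diff(tapply(vals, labs, mean)[c("a", "b")])) / se
  ab_row <- gc4$pairwise$p_adj[gc4$pairwise$comparison == "b-a"]
  expect_equal(ab_row,
               unname(ptukey(q_ab, nmeans = 3, df = 6, lower.tail = FALSE)),
               tolerance = 1e-6)
  # n < 3 groups are reported not determined
  gc5 <- group_comparison(c(1, 2, 5, 6), rep(c("a", "b"), each = 2))
  expect_true(gc5$not_determined)
  expect_true(is.na(gc5$p_value))
  expect_error(group_comparison(1:3, rep("only", 3)), "two groups")
})

test_that("representativeness bundles detection, biomass and misses", {
  tumor <- make_profile(A = 0.5, B = 0.3, C = 0.15, D = 0.05)
  needle <- make_profile(A = 0.6, C = 0.4)
  rep1 <- representativeness(needle, tumor)
  expect_equal(rep1$pct_barcodes_detected, 50)
  expect_equal(rep1$pct_biomass_captured, 65)
  expect_setequal(rep1$missed_dominant, c("B", "D"))
  # adding a second biopsy can only improve coverage
  cf <- make_profile(B = 1)
  rep2 <- representativeness(list(needle, cf), tumor)
  expect_gte(rep2$pct_biomass_captured, rep1$pct_biomass_captured)
})
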