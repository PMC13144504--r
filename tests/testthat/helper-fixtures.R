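# shared fixture builders; everything is generated in code

# a sample sheet of k replicates per group
make_sheet <- function(groups, reps_per_group, sample_class = "tumor_piece",
                       tissue_location = NA_character_) {
  ids <- unlist(lapply(groups, function(g) sprintf("%s_rep%d", g,
                                                   seq_len(reps_per_group))))
  grp <- rep(groups, each = reps_per_group)
  cls <- rep(sample_class, length.out = length(groups))
  loc <- rep(tissue_location, length.out = length(groups))
  sample_sheet(ids, make_indexes(length(ids)),
               replicate_group = rep(groups, each = reps_per_group),
               sample_class = rep(cls, each = reps_per_group),
               tissue_location = rep(loc, each = reps_per_group))
}

# count_matrix from a plain matrix, with auto metadata
make_cm <- function(counts, groups = colnames(counts),
                    sample_class = "tumor_piece") {
  sheet <- sample_sheet(colnames(counts), make_indexes(ncol(counts)),
                        replicate_group = groups,
                        sample_class = rep(sample_class,
                                           length.out = ncol(counts)))
  count_matrix(counts, sheet)
}

# profile from a plain named vector
make_profile <- function(...) {
  v <- c(...)
  clone_profile(v, label = "p")
}

# two integer replicate columns with Pearson r exactly 0.6
# (phi-coefficient construction: 2x2 table a=4, b=1, c=1, d=4 gives
# phi = 15/25 = 0.6; correlation is affine-invariant)
concordant_pair_r060 <- function() {
  x <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  cbind(rep1 = 100L + 50L * x, rep2 = 100L + 50L * y)
}

# two integer replicate columns with Pearson r = 0.58999... (< 0.6)
discordant_pair_r059 <- function() {
  cbind(rep1 = c(100L, 430L, 761L, 1091L, 1421L, 1751L, 2082L, 2412L,
                 2742L, 3073L),
        rep2 = c(100L, 969L, 709L, 1733L, 759L, 2006L, 724L, 3462L,
                 2408L, 1222L))
}

# brute-force per-cell recount of a tumor state (oracle for clone_census)
recount_cells <- function(state) {
  tab <- table(factor(state$barcode))
  stats::setNames(as.integer(tab), names(tab))
}

# total variation distance between two frequency vectors over the union
tv_dist <- function(p, q) {
  ids <- union(names(p), names(q))
  pp <- stats::setNames(numeric(length(ids)), ids); pp[names(p)] <- p
  qq <- stats::setNames(numeric(length(ids)), ids); qq[names(q)] <- q
  sum(abs(pp - qq)) / 2
}
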