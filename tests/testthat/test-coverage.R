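test_that("filter_reads applies quality, uniqueness and dedup rules", {
  r <- rbind(make_reads("chr1", 100, mapq = 6),
             make_reads("chr1", 100, mapq = 7),
             make_reads("chr1", 100, mapq = 7),          # positional dup
             make_reads("chr1", 100, strand = "-"),      # other strand kept
             make_reads("chr1", 200, is_unique = FALSE))
  out <- filter_reads(r)
  expect_equal(nrow(out), 2)
  expect_equal(out$pos5, c(100L, 100L))
  expect_equal(sort(out$strand), c("+", "-"))
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["input"]), 5)
  expect_equal(unname(counts["retained"]), 2)
  expect_equal(unname(counts["duplicate_removed"]), 1)
})

test_that("filter_reads is idempotent", {
  set.seed(4)
  r <- make_reads("chr1", sample.int(1000, 300, replace = TRUE),
                  strand = sample(c("+", "-"), 300, replace = TRUE),
                  mapq = sample(0:60, 300, replace = TRUE),
                  is_unique = sample(c(TRUE, FALSE), 300, replace = TRUE))
  once <- filter_reads(r)
  twice <- filter_reads(once)
  attr(once, "filter_counts") <- attr(twice, "filter_counts") <- NULL
  expect_equal(twice, once)
})

test_that("extend_read is directional and clips at boundaries", {
  plus <- extend_read(make_reads("chr1", 100), 150)
  expect_equal(c(plus$start, plus$end), c(100L, 250L))
  minus <- extend_read(make_reads("chr1", 249, strand = "-"), 150)
  expect_equal(c(minus$start, minus$end), c(100L, 250L))
  near0 <- extend_read(make_reads("chr1", 10, strand = "-"), 150)
  expect_equal(near0$start, 0L)
  capped <- extend_read(make_reads("chr1", 990), 150,
                        chrom_sizes = c(chr1 = 1000L))
  expect_equal(capped$end, 1000L)
})

test_that("mask_te_reads drops fragments overlapping TE bodies by >= 1 bp", {
  te <- make_insertion(start = 240L, end = 5000L)
  overlapping <- make_reads("chr1", 100)   # fragment [100, 250)
  kept_read <- make_reads("chr1", 239, strand = "-")  # fragment [90, 240)
  expect_equal(nrow(mask_te_reads(overlapping, te, 150)), 0)
  expect_equal(nrow(mask_te_reads(kept_read, te, 150)), 1)
})

test_that("mask_te_reads matches a brute-force overlap check", {
  set.seed(5)
  n <- 300
  reads <- make_reads("chr1", sample.int(20000, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE))
  starts <- sort(sample.int(19000, 8))
  te <- make_insertion(copy_id = sprintf("t%d", 1:8), start = starts,
                       end = starts + sample(200:800, 8, replace = TRUE))
  got <- mask_te_reads(reads, te, 150)
  fr <- extend_read(reads, 150)
  hit <- vapply(seq_len(n), function(i)
    any(fr$start[i] < te$end & te$start < fr$end[i]), logical(1))
  expect_equal(got$pos5, reads$pos5[!hit])
})

test_that("build_coverage matches definition and conserves fragment mass", {
  sizes <- c(chr1 = 1000L)
  one <- build_coverage(make_reads("chr1", 100), 150, sizes)
  v <- track_values(one, "chr1", 0, 1000)
  expect_equal(sum(v == 1), 150)
  expect_equal(which(v == 1), 101:250)

  two <- build_coverage(make_reads("chr1", c(100, 249),
                                   strand = c("+", "-")), 150, sizes)
  expect_equal(track_values(two, "chr1", 100, 250), rep(2, 150))

  expect_error(build_coverage(make_reads("chrX", 1), 150, sizes),
               "unknown chromosome")
})

test_that("build_coverage equals brute-force accumulation on random reads", {
  set.seed(6)
  n <- 200
  reads <- make_reads("chr1", sample.int(5000, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE))
  tr <- build_coverage(reads, 150, c(chr1 = 5200L))
  got <- track_values(tr, "chr1", 0, 5200)
  want <- brute_coverage(reads, 150, 5200L)
  expect_equal(got, want)
  # conservation: total coverage = summed clipped fragment lengths
  fr <- extend_read(reads, 150, c(chr1 = 5200L))
  expect_equal(sum(got), sum(fr$end - fr$start))
})

test_that("extract_flank_profile orients flanks away from the element", {
  sizes <- c(chr1 = 40000L)
  te <- make_insertion(start = 10000L, end = 15000L, strand = "+")
  # single covered base immediately 5' of a + strand element
  tr <- signal_track(list(chr1 = replace(numeric(40000), 10000, 1)),
                     sizes)
  pr <- extract_flank_profile(tr, te, flank_len = 5000)
  expect_equal(pr$five_prime$values[1], 1)
  expect_equal(sum(pr$five_prime$values), 1)
  expect_equal(sum(pr$three_prime$values), 0)
  expect_false(pr$five_prime$truncated)

  # mirror-image track around a - strand element gives identical arrays
  te_m <- make_insertion(start = 10000L, end = 15000L, strand = "-")
  tr_m <- signal_track(list(chr1 = replace(numeric(40000), 15001, 1)),
                       sizes)
  pr_m <- extract_flank_profile(tr_m, te_m, flank_len = 5000)
  expect_equal(pr_m$five_prime$values, pr$five_prime$values)
  expect_equal(pr_m$three_prime$values, pr$three_prime$values)
})

test_that("truncated flanks are zero-padded and flagged", {
  te <- make_insertion(start = 2000L, end = 7000L)
  tr <- signal_track(list(chr1 = rep(1, 20000)), c(chr1 = 20000L))
  pr <- extract_flank_profile(tr, te, flank_len = 5000)
  expect_true(pr$five_prime$truncated)
  expect_equal(pr$five_prime$values, c(rep(1, 2000), rep(0, 3000)))
  expect_false(pr$three_prime$truncated)
})

test_that("aggregate_profiles normalizes by copy count and library scale", {
  set.seed(7)
  profs <- lapply(1:10, function(i)
    make_profile(runif(100), copy_id = sprintf("c%d", i)))
  mp <- aggregate_profiles(profs)
  # direct recomputation oracle
  want <- Reduce(`+`, lapply(profs, `[[`, "values")) / 10
  expect_equal(mp$values, want)
  # duplicating every profile leaves the metaprofile unchanged
  mp2 <- aggregate_profiles(c(profs, profs))
  expect_equal(mp2$values, mp$values)
  # doubling this line's library halves values via lib_scale
  mp_half <- aggregate_profiles(profs, lib_scale = 0.5)
  expect_equal(mp_half$values, mp$values / 2)
  # permutation invariance
  mp_perm <- aggregate_profiles(profs[sample(10)])
  expect_equal(mp_perm$values, mp$values)
  # mixed sides refuse
  bad <- c(profs, list(make_profile(runif(100), side = "three_prime")))
  expect_error(aggregate_profiles(bad), "sides")
})
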