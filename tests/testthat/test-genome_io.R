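te_tsv <- function(rows, header = "copy_id\tchrom\tstart\tend\tstrand\tfamily\tTT2\tJ1") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

test_that("read_te_table converts coordinates and derives status", {
  path <- te_tsv(c(
    "ins8852\t14\t72200881\t72203815\t+\tIAP\t+/+\t−/−",
    "c2\tchr1\t101\t601\t-\tIAP\t+/+\t+/+",
    "c3\tchr1\t5001\t5320\t+\tIAP\t+/-\t-/-"))
  te <- read_te_table(path)
  expect_s3_class(te, "te_table")
  # published 1-based inclusive -> 0-based half-open
  expect_equal(te$start[1], 72200880)
  expect_equal(te$end[1], 72203815)
  expect_equal(te$status, c("polymorphic", "common", "polymorphic"))
  expect_equal(te$present_in, c("TT2", "TT2,J1", "TT2"))
  expect_equal(te$length_bp[1], 72203815 - 72200880)
  # heterozygous +/- counts as present
  expect_true(grepl("TT2", te$present_in[3]))
})

test_that("read_te_table errors name the offending row", {
  path <- te_tsv(c("c1\tchr1\t100\t200\t+\tIAP\t+/+\t-/-",
                   "c2\tchr1\tNA\t300\t+\tIAP\t+/+\t-/-"))
  expect_error(read_te_table(path), "row 2")
  path2 <- te_tsv("c1\tchr1\t100\t200\t+\tIAP\t+/+\t?/?")
  expect_error(read_te_table(path2), "presence code")
})

test_that("te table round-trips through write_te_table", {
  path <- te_tsv(c("c1\tchr1\t101\t601\t+\tIAP\t+/+\t-/-",
                   "c2\tchr2\t1001\t5001\t-\tETn\t+/+\t+/+"))
  te <- read_te_table(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_te_table(te, out, c("TT2", "J1"))
  te2 <- read_te_table(out)
  expect_equal(te2, te)
})

test_that("classify_copy follows the length rules and is total", {
  expect_equal(classify_copy(4000), "full_length")   # boundary inclusive
  expect_equal(classify_copy(320), "solo_LTR")
  expect_equal(classify_copy(1000), "other")
  expect_equal(classify_copy(c(384, 385)), c("solo_LTR", "other"))  # +20%
  expect_equal(classify_copy(c(256, 255)), c("solo_LTR", "other"))  # -20%
  set.seed(1)
  lens <- sample.int(10000, 500)
  cls <- classify_copy(lens)
  expect_true(all(cls %in% c("full_length", "solo_LTR", "other")))
  expect_length(cls, 500)
})

test_that("filter_full_length keeps >= min_len, order preserved", {
  te <- make_insertion(copy_id = c("a", "b", "c"), start = 0,
                       end = c(3999, 4000, 5000))
  kept <- filter_full_length(te)
  expect_equal(kept$copy_id, c("b", "c"))
  expect_equal(nrow(filter_full_length(te[0, ])), 0)
  # brute-force oracle on random lengths
  set.seed(2)
  lens <- sample.int(8000, 100)
  te2 <- make_insertion(copy_id = sprintf("r%03d", 1:100), start = 0,
                        end = lens)
  expect_equal(filter_full_length(te2)$copy_id, te2$copy_id[lens >= 4000])
})

test_that("read_reads parses the bed6q dialect strand-correctly", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr1\t37\t+",
               "chr1\t100\t136\tr2\t37\t-",
               "chr1\t500\t536\tr3\t5\t+\t0"), path)
  r <- read_reads(path, "bed6q")
  expect_equal(r$pos5, c(100L, 135L, 500L))
  expect_equal(r$read_len, c(36L, 36L, 36L))
  expect_equal(r$mapq, c(37L, 37L, 5L))
  expect_equal(r$is_unique, c(TRUE, TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t-5\t30\tr1\t37\t+", bad)
  expect_error(read_reads(bad, "bed6q"), "coordinates")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5\t30\tr1\t37\t.", bad2)
  expect_error(read_reads(bad2, "bed6q"), "strand")
})

test_that("reads round-trip through write_reads", {
  r <- make_reads("chr2", c(10L, 250L, 77L), strand = c("+", "-", "+"),
                  mapq = c(37L, 7L, 6L), is_unique = c(TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".bed")
  write_reads(r, path)
  expect_equal(read_reads(path, "bed6q"), r)
})

test_that("read_reads handles a minimal SAM subset", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste("q1", 0, "chr1", 101, 37, "36M", "*", 0, 0,
                     strrep("A", 36), "*", sep = "\t"),
               paste("q2", 16, "chr1", 101, 37, "36M", "*", 0, 0,
                     strrep("A", 36), "*", sep = "\t"),
               paste("q3", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*",
                     sep = "\t")), path)
  r <- read_reads(path, "sam_min")
  expect_equal(nrow(r), 2)              # unmapped dropped
  expect_equal(r$pos5, c(100L, 135L))   # minus strand anchored at 3' end
  expect_equal(r$strand, c("+", "-"))
})

test_that("signal tracks parse bedGraph and fixedStep wiggle", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t1.0", bg)
  tr <- read_signal_track(bg)
  expect_equal(track_values(tr, "chr1", 0, 10), rep(1, 10))

  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1 span=1",
               "1", "2", "3", "4", "5"), wig)
  tw <- read_signal_track(wig)
  expect_equal(track_values(tw, "chr1", 0, 5), 1:5)

  overlapping <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t1.0", "chr1\t5\t15\t2.0"), overlapping)
  expect_error(read_signal_track(overlapping), "overlapping")
})

test_that("signal track write/read round trip is bitwise lossless", {
  set.seed(3)
  vals <- runif(3)
  tr <- signal_track(list(chr1 = S4Vectors::Rle(vals, c(7, 11, 13))))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_signal_track(tr, path)
  tr2 <- read_signal_track(path)
  expect_identical(track_values(tr2, "chr1", 0, 31),
                   track_values(tr, "chr1", 0, 31))
})

test_that("read_genes parses BED6 and minimal GTF with TSS per strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tgA\t0\t+", "chr1\t900\t1400\tgB\t0\t-"), bed)
  g <- read_genes(bed, "bed6")
  expect_equal(g$tss, c(100L, 1399L))
  expect_equal(g$length_bp, c(500L, 500L))

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", 101, 600, ".", "+", ".",
                   'gene_id "gA"; gene_name "A";', sep = "\t"), gtf)
  g2 <- read_genes(gtf, "gtf")
  expect_equal(g2$gene_id, "gA")
  expect_equal(g2$start, 100L)
  expect_equal(g2$tss, 100L)
})
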