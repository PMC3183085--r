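# small deterministic builders shared across test files

make_reads <- function(chrom, pos5, strand = "+", mapq = 37L,
                       is_unique = TRUE, read_len = 36L) {
  n <- max(length(chrom), length(pos5), length(strand))
  data.frame(chrom = rep_len(chrom, n), pos5 = as.integer(rep_len(pos5, n)),
             read_len = as.integer(rep_len(read_len, n)),
             strand = rep_len(strand, n),
             mapq = as.integer(rep_len(mapq, n)),
             is_unique = rep_len(is_unique, n), stringsAsFactors = FALSE)
}

make_insertion <- function(copy_id = "c1", chrom = "chr1", start = 10000L,
                           end = 15000L, strand = "+",
                           status = "polymorphic", family = "IAP",
                           present_in = "lineA") {
  df <- data.frame(copy_id = copy_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, family = family, status = status,
                   present_in = present_in, stringsAsFactors = FALSE)
  df$length_bp <- df$end - df$start
  df$copy_class <- classify_copy(df$length_bp)
  class(df) <- c("te_table", "data.frame")
  df
}

make_profile <- function(values, copy_id = "c1", side = "five_prime") {
  structure(list(copy_id = copy_id, side = side,
                 values = as.numeric(values), truncated = FALSE),
            class = "flank_profile")
}

# uniform reads spanning [from, to) on + strand, one per `by` bp
dense_reads <- function(chrom, from, to, by = 1L) {
  make_reads(chrom, seq.int(from, to - 1L, by = by))
}

# brute-force per-base coverage oracle, independent of IRanges
brute_coverage <- function(reads, fragment_len, chrom_len, chrom = "chr1") {
  v <- numeric(chrom_len)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    if (reads$strand[i] == "+") {
      s <- reads$pos5[i]; e <- reads$pos5[i] + fragment_len
    } else {
      s <- reads$pos5[i] - fragment_len + 1L; e <- reads$pos5[i] + 1L
    }
    s <- max(s, 0L); e <- min(e, chrom_len)
    if (e > s) v[(s + 1):e] <- v[(s + 1):e] + 1
  }
  v
}
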