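#' Filter aligned reads by mapping quality, uniqueness, and duplication
#'
#' Keeps reads with `mapq >= min_mapq` that align uniquely, then collapses
#' duplicates: reads identical in `(chrom, pos5, strand)` are counted once
#' (first occurrence kept).  Idempotent.
#'
#' @param reads read data.frame (see [read_reads()]).
#' @param min_mapq minimum mapping quality (inclusive), default 7.
#' @param unique_only drop multi-mapping reads, default TRUE.
#' @param dedup collapse positional duplicates, default TRUE.
#' @return filtered data.frame; attribute `filter_counts` holds the number
#'   of input, quality-removed, duplicate-removed and retained reads.
#' @export
filter_reads <- function(reads, min_mapq = 7, unique_only = TRUE,
                         dedup = TRUE) {
  n_in <- nrow(reads)
  keep <- reads$mapq >= min_mapq
  if (unique_only) keep <- keep & reads$is_unique
  out <- reads[keep, , drop = FALSE]
  n_qual <- n_in - nrow(out)
  n_dup <- 0L
  if (dedup && nrow(out) > 0) {
    dup <- duplicated(paste(out$chrom, out$pos5, out$strand))
    n_dup <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(input = n_in, quality_removed = n_qual,
                                  duplicate_removed = n_dup,
                                  retained = nrow(out))
  out
}

#' Directionally extend reads into fragment intervals
#'
#' Each read is extended from its 5' end to a total fragment length
#' (mono-nucleosome native ChIP: 150 bp default; use ~200 bp for MeDIP).
#' `+` strand: `[pos5, pos5 + fragment_len)`; `-` strand:
#' `[pos5 - fragment_len + 1, pos5 + 1)`.  Fragments are silently clipped
#' to `[0, chrom_size)`.
#'
#' @param reads read data.frame.
#' @param fragment_len total fragment length in bp.
#' @param chrom_sizes optional named integer vector for right clipping.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   one row per read.
#' @export
extend_read <- function(reads, fragment_len = 150, chrom_sizes = NULL) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  reads$pos5 - fragment_len + 1L)
  end <- start + fragment_len
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    size <- chrom_sizes[reads$chrom]
    end <- ifelse(is.na(size), end, pmin(end, size))
  }
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

.fragments_granges <- function(reads, fragment_len, chrom_sizes = NULL) {
  fr <- extend_read(reads, fragment_len, chrom_sizes)
  GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))  # to 1-based for GRanges
}

#' Remove reads whose extended fragment overlaps a TE body
#'
#' A read is dropped when its extended fragment overlaps any element body
#' interval by at least 1 bp, so element-internal signal cannot leak into
#' flank statistics.
#'
#' @param reads read data.frame.
#' @param te_intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. a `te_table`.
#' @param fragment_len fragment length used for extension.
#' @param chrom_sizes optional clipping bounds.
#' @return the retained reads.
#' @export
mask_te_reads <- function(reads, te_intervals, fragment_len = 150,
                          chrom_sizes = NULL) {
  if (nrow(reads) == 0 || nrow(te_intervals) == 0) return(reads)
  frags <- .fragments_granges(reads, fragment_len, chrom_sizes)
  tes <- GRanges(te_intervals$chrom,
                 IRanges(te_intervals$start + 1L, te_intervals$end))
  hit <- IRanges::overlapsAny(frags, tes, minoverlap = 1L)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a fragment-coverage track
#'
#' The value at base b is the number of extended fragments covering b.
#' Conservation: the track total equals the summed (clipped) fragment
#' lengths.
#'
#' @param reads filtered read data.frame.
#' @param fragment_len total fragment length in bp.
#' @param chrom_sizes named integer vector of chromosome lengths; every
#'   read chromosome must be present.
#' @return a [signal_track()].
#' @export
build_coverage <- function(reads, fragment_len = 150, chrom_sizes) {
  .assert(!is.null(names(chrom_sizes)), "chrom_sizes must be named")
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  .assert(length(unknown) == 0, "reads on unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  fr <- extend_read(reads, fragment_len, chrom_sizes)
  vals <- lapply(names(chrom_sizes), function(chrom) {
    i <- fr$chrom == chrom
    coverage(IRanges(fr$start[i] + 1L, fr$end[i]),
             width = chrom_sizes[[chrom]])
  })
  names(vals) <- names(chrom_sizes)
  signal_track(vals, chrom_sizes = chrom_sizes)
}

#' Extract strand-aware 5' and 3' flank profiles for one element
#'
#' Profiles are oriented: index 1 is the base adjacent to the element
#' edge, increasing away from the element.  For a `+` strand element the
#' 5' flank is genomic `[start - flank_len, start)` read right-to-left and
#' the 3' flank `[end, end + flank_len)` left-to-right; for `-` strand
#' elements the genomic sides swap.  Flanks running off the chromosome
#' are zero-padded and flagged `truncated`.
#'
#' @param track coverage [signal_track()].
#' @param insertion single-row `te_table` (or list with `copy_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param flank_len flank length in bp, default 5000.
#' @return list with elements `five_prime` and `three_prime`, each of class
#'   `flank_profile` (fields `copy_id`, `side`, `values`, `truncated`).
#' @export
extract_flank_profile <- function(track, insertion, flank_len = 5000) {
  chrom <- as.character(insertion$chrom)
  start <- as.integer(insertion$start); end <- as.integer(insertion$end)
  strand <- as.character(insertion$strand)
  size <- track$chrom_sizes[[chrom]] %||% length(track$values[[chrom]])
  .assert(!is.null(size) && start >= 0 && end <= size,
          "insertion %s outside chromosome", insertion$copy_id)

  left <- track_values(track, chrom, start - flank_len, start)  # genomic order
  right <- track_values(track, chrom, end, end + flank_len)
  left_trunc <- (start - flank_len) < 0
  right_trunc <- (end + flank_len) > size

  upstream <- list(values = rev(left), truncated = left_trunc)    # away from 5' edge
  downstream <- list(values = right, truncated = right_trunc)
  if (identical(strand, "-")) {
    upstream <- list(values = right, truncated = right_trunc)
    downstream <- list(values = rev(left), truncated = left_trunc)
  }
  mk <- function(side, x) structure(
    list(copy_id = as.character(insertion$copy_id), side = side,
         values = x$values, truncated = x$truncated),
    class = "flank_profile")
  list(five_prime = mk("five_prime", upstream),
       three_prime = mk("three_prime", downstream))
}

#' Aggregate per-copy flank profiles into a family metaprofile
#'
#' The metaprofile is the per-base sum over copies, normalized by
#' (1) the number of copies and (2) relative library size:
#' `values = (sum of profiles) / n_copies * lib_scale` with
#' `lib_scale = N_reference_line / N_this_line` (1 for the reference line).
#'
#' @param profiles list of `flank_profile`s, all same side and length.
#' @param n_copies number of copies (defaults to `length(profiles)`).
#' @param lib_scale relative library-size factor.
#' @param family family label carried into the result.
#' @return object of class `meta_profile` (fields `family`, `side`,
#'   `values`, `n_copies`, `lib_scale`).
#' @export
aggregate_profiles <- function(profiles, n_copies = length(profiles),
                               lib_scale = 1, family = "TE") {
  .assert(length(profiles) >= 1, "no profiles")
  sides <- unique(vapply(profiles, function(p) p$side, character(1)))
  lens <- unique(vapply(profiles, function(p) length(p$values), integer(1)))
  .assert(length(sides) == 1 && length(lens) == 1,
          "profiles mix sides or lengths")
  total <- Reduce(`+`, lapply(profiles, function(p) p$values))
  structure(list(family = family, side = sides, values = total / n_copies *
                   lib_scale, n_copies = n_copies, lib_scale = lib_scale),
            class = "meta_profile")
}

#' Write a metaprofile as TSV (offset_bp, density)
#'
#' @param profile a `meta_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_profile <- function(profile, path) {
  write.table(data.frame(offset_bp = seq_along(profile$values) - 1L,
                         density = profile$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
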