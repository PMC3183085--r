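#' @section Coordinate conventions:
#' Internal coordinates are 0-based half-open throughout (BED native).
#' TE tables follow the published convention of 1-based inclusive
#' coordinates and are converted on read.
#' @name teflank-coordinates
#' @keywords internal
NULL

.normalize_presence <- function(x) {
  # published tables use a unicode minus sign
  gsub("−", "-", trimws(x))
}

.known_te_cols <- c("copy_id", "chrom", "start", "end", "strand", "family")

#' Read a TE insertion table
#'
#' Expects a TSV with header columns `copy_id`, `chrom`, `start`, `end`
#' (1-based inclusive, converted to 0-based half-open), optional `strand`
#' and `family`, plus one presence column per cell line with codes like
#' `+/+`, `+/-`, `-/-` (heterozygous presence counts as present).  An
#' insertion present in every line is `common`, otherwise `polymorphic`.
#'
#' @param path TSV file.
#' @param presence_columns character vector naming the per-line presence
#'   columns; `NULL` (default) uses every column not among
#'   `copy_id/chrom/start/end/strand/family`.
#' @return data.frame of class `te_table` with columns `copy_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `family`, `status`,
#'   `present_in` (comma-joined line labels), `length_bp`, `copy_class`.
#' @export
read_te_table <- function(path, presence_columns = NULL) {
  .assert(file.exists(path), "no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .assert(all(c("chrom", "start", "end") %in% names(df)),
          "TE table must have chrom/start/end columns")
  presence_columns <- presence_columns %||%
    setdiff(names(df), .known_te_cols)
  .assert(length(presence_columns) >= 1, "no presence columns found")
  .assert(all(presence_columns %in% names(df)),
          "missing presence columns: %s",
          paste(setdiff(presence_columns, names(df)), collapse = ", "))

  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  for (i in seq_len(nrow(df))) {
    if (is.na(start[i]) || is.na(end[i]) || start[i] < 1 || end[i] < start[i])
      stop(sprintf("malformed TE table row %d in %s: start=%s end=%s",
                   i, path, df$start[i], df$end[i]), call. = FALSE)
    for (col in presence_columns) {
      code <- .normalize_presence(df[[col]][i])
      if (!code %in% c("+/+", "+/-", "-/+", "-/-", "+", "-"))
        stop(sprintf("unknown presence code '%s' (row %d, column %s)",
                     df[[col]][i], i, col), call. = FALSE)
    }
  }

  present <- sapply(presence_columns, function(col)
    grepl("\\+", .normalize_presence(df[[col]])))
  present <- matrix(present, nrow = nrow(df),
                    dimnames = list(NULL, presence_columns))
  present_in <- apply(present, 1, function(p)
    paste(presence_columns[p], collapse = ","))
  status <- ifelse(rowSums(present) == length(presence_columns),
                   "common", "polymorphic")

  out <- data.frame(
    copy_id = as.character(df$copy_id %||% sprintf("copy%04d", seq_len(nrow(df)))),
    chrom = as.character(df$chrom),
    start = as.integer(start - 1L),   # to 0-based half-open
    end = as.integer(end),
    strand = as.character(df$strand %||% "+"),
    family = as.character(df$family %||% "TE"),
    status = status,
    present_in = present_in,
    stringsAsFactors = FALSE
  )
  out$length_bp <- out$end - out$start
  out$copy_class <- classify_copy(out$length_bp)
  class(out) <- c("te_table", "data.frame")
  out
}

#' Classify a TE copy by length
#'
#' Full-length copies are at least `full_len_min` bp; solo LTRs are within
#' `solo_tol` of the typical solo-LTR length; anything else is `other`.
#' Full-length takes precedence.
#'
#' @param length_bp integer vector of element lengths.
#' @param full_len_min minimum full-length size (bp), default 4000.
#' @param solo_ltr_len typical solo-LTR size (bp), default 320.
#' @param solo_tol relative tolerance around `solo_ltr_len`, default 0.20.
#' @return character vector in `full_length`, `solo_LTR`, `other`.
#' @export
classify_copy <- function(length_bp, full_len_min = 4000,
                          solo_ltr_len = 320, solo_tol = 0.20) {
  .assert(all(length_bp >= 0), "negative length")
  ifelse(length_bp >= full_len_min, "full_length",
         ifelse(abs(length_bp - solo_ltr_len) <= solo_tol * solo_ltr_len,
                "solo_LTR", "other"))
}

#' Keep only full-length elements
#'
#' @param insertions a `te_table` data.frame.
#' @param min_len minimum total element length in bp (inclusive).
#' @return the subset, input order preserved.
#' @export
filter_full_length <- function(insertions, min_len = 4000) {
  insertions[insertions$length_bp >= min_len, , drop = FALSE]
}

#' Read aligned reads (BED6+mapq dialect or minimal SAM)
#'
#' In the `bed6q` dialect the BED score column holds the mapping quality
#' and an optional 7th column (0/1) flags unique alignment (default 1).
#' Reads are carried as 5'-anchored records: for `-` strand reads
#' `pos5 = end - 1`.
#'
#' @param path input file.
#' @param dialect `"bed6q"` or `"sam_min"`.
#' @return data.frame with columns `chrom`, `pos5`, `read_len`, `strand`,
#'   `mapq`, `is_unique`.
#' @export
read_reads <- function(path, dialect = c("bed6q", "sam_min")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "no such file: %s", path)
  if (dialect == "bed6q") .read_reads_bed6q(path) else .read_reads_sam(path)
}

.read_reads_bed6q <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 6, "bed6q needs >= 6 columns")
  .assert(all(df[[2]] >= 0) && all(df[[3]] > df[[2]]),
          "negative or inverted coordinates in %s", path)
  .assert(all(df[[6]] %in% c("+", "-")), "missing/invalid strand in %s", path)
  is_unique <- if (ncol(df) >= 7) is.na(df[[7]]) | df[[7]] != 0 else TRUE
  data.frame(
    chrom = as.character(df[[1]]),
    pos5 = as.integer(ifelse(df[[6]] == "+", df[[2]], df[[3]] - 1L)),
    read_len = as.integer(df[[3]] - df[[2]]),
    strand = df[[6]],
    mapq = as.integer(df[[5]]),
    is_unique = as.logical(is_unique),
    stringsAsFactors = FALSE
  )
}

.cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    lens <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", lens))
    op <- sub("[0-9]+", "", lens)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

.read_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos5 = integer(),
                      read_len = integer(), strand = character(),
                      mapq = integer(), is_unique = logical()))
  f <- strsplit(lines, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L          # drop unmapped
  f <- f[keep]; flag <- flag[keep]
  pos0 <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  .assert(all(pos0 >= 0), "negative coordinates in %s", path)
  cigar <- vapply(f, function(x) x[6], character(1))
  seqlen <- vapply(f, function(x) nchar(x[10]), integer(1))
  rlen <- .cigar_ref_len(cigar)
  rlen[is.na(rlen)] <- seqlen[is.na(rlen)]
  .assert(all(rlen > 0), "zero-length read in %s", path)
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  data.frame(
    chrom = vapply(f, function(x) x[3], character(1)),
    pos5 = as.integer(ifelse(strand == "+", pos0, pos0 + rlen - 1L)),
    read_len = as.integer(rlen),
    strand = strand,
    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
    is_unique = bitwAnd(flag, 256L) == 0L,
    stringsAsFactors = FALSE
  )
}

#' Write aligned reads in the BED6+mapq dialect
#'
#' Inverse of [read_reads()] with `dialect = "bed6q"`.
#'
#' @param reads read data.frame (see [read_reads()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  reads$pos5 - reads$read_len + 1L)
  end <- start + reads$read_len
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d",
                   reads$chrom, start, end,
                   sprintf("r%d", seq_len(nrow(reads))),
                   reads$mapq, reads$strand, as.integer(reads$is_unique))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models (BED6 or minimal GTF)
#'
#' @param path input file.
#' @param format `"bed6"` or `"gtf"` (only `gene` features are used; the
#'   `gene_id` attribute is required).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss` (0-based position of the transcription
#'   start site), `length_bp`.
#' @export
read_genes <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  .assert(file.exists(path), "no such file: %s", path)
  if (format == "bed6") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    .assert(ncol(df) >= 6, "gene BED needs >= 6 columns")
    out <- data.frame(gene_id = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                      strand = df[[6]], stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t")
    f <- f[vapply(f, function(x) x[3] == "gene", logical(1))]
    .assert(length(f) > 0, "no gene features in %s", path)
    gid <- vapply(f, function(x) {
      m <- regmatches(x[9], regexec('gene_id[ =]+"?([^";]+)"?', x[9]))[[1]]
      .assert(length(m) == 2, "missing gene_id in GTF attributes: %s", x[9])
      m[2]
    }, character(1))
    out <- data.frame(gene_id = gid,
                      chrom = vapply(f, function(x) x[1], character(1)),
                      start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
                      end = vapply(f, function(x) as.integer(x[5]), integer(1)),
                      strand = vapply(f, function(x) x[7], character(1)),
                      stringsAsFactors = FALSE)
  }
  .assert(all(out$strand %in% c("+", "-")), "genes need +/- strand")
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out$length_bp <- out$end - out$start
  out
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chrom, size), no header.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Write a TE insertion table (inverse of [read_te_table()])
#'
#' Coordinates are written back out 1-based inclusive; presence columns are
#' reconstructed from `present_in`.
#'
#' @param insertions `te_table` data.frame.
#' @param path output TSV.
#' @param line_labels labels of the lines under comparison (presence
#'   columns to emit).
#' @return `path`, invisibly.
#' @export
write_te_table <- function(insertions, path, line_labels) {
  df <- data.frame(copy_id = insertions$copy_id, chrom = insertions$chrom,
                   start = insertions$start + 1L, end = insertions$end,
                   strand = insertions$strand, family = insertions$family,
                   stringsAsFactors = FALSE, check.names = FALSE)
  pres <- strsplit(insertions$present_in, ",", fixed = TRUE)
  for (lab in line_labels)
    df[[lab]] <- ifelse(vapply(pres, function(p) lab %in% p, logical(1)),
                        "+/+", "-/-")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
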