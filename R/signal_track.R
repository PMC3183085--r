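#' Per-base signal track
#'
#' A `signal_track` stores one run-length-encoded numeric vector per
#' chromosome (fragment coverage, mappability fraction in \[0,1\], or
#' normalized density), 0-based.  Bases beyond the stored runs are
#' implicitly 0.
#'
#' @param values named list (or `RleList`) of per-chromosome [S4Vectors::Rle]
#'   (or plain numeric vectors, converted).
#' @param chrom_sizes optional named integer vector; runs are padded with
#'   zeros (or truncated) to these lengths.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, chrom_sizes = NULL) {
  .assert(length(values) > 0 && !is.null(names(values)),
          "signal_track: 'values' must be a named list of per-chromosome runs")
  vals <- lapply(values, function(v) {
    v <- if (methods::is(v, "Rle")) v else Rle(as.numeric(v))
    .assert(all(runValue(v) >= 0 | is.na(runValue(v))),
            "signal_track: values must be >= 0")
    v
  })
  if (!is.null(chrom_sizes)) {
    .assert(!is.null(names(chrom_sizes)), "chrom_sizes must be named")
    for (chrom in names(vals)) {
      size <- chrom_sizes[[chrom]]
      if (is.null(size) || is.na(size)) next
      n <- length(vals[[chrom]])
      if (n < size) vals[[chrom]] <- c(vals[[chrom]], Rle(0, size - n))
      if (n > size) vals[[chrom]] <- vals[[chrom]][seq_len(size)]
    }
  } else {
    chrom_sizes <- vapply(vals, length, integer(1))
  }
  structure(list(values = vals, chrom_sizes = chrom_sizes),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosome(s)\n")
  for (chrom in names(x$values))
    cat(sprintf("  %s: %d bp, mean %.4g\n", chrom, length(x$values[[chrom]]),
                mean(x$values[[chrom]])))
  invisible(x)
}

#' Extract per-base values over a region (zero-padded outside the track)
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region.
#' @return numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  .assert(inherits(track, "signal_track"), "not a signal_track")
  .assert(end > start, "empty or inverted region [%d, %d)", start, end)
  out <- numeric(end - start)
  v <- track$values[[chrom]]
  if (is.null(v)) return(out)
  lo <- max(start, 0L)
  hi <- min(end, length(v))
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <-
      as.numeric(v[(lo + 1L):hi])
  out
}

.detect_track_format <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("empty track file: ", path, call. = FALSE)
    if (grepl("^(#|track)", line) || !nzchar(trimws(line))) next
    if (grepl("^(fixedStep|variableStep)", line)) return("wig")
    return("bedGraph")
  }
}

#' Read a bedGraph or fixedStep wiggle file into a signal track
#'
#' Parsing is delegated to [rtracklayer::import]; intervals are converted
#' to 0-based half-open internally.  Overlapping bedGraph intervals are an
#' error (the per-base value would be ambiguous).
#'
#' @param path bedGraph or wiggle file.
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return a [signal_track()].
#' @export
read_signal_track <- function(path, chrom_sizes = NULL) {
  .assert(file.exists(path), "no such file: %s", path)
  fmt <- .detect_track_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) > 1) {
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    .assert(length(hits) == 0,
            "overlapping intervals in %s (first at %s:%d)", path,
            as.character(seqnames(gr)[queryHits(hits)[1]]),
            start(gr)[queryHits(hits)[1]] - 1L)
  }
  cov <- coverage(gr, weight = gr$score)
  vals <- as.list(cov)
  signal_track(vals, chrom_sizes = chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' Every run is written, including zero runs, with `%.17g` formatting so
#' that step-constant tracks round-trip bitwise through
#' [read_signal_track()].
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  .assert(inherits(track, "signal_track"), "not a signal_track")
  lines <- character(0)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    ends <- cumsum(runLength(v))
    starts <- ends - runLength(v)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.17g", chrom, starts, ends,
                              runValue(v)))
  }
  writeLines(lines, path)
  invisible(path)
}
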