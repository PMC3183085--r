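#' Configuration for the two-line synthetic cohort generator
#'
#' The generator emulates the statistical structure of a full-site vs
#' empty-site comparison: two cell lines aligned to the same
#' (insertion-carrying) reference, sharing `common` insertions and
#' differing at `polymorphic` ones; Poisson read background; TE-body
#' enrichment; flank enrichment decaying with distance according to a
#' step or exponential kernel; mappability holes inside element bodies;
#' and a gene expression model where selected promoter-proximal
#' insertions silence the full-site line's gene.
#'
#' The default genome (4 x 20 Mb) is deliberately large relative to the
#' number of copies so that TE-derived reads stay a small fraction of the
#' library, as in real data — otherwise library-size normalization alone
#' shifts distal-window asymmetries.
#'
#' @param seed RNG seed (fixed seed gives byte-identical cohorts).
#' @param n_chroms,chrom_len_bp genome shape.
#' @param n_common_copies,n_polymorphic_copies copy counts; common copies
#'   are present in both lines, polymorphic ones only in line A (the
#'   full-site line).
#' @param te_len_bp element length (bp).
#' @param background_rate expected fragments per bp per library.
#' @param te_fold coverage fold inside present element bodies.
#' @param flank_fold initial enrichment fold at the element edge.
#' @param spreading_len_bp spreading extent S: step kernel is enriched for
#'   S bp then drops to background.
#' @param kernel `"step"` or `"exponential"` (scale `kernel_tau`).
#' @param kernel_tau exponential decay length (bp).
#' @param lib_size_a,lib_size_b target expected library sizes; the line's
#'   whole rate landscape is rescaled so its expected total matches.
#'   `NULL` draws raw Poisson strata at the stated rates (the per-stratum
#'   moment identities then hold exactly).
#' @param read_len,fragment_len read and fragment lengths (bp).
#' @param mappability_hole_frac fraction of each element body (central
#'   block) that is non-uniquely mappable; reads starting there are
#'   flagged `is_unique = FALSE`.
#' @param flank_len flank length reserved around copies and used by
#'   downstream profile analyses.
#' @param n_genes,gene_len_bp background gene count and length.
#' @param expr_mean expected RNA-seq counts per gene per line.
#' @param planted_impact_genes list of `list(tss_distance =, silencing_fold =)`
#'   entries; each is attached downstream of one polymorphic copy and
#'   silenced in line A by `silencing_fold`.
#' @param line_labels labels for lines A (full-site) and B (empty-site).
#' @param family family label for the simulated elements.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 4, chrom_len_bp = 2e7,
                       n_common_copies = 100, n_polymorphic_copies = 100,
                       te_len_bp = 5000, background_rate = 0.01,
                       te_fold = 10, flank_fold = 4,
                       spreading_len_bp = 1000,
                       kernel = c("step", "exponential"), kernel_tau = 500,
                       lib_size_a = NULL, lib_size_b = NULL,
                       read_len = 36, fragment_len = 150,
                       mappability_hole_frac = 0.5, flank_len = 5000,
                       n_genes = 20, gene_len_bp = 2000, expr_mean = 500,
                       planted_impact_genes = list(),
                       line_labels = c("lineA", "lineB"), family = "IAP") {
  kernel <- match.arg(kernel)
  cfg <- as.list(environment())
  .assert(background_rate > 0 && te_fold > 0 && flank_fold > 0,
          "rates and folds must be > 0")
  .assert(spreading_len_bp >= 0 && spreading_len_bp <= flank_len,
          "spreading_len_bp must be in [0, flank_len]")
  .assert(mappability_hole_frac >= 0 && mappability_hole_frac <= 1,
          "mappability_hole_frac must be in [0,1]")
  .assert(length(line_labels) == 2, "exactly two line labels")
  structure(cfg, class = "sim_config")
}

# non-overlapping placement with a margin; rejection-sampled, erroring
# after 1000 attempts per element as a clear failure mode for over-full
# genomes
.place_intervals <- function(n, len, margin, chrom_sizes, occupied) {
  chroms <- names(chrom_sizes)
  placed <- data.frame(chrom = character(n), start = integer(n),
                       end = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      chrom <- sample(chroms, 1, prob = chrom_sizes / sum(chrom_sizes))
      lo <- margin
      hi <- chrom_sizes[[chrom]] - len - margin
      .assert(hi > lo, "chromosome %s too short for placement", chrom)
      start <- lo + sample.int(hi - lo, 1) - 1L
      cand <- c(start - margin, start + len + margin)
      occ <- occupied[[chrom]]
      clash <- !is.null(occ) &&
        any(cand[1] < occ[, 2] & occ[, 1] < cand[2])
      if (!clash) {
        occupied[[chrom]] <- rbind(occ, cand)
        placed$chrom[i] <- chrom
        placed$start[i] <- as.integer(start)
        placed$end[i] <- as.integer(start + len)
        ok <- TRUE
        break
      }
    }
    .assert(ok, "could not place element %d after 1000 attempts", i)
  }
  list(placed = placed, occupied = occupied)
}

# expected extra fragment mass of one flank side under the kernel
.flank_mass <- function(cfg) {
  extra <- cfg$flank_fold - 1
  if (extra <= 0) return(0)
  if (cfg$kernel == "step") {
    extra * cfg$spreading_len_bp
  } else {
    extra * cfg$kernel_tau * (1 - exp(-cfg$flank_len / cfg$kernel_tau))
  }
}

# sample distances-from-edge for flank reads under the kernel
.flank_distances <- function(n, cfg) {
  if (cfg$kernel == "step") {
    floor(runif(n, 0, cfg$spreading_len_bp))
  } else {
    d <- rexp(n, 1 / cfg$kernel_tau)
    while (any(d >= cfg$flank_len))
      d[d >= cfg$flank_len] <- rexp(sum(d >= cfg$flank_len),
                                    1 / cfg$kernel_tau)
    floor(d)
  }
}

.simulate_line_reads <- function(cfg, te, present, chrom_sizes, lib_size) {
  r <- cfg$background_rate
  genome_len <- sum(chrom_sizes)
  body_extra <- (cfg$te_fold - 1) * r * cfg$te_len_bp
  flank_extra <- r * .flank_mass(cfg)
  n_present <- sum(present)
  expected <- r * genome_len + n_present * (body_extra + 2 * flank_extra)
  scale <- if (is.null(lib_size)) 1 else lib_size / expected

  # background stratum (per-chromosome in one vectorized draw)
  n_bg <- rpois(1, r * genome_len * scale)
  counts <- as.vector(stats::rmultinom(1, n_bg,
                                       prob = chrom_sizes / sum(chrom_sizes)))
  chrom <- rep(names(chrom_sizes), counts)
  pos <- unlist(lapply(seq_along(chrom_sizes), function(i) {
    if (counts[i] == 0) return(integer(0))
    sample.int(chrom_sizes[[i]], counts[i], replace = TRUE) - 1L
  }), use.names = FALSE)

  tep <- te[present, , drop = FALSE]
  if (nrow(tep) > 0) {
    # element-body stratum
    n_body <- rpois(nrow(tep), body_extra * scale)
    if (sum(n_body) > 0) {
      idx <- rep(seq_len(nrow(tep)), n_body)
      chrom <- c(chrom, tep$chrom[idx])
      pos <- c(pos, tep$start[idx] +
                 floor(runif(sum(n_body), 0, cfg$te_len_bp)))
    }
    # flank strata, one per side
    for (side in c("left", "right")) {
      n_fl <- rpois(nrow(tep), flank_extra * scale)
      if (sum(n_fl) == 0) next
      idx <- rep(seq_len(nrow(tep)), n_fl)
      d <- .flank_distances(sum(n_fl), cfg)
      p <- if (side == "left") tep$start[idx] - 1L - d else tep$end[idx] + d
      chrom <- c(chrom, tep$chrom[idx])
      pos <- c(pos, p)
    }
  }
  pos <- as.integer(pmax(pmin(pos, chrom_sizes[chrom] - 1L), 0L))
  n <- length(pos)
  data.frame(chrom = chrom,
             pos5 = pos,
             read_len = cfg$read_len,
             strand = ifelse(rbinom(n, 1, 0.5) == 1, "+", "-"),
             mapq = 37L,
             is_unique = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a two-line cohort with known ground truth
#'
#' See [sim_config()] for the generative model.  Output reads for both
#' lines are in reference coordinates of the insertion-carrying genome.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort`: `te_table`, `genes`,
#'   `reads_a`, `reads_b` (full-site / empty-site lines), `mappability`
#'   ([signal_track()]), `expr_a`, `expr_b` (per-gene count tables),
#'   `chrom_sizes`, `truth` (per-copy spreading length, per-gene impact
#'   flag), and the `config`.
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  chrom_sizes <- stats::setNames(rep(as.integer(cfg$chrom_len_bp),
                                     cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))

  # --- place TE copies ------------------------------------------------
  n_te <- cfg$n_common_copies + cfg$n_polymorphic_copies
  occupied <- stats::setNames(vector("list", length(chrom_sizes)),
                              names(chrom_sizes))
  pl <- .place_intervals(n_te, cfg$te_len_bp, cfg$flank_len, chrom_sizes,
                         occupied)
  te <- pl$placed
  occupied <- pl$occupied
  te$copy_id <- sprintf("copy%04d", seq_len(n_te))
  te$strand <- ifelse(rbinom(n_te, 1, 0.5) == 1, "+", "-")
  te$family <- cfg$family
  te$status <- rep(c("common", "polymorphic"),
                   c(cfg$n_common_copies, cfg$n_polymorphic_copies))
  te$present_in <- ifelse(te$status == "common",
                          paste(cfg$line_labels, collapse = ","),
                          cfg$line_labels[1])
  te$length_bp <- te$end - te$start
  te$copy_class <- classify_copy(te$length_bp)
  te <- te[, c("copy_id", "chrom", "start", "end", "strand", "family",
               "status", "present_in", "length_bp", "copy_class")]
  class(te) <- c("te_table", "data.frame")

  # --- genes: planted impacted ones downstream of polymorphic copies ---
  n_plant <- length(cfg$planted_impact_genes)
  poly_idx <- which(te$status == "polymorphic")
  .assert(n_plant <= length(poly_idx),
          "more planted impact genes than polymorphic copies")
  genes <- list()
  for (i in seq_len(n_plant)) {
    spec <- cfg$planted_impact_genes[[i]]
    host <- te[poly_idx[i], ]
    gstart <- host$end + as.integer(spec$tss_distance)
    genes[[i]] <- data.frame(
      gene_id = sprintf("geneImpact%02d", i), chrom = host$chrom,
      start = gstart, end = gstart + cfg$gene_len_bp, strand = "+",
      impacted = TRUE, silencing_fold = spec$silencing_fold,
      host_copy = host$copy_id, stringsAsFactors = FALSE)
    occupied[[host$chrom]] <- rbind(occupied[[host$chrom]],
                                    c(gstart, gstart + cfg$gene_len_bp))
  }
  if (cfg$n_genes > n_plant) {
    # background genes kept strictly clear of every copy's 5-kb zone
    plg <- .place_intervals(cfg$n_genes - n_plant, cfg$gene_len_bp,
                            cfg$flank_len + 1000L, chrom_sizes, occupied)
    bg <- plg$placed
    bg$gene_id <- sprintf("gene%04d", seq_len(nrow(bg)))
    bg$strand <- ifelse(rbinom(nrow(bg), 1, 0.5) == 1, "+", "-")
    bg$impacted <- FALSE
    bg$silencing_fold <- 1
    bg$host_copy <- NA_character_
    genes[[length(genes) + 1]] <-
      bg[, c("gene_id", "chrom", "start", "end", "strand", "impacted",
             "silencing_fold", "host_copy")]
  }
  genes <- if (length(genes) == 0) {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               impacted = logical(), silencing_fold = numeric(),
               host_copy = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$length_bp <- genes$end - genes$start
  rownames(genes) <- NULL

  # --- mappability: holes in the central part of every element body ----
  map_vals <- lapply(names(chrom_sizes), function(chrom)
    Rle(1, chrom_sizes[[chrom]]))
  names(map_vals) <- names(chrom_sizes)
  hole_len <- as.integer(round(cfg$mappability_hole_frac * cfg$te_len_bp))
  holes <- NULL
  if (hole_len > 0) {
    off <- (cfg$te_len_bp - hole_len) %/% 2
    holes <- data.frame(chrom = te$chrom, start = te$start + off,
                        end = te$start + off + hole_len,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(holes))) {
      v <- map_vals[[holes$chrom[i]]]
      v[(holes$start[i] + 1L):holes$end[i]] <- 0
      map_vals[[holes$chrom[i]]] <- v
    }
  }
  mappability <- signal_track(map_vals, chrom_sizes = chrom_sizes)

  flag_holes <- function(reads) {
    if (is.null(holes) || nrow(reads) == 0) return(reads)
    pts <- GRanges(reads$chrom, IRanges(reads$pos5 + 1L, reads$pos5 + 1L))
    hr <- GRanges(holes$chrom, IRanges(holes$start + 1L, holes$end))
    reads$is_unique <- !IRanges::overlapsAny(pts, hr)
    reads
  }

  reads_a <- flag_holes(.simulate_line_reads(
    cfg, te, rep(TRUE, n_te), chrom_sizes, cfg$lib_size_a))
  reads_b <- flag_holes(.simulate_line_reads(
    cfg, te, te$status == "common", chrom_sizes, cfg$lib_size_b))

  # --- expression ------------------------------------------------------
  mu_a <- cfg$expr_mean / genes$silencing_fold
  mu_b <- rep(cfg$expr_mean, nrow(genes))
  expr_a <- data.frame(gene_id = genes$gene_id, length_bp = genes$length_bp,
                       count = rpois(nrow(genes), mu_a),
                       stringsAsFactors = FALSE)
  expr_b <- data.frame(gene_id = genes$gene_id, length_bp = genes$length_bp,
                       count = rpois(nrow(genes), mu_b),
                       stringsAsFactors = FALSE)

  truth <- list(
    copies = data.frame(
      copy_id = te$copy_id, status = te$status,
      spreading_len = ifelse(cfg$flank_fold > 1, cfg$spreading_len_bp, 0),
      stringsAsFactors = FALSE),
    genes = data.frame(gene_id = genes$gene_id, impacted = genes$impacted,
                       host_copy = genes$host_copy,
                       stringsAsFactors = FALSE))

  structure(list(te_table = te,
                 genes = genes[, c("gene_id", "chrom", "start", "end",
                                   "strand", "tss", "length_bp")],
                 reads_a = reads_a, reads_b = reads_b,
                 mappability = mappability, expr_a = expr_a,
                 expr_b = expr_b, chrom_sizes = chrom_sizes, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d copies (%d common, %d polymorphic), %d genes\n",
    nrow(x$te_table), sum(x$te_table$status == "common"),
    sum(x$te_table$status == "polymorphic"), nrow(x$genes)))
  cat(sprintf("  reads: %s %d, %s %d; genome %d x %g bp\n",
              x$config$line_labels[1], nrow(x$reads_a),
              x$config$line_labels[2], nrow(x$reads_b),
              x$config$n_chroms, x$config$chrom_len_bp))
  invisible(x)
}
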