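#' Configuration of the QTL interval caller
#'
#' A locus is a maximal cluster of hit markers: markers of the target class,
#' allowing up to `gap_tolerance` consecutive non-hit markers inside the
#' cluster, with at least `min_run` hit markers in total. `gap_tolerance = 0`
#' reduces the rule to plain adjacency ("at least `min_run` adjacent
#' markers"); larger values admit "closely clustered" markers.
#'
#' @param min_run Minimum hit markers per locus (default 3).
#' @param gap_tolerance Maximum consecutive non-hit markers inside a cluster
#'   (default 2).
#' @param boundary_rule `"flanking_marker"` (default: interval extends to,
#'   but excludes, the nearest non-hit marker on each side; chromosome ends
#'   where there is none) or `"last_significant"` (interval spans exactly
#'   the outermost hit markers).
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_run = 3, gap_tolerance = 2,
                          boundary_rule = c("flanking_marker",
                                            "last_significant")) {
  boundary_rule <- match.arg(boundary_rule)
  stopifnot(min_run >= 1, gap_tolerance >= 0)
  structure(list(min_run = as.integer(min_run),
                 gap_tolerance = as.integer(gap_tolerance),
                 boundary_rule = boundary_rule),
            class = "caller_config")
}

# Cluster a boolean hit track (one chromosome, marker order) into maximal
# clusters allowing <= gap internal non-hits; returns list of integer index
# vectors of the hit markers per cluster (min_run not yet applied).
cluster_hits <- function(hit, gap) {
  idx <- which(hit)
  if (!length(idx)) return(list())
  grp <- cumsum(c(1L, diff(idx) > gap + 1L))
  unname(split(idx, grp))
}

# Build locus rows from hit clusters; scan_chr is the per-chromosome slice
# of a scan, hit a parallel logical vector, chrom_len the chromosome length
# (bp) or NA.
loci_from_clusters <- function(scan_chr, hit, cfg, chrom_len, class_label) {
  clusters <- Filter(function(ix) length(ix) >= cfg$min_run,
                     cluster_hits(hit, cfg$gap_tolerance))
  if (!length(clusters)) return(NULL)
  rows <- lapply(clusters, function(ix) {
    first <- min(ix); last <- max(ix)
    if (cfg$boundary_rule == "flanking_marker") {
      # adjacent outside markers are non-hit by cluster maximality
      start0 <- if (first > 1) scan_chr$bp[first - 1] else 0
      end0 <- if (last < nrow(scan_chr)) scan_chr$bp[last + 1] - 1 else
        chrom_len
    } else {
      start0 <- scan_chr$bp[first] - 1
      end0 <- scan_chr$bp[last]
    }
    if (is.na(end0)) end0 <- scan_chr$bp[nrow(scan_chr)]
    peak_i <- ix[which.max(scan_chr$neglog10p[ix])]  # ties -> leftmost
    data.frame(
      trait = scan_chr$trait[1], chrom = scan_chr$chrom[1],
      start = start0, end = end0,
      n_markers = length(ix),
      peak_marker = scan_chr$marker_id[peak_i],
      peak_bp = scan_chr$bp[peak_i],
      peak_neglog10p = scan_chr$neglog10p[peak_i],
      peak_effect = scan_chr$effect[peak_i],
      effect_sign = sign(scan_chr$effect[peak_i]),
      class = class_label,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

check_scan_sorted <- function(scan) {
  for (ch in unique(scan$chrom)) {
    if (is.unsorted(scan$bp[scan$chrom == ch], strictly = TRUE)) {
      stop("qtl caller: scan markers must be sorted by position within ",
           "chromosome ", ch)
    }
  }
}

new_cc_loci <- function(rows, trait) {
  if (is.null(rows) || !nrow(rows)) {
    rows <- data.frame(trait = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       n_markers = integer(), peak_marker = character(),
                       peak_bp = numeric(), peak_neglog10p = numeric(),
                       peak_effect = numeric(), effect_sign = numeric(),
                       class = character(), stringsAsFactors = FALSE)
  }
  rows$locus_id <- if (nrow(rows)) {
    sprintf("%s_%s_%02d", rows$trait, rows$class, seq_len(nrow(rows)))
  } else character(0)
  rownames(rows) <- NULL
  structure(rows, class = c("cc_loci", "data.frame"))
}

#' Call significant QTL intervals from a genome scan
#'
#' Maximal clusters of significant markers (allowing up to
#' `cfg$gap_tolerance` internal non-significant markers) with at least
#' `cfg$min_run` significant markers become loci. Under the default
#' boundary rule the interval runs from the nearest flanking non-significant
#' marker on each side (exclusive), truncated at the chromosome ends.
#' Intervals are 0-based half-open; the peak is the marker with the largest
#' -log10 p, ties broken by leftmost position.
#'
#' @param scan A `cc_scan`, markers ordered by (chrom, bp).
#' @param cfg A [caller_config()].
#' @return A data.frame of class `cc_loci` with columns `trait`, `chrom`,
#'   `start`, `end`, `n_markers`, `peak_marker`, `peak_bp`,
#'   `peak_neglog10p`, `peak_effect`, `effect_sign`, `class`, `locus_id`.
#' @export
call_significant <- function(scan, cfg = caller_config()) {
  stopifnot(inherits(scan, "cc_scan") || is.data.frame(scan))
  check_scan_sorted(scan)
  lens <- attr(scan, "chrom_lengths")
  rows <- NULL
  for (ch in unique(scan$chrom)) {
    sc <- scan[scan$chrom == ch, , drop = FALSE]
    chrom_len <- if (!is.null(lens) && ch %in% names(lens)) lens[[ch]] else NA
    rows <- rbind(rows, loci_from_clusters(sc, sc$class == "significant",
                                           cfg, chrom_len, "significant"))
  }
  new_cc_loci(rows, attr(scan, "trait"))
}

#' Call suggestive loci restricted to the other trait's significant regions
#'
#' Suggestive loci for trait A are only sought inside regions where the
#' other trait (B) already has a significant locus: a marker of scan A
#' counts as a hit iff its class is `"suggestive"` and its position falls
#' inside some interval of `lociB`. Hits are clustered under the same run
#' and boundary rules as [call_significant()].
#'
#' @param scanA A `cc_scan` for the trait whose suggestive loci are sought.
#' @param lociB A `cc_loci` of significant loci of the other trait, on the
#'   same marker map.
#' @param cfg A [caller_config()].
#' @return A `cc_loci` with `class = "suggestive"`.
#' @export
call_suggestive <- function(scanA, lociB, cfg = caller_config()) {
  check_scan_sorted(scanA)
  lens <- attr(scanA, "chrom_lengths")
  in_b <- rep(FALSE, nrow(scanA))
  if (nrow(lociB)) {
    lv <- union(scanA$chrom, lociB$chrom)
    gr_m <- GenomicRanges::GRanges(
      factor(scanA$chrom, levels = lv),
      IRanges::IRanges(start = scanA$bp, width = 1))
    gr_b <- GenomicRanges::GRanges(
      factor(lociB$chrom, levels = lv),
      IRanges::IRanges(start = lociB$start + 1, end = lociB$end))
    in_b <- GenomicRanges::countOverlaps(gr_m, gr_b) > 0
  }
  rows <- NULL
  for (ch in unique(scanA$chrom)) {
    sel <- scanA$chrom == ch
    sc <- scanA[sel, , drop = FALSE]
    hit <- sc$class == "suggestive" & in_b[sel]
    chrom_len <- if (!is.null(lens) && ch %in% names(lens)) lens[[ch]] else NA
    rows <- rbind(rows, loci_from_clusters(sc, hit, cfg, chrom_len,
                                           "suggestive"))
  }
  new_cc_loci(rows, attr(scanA, "trait"))
}

#' Score recovery of planted loci by called QTL
#'
#' A planted locus counts as recovered if any called locus of the same
#' trait has its peak within `window` bp of the planted (marker-resolved)
#' position. Called loci whose peak is not within `window` of any planted
#' locus of their trait count as false positives.
#'
#' @param loci A `cc_loci` (typically significant calls for one or both
#'   traits, row-bound).
#' @param truth data.frame with `trait`, `chrom`, `bp` (use the `truth`
#'   attribute of a simulated `cc_pheno`, which carries marker-snapped
#'   positions in `marker_bp`; plain `bp` is used when `marker_bp` is
#'   absent).
#' @param window Matching window in bp (> 0).
#' @return `list(n_true, n_recovered, recovery, n_called, n_false,
#'   recovered)` where `recovered` is a logical vector over truth rows.
#' @export
planted_recovery <- function(loci, truth, window) {
  stopifnot(window > 0)
  pos <- if ("marker_bp" %in% names(truth)) truth$marker_bp else truth$bp
  n_true <- nrow(truth)
  recovered <- logical(n_true)
  matched_locus <- rep(FALSE, nrow(loci))
  for (i in seq_len(n_true)) {
    cand <- which(loci$trait == truth$trait[i] &
                    loci$chrom == truth$chrom[i] &
                    abs(loci$peak_bp - pos[i]) <= window)
    if (length(cand)) {
      recovered[i] <- TRUE
      matched_locus[cand] <- TRUE
    }
  }
  list(
    n_true = n_true,
    n_recovered = sum(recovered),
    recovery = if (n_true) sum(recovered) / n_true else NA_real_,
    n_called = nrow(loci),
    n_false = sum(!matched_locus),
    recovered = recovered
  )
}
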