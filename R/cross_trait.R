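#' Per-strain, per-sex phenotype summaries and cross-trait correlations
#'
#' Computes, for each strain and sex, the mean, SD and count of each trait;
#' the cross-sex Pearson correlation of strain means for each trait
#' (strains with only one sex are excluded from this statistic and listed);
#' and the per-sex Spearman correlation between the two traits over
#' animals (midrank ties).
#'
#' @param ph A `cc_pheno` (or data.frame with `strain`, `sex` and two trait
#'   columns).
#' @param traits Character vector of the two trait columns (default: all
#'   numeric non-bookkeeping columns, first two).
#' @return An object of class `strain_summary`: list with `per_strain_sex`
#'   (data.frame), `cross_sex_pearson` (named per trait),
#'   `spearman_between_traits` (named per sex), `excluded_strains`.
#' @export
summarize_strains <- function(ph, traits = NULL) {
  if (is.null(traits)) {
    num <- vapply(ph, is.numeric, logical(1))
    num[names(num) %in% c("n_trials")] <- FALSE
    traits <- names(ph)[num][1:2]
  }
  stopifnot(length(traits) == 2, all(traits %in% names(ph)),
            length(unique(ph$strain)) >= 2)
  key <- interaction(ph$strain, ph$sex, drop = TRUE)
  per <- do.call(rbind, lapply(split(seq_len(nrow(ph)), key), function(ix) {
    row <- data.frame(strain = ph$strain[ix[1]], sex = ph$sex[ix[1]],
                      n = length(ix), stringsAsFactors = FALSE)
    for (t in traits) {
      row[[paste0(t, "_mean")]] <- mean(ph[[t]][ix])
      row[[paste0(t, "_sd")]] <- stats::sd(ph[[t]][ix])
    }
    row
  }))
  per <- per[order(per$strain, per$sex), , drop = FALSE]
  rownames(per) <- NULL

  sex_tab <- table(unique(per[, c("strain", "sex")]))
  both <- rownames(sex_tab)[rowSums(sex_tab > 0) == 2]
  excluded <- setdiff(unique(ph$strain), both)
  cross <- stats::setNames(numeric(length(traits)), traits)
  for (t in traits) {
    fm <- per[per$sex == "F" & per$strain %in% both, ]
    mm <- per[per$sex == "M" & per$strain %in% both, ]
    mm <- mm[match(fm$strain, mm$strain), ]
    cross[t] <- if (nrow(fm) >= 2) {
      stats::cor(fm[[paste0(t, "_mean")]], mm[[paste0(t, "_mean")]])
    } else NA_real_
  }
  sp <- vapply(sort(unique(ph$sex)), function(s) {
    sel <- ph$sex == s
    stats::cor(ph[[traits[1]]][sel], ph[[traits[2]]][sel],
               method = "spearman")
  }, numeric(1))
  structure(
    list(per_strain_sex = per, cross_sex_pearson = cross,
         spearman_between_traits = sp, excluded_strains = excluded,
         traits = traits),
    class = "strain_summary"
  )
}

#' @export
print.strain_summary <- function(x, ...) {
  cat("<strain_summary>", length(unique(x$per_strain_sex$strain)),
      "strains\n")
  cat("cross-sex Pearson (strain means):",
      paste(sprintf("%s = %.3f", names(x$cross_sex_pearson),
                    x$cross_sex_pearson), collapse = ", "), "\n")
  cat("between-trait Spearman (animals):",
      paste(sprintf("%s = %.3f", names(x$spearman_between_traits),
                    x$spearman_between_traits), collapse = ", "), "\n")
  if (length(x$excluded_strains)) {
    cat("strains excluded from cross-sex correlation:",
        paste(x$excluded_strains, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Intersect two sets of QTL intervals
#'
#' Emits a pair for every (A, B) combination on the same chromosome whose
#' half-open intervals intersect. One A locus may pair with several B loci.
#'
#' @param lociA,lociB `cc_loci` data.frames.
#' @return data.frame with one row per overlapping pair: ids, coordinates,
#'   and the intersection span (`int_start`, `int_end`, 0-based half-open).
#' @export
intersect_loci <- function(lociA, lociB) {
  empty <- data.frame(
    locusA = character(), locusB = character(), chrom = character(),
    startA = numeric(), endA = numeric(), startB = numeric(),
    endB = numeric(), int_start = numeric(), int_end = numeric(),
    stringsAsFactors = FALSE)
  if (!nrow(lociA) || !nrow(lociB)) return(empty)
  lv <- union(lociA$chrom, lociB$chrom)
  grA <- GenomicRanges::GRanges(factor(lociA$chrom, levels = lv),
                                IRanges::IRanges(lociA$start + 1, lociA$end))
  grB <- GenomicRanges::GRanges(factor(lociB$chrom, levels = lv),
                                IRanges::IRanges(lociB$start + 1, lociB$end))
  ov <- GenomicRanges::findOverlaps(grA, grB)
  if (!length(ov)) return(empty)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  data.frame(
    locusA = lociA$locus_id[qa], locusB = lociB$locus_id[qb],
    chrom = lociA$chrom[qa],
    startA = lociA$start[qa], endA = lociA$end[qa],
    startB = lociB$start[qb], endB = lociB$end[qb],
    int_start = pmax(lociA$start[qa], lociB$start[qb]),
    int_end = pmin(lociA$end[qa], lociB$end[qb]),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric test of QTL-set overlap
#'
#' Upper-tail probability `P(X >= k_both)` for the overlap of two random
#' subsets of sizes `kA` and `kB` of a universe of `N` genomic bins.
#'
#' @param kA,kB Number of bins (loci) in each set.
#' @param k_both Observed overlap count.
#' @param N Universe size (e.g. [genome_bins()]).
#' @return The tail probability, in `(0, 1]`.
#' @export
#' @examples
#' overlap_test(5, 5, 5, 20)  # 1 / choose(20, 5)
overlap_test <- function(kA, kB, k_both, N) {
  stopifnot(length(kA) == 1, length(kB) == 1, length(k_both) == 1,
            length(N) == 1)
  if (k_both > min(kA, kB)) {
    stop("overlap_test: k_both must be <= min(kA, kB)")
  }
  if (kA > N || kB > N) stop("overlap_test: kA, kB must be <= N")
  if (min(kA, kB, k_both, N) < 0) stop("overlap_test: counts must be >= 0")
  stats::phyper(k_both - 1, kA, N - kA, kB, lower.tail = FALSE)
}

#' Number of disjoint genomic bins covering a genome
#'
#' Universe size for [overlap_test()]: each chromosome contributes
#' `ceiling(length / bin_width)` bins.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp), or
#'   a [genome_layout()].
#' @param bin_width Bin width in bp (default 5 Mb).
#' @return Integer bin count.
#' @export
genome_bins <- function(chrom_lengths, bin_width = 5e6) {
  if (inherits(chrom_lengths, "genome_layout")) {
    chrom_lengths <- chrom_lengths_of(chrom_lengths)
  }
  stopifnot(bin_width > 0, all(chrom_lengths > 0))
  sum(ceiling(chrom_lengths / bin_width))
}

#' Permutation null for QTL interval overlap
#'
#' Places the A intervals uniformly at random within their own chromosomes
#' (lengths preserved, no self-overlap among A intervals on a chromosome)
#' `n_perm` times and counts, per permutation, how many A loci intersect
#' any B locus. The p-value is `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param lociA,lociB `cc_loci` data.frames.
#' @param chrom_lengths Named chromosome lengths (bp) or a
#'   [genome_layout()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return `list(p, observed, n_perm, mc_se)`.
#' @export
permutation_overlap_null <- function(lociA, lociB, chrom_lengths, n_perm,
                                     seed) {
  if (inherits(chrom_lengths, "genome_layout")) {
    chrom_lengths <- chrom_lengths_of(chrom_lengths)
  }
  stopifnot(n_perm >= 100)
  set.seed(as.integer(seed))
  widths <- lociA$end - lociA$start
  if (nrow(lociA) &&
      any(widths > chrom_lengths[lociA$chrom])) {
    stop("permutation_overlap_null: locus longer than its chromosome")
  }
  observed <- count_a_overlapping(lociA, lociB)
  if (!nrow(lociA)) {
    return(list(p = 1, observed = 0L, n_perm = n_perm, mc_se = 0))
  }
  b_by_chrom <- split(seq_len(nrow(lociB)), lociB$chrom)
  a_by_chrom <- split(seq_len(nrow(lociA)), lociA$chrom)
  counts <- integer(n_perm)
  for (p_i in seq_len(n_perm)) {
    hits <- 0L
    for (ch in names(a_by_chrom)) {
      ia <- a_by_chrom[[ch]]
      L <- chrom_lengths[[ch]]
      w <- widths[ia]
      # rejection-sample non-self-overlapping placements
      for (attempt in 1:1000) {
        starts <- floor(stats::runif(length(ia), 0, L - w + 1))
        ends <- starts + w
        o <- order(starts)
        if (all(starts[o][-1] >= ends[o][-length(o)])) break
        if (attempt == 1000) {
          stop("permutation_overlap_null: cannot place loci without ",
               "self-overlap on ", ch)
        }
      }
      ib <- b_by_chrom[[ch]]
      if (!is.null(ib) && length(ib)) {
        bs <- lociB$start[ib]; be <- lociB$end[ib]
        for (j in seq_along(ia)) {
          if (any(starts[j] < be & bs < ends[j])) hits <- hits + 1L
        }
      }
    }
    counts[p_i] <- hits
  }
  p <- (1 + sum(counts >= observed)) / (n_perm + 1)
  list(p = p, observed = observed, n_perm = n_perm,
       mc_se = sqrt(p * (1 - p) / n_perm))
}

# number of A loci intersecting >= 1 B locus
count_a_overlapping <- function(lociA, lociB) {
  if (!nrow(lociA) || !nrow(lociB)) return(0L)
  pairs <- intersect_loci(lociA, lociB)
  length(unique(pairs$locusA))
}

#' Effect-direction concordance of a pair of overlapping loci
#'
#' Within the intersection of the two intervals, the shared peak is the
#' marker maximizing `min(-log10 p1, -log10 p2)`; the pair is
#' `"concordant"` when the two allele effects there have the same sign and
#' `"discordant"` when opposite. A zero effect at the shared peak yields
#' `NA` with a warning.
#'
#' @param scan1,scan2 `cc_scan` objects on the same marker map.
#' @param pair One row of [intersect_loci()] output (or any list with
#'   `chrom`, `int_start`, `int_end`).
#' @return `"concordant"`, `"discordant"` or `NA`.
#' @export
direction_concordance <- function(scan1, scan2, pair) {
  stopifnot(identical(scan1$marker_id, scan2$marker_id))
  sel <- scan1$chrom == pair$chrom &
    scan1$bp - 1 >= pair$int_start & scan1$bp - 1 < pair$int_end
  if (!any(sel)) {
    stop("direction_concordance: no markers in the locus intersection")
  }
  score <- pmin(scan1$neglog10p[sel], scan2$neglog10p[sel])
  i <- which(sel)[which.max(score)]
  s <- sign(scan1$effect[i]) * sign(scan2$effect[i])
  if (s == 0) {
    warning("direction_concordance: zero effect at shared peak")
    return(NA_character_)
  }
  if (s > 0) "concordant" else "discordant"
}

#' Full cross-trait QTL overlap analysis
#'
#' Counts loci of A intersecting any locus of B, tests the count against a
#' binned hypergeometric null and an interval-permutation null, and labels
#' every overlapping pair by effect-direction concordance.
#'
#' @param lociA,lociB `cc_loci` (significant calls of the two traits).
#' @param scanA,scanB Matching `cc_scan` objects (for directions).
#' @param chrom_lengths Named chromosome lengths (bp) or a
#'   [genome_layout()].
#' @param bin_width Bin width for the hypergeometric universe (default 5
#'   Mb); the universe size `N` is always reported alongside the p-value.
#' @param n_perm Permutations for the interval null (default 1000).
#' @param seed Seed for the permutation null.
#' @return An object of class `overlap_result`: list with `n_lociA`,
#'   `n_lociB`, `n_overlapping`, `N`, `bin_width`, `hypergeom_p`,
#'   `permutation` (list), `pairs` (data.frame with a `direction` column).
#' @export
qtl_overlap <- function(lociA, lociB, scanA, scanB, chrom_lengths,
                        bin_width = 5e6, n_perm = 1000, seed = 1) {
  if (inherits(chrom_lengths, "genome_layout")) {
    chrom_lengths <- chrom_lengths_of(chrom_lengths)
  }
  pairs <- intersect_loci(lociA, lociB)
  pairs$direction <- if (nrow(pairs)) {
    vapply(seq_len(nrow(pairs)), function(i) {
      direction_concordance(scanA, scanB, pairs[i, ])
    }, character(1))
  } else character(0)
  N <- genome_bins(chrom_lengths, bin_width)
  k_both <- length(unique(pairs$locusA))
  hg <- overlap_test(nrow(lociA), nrow(lociB), k_both, N)
  perm <- permutation_overlap_null(lociA, lociB, chrom_lengths, n_perm,
                                   seed)
  structure(
    list(n_lociA = nrow(lociA), n_lociB = nrow(lociB),
         n_overlapping = k_both, N = N, bin_width = bin_width,
         hypergeom_p = hg, permutation = perm, pairs = pairs),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %d of %d A loci intersect %d B loci\n",
    x$n_overlapping, x$n_lociA, x$n_lociB))
  cat(sprintf("hypergeometric p = %.3g (universe N = %d bins of %g bp)\n",
              x$hypergeom_p, x$N, x$bin_width))
  cat(sprintf("permutation p = %.3g (n_perm = %d)\n",
              x$permutation$p, x$permutation$n_perm))
  if (nrow(x$pairs)) {
    cat("directions:", paste(sprintf("%s~%s:%s", x$pairs$locusA,
                                     x$pairs$locusB, x$pairs$direction),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
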