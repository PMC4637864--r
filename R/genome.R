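#' Describe a genome layout for simulation
#'
#' A genome layout holds the chromosome sizes plus the two densities that
#' drive the simulator: markers per Mb and expected recombination breakpoints
#' per Mb per inbred genome. Recombinant inbred genomes accumulate
#' breakpoints over many generations of inbreeding, so `recomb_rate` is the
#' realized (fixed) breakpoint density of a finished strain, not a per-meiosis
#' rate.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param marker_density Markers per Mb (> 0).
#' @param recomb_rate Expected breakpoints per Mb per strain (>= 0).
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chrom` (data.frame with `name`, `length`), `marker_density`,
#'   `recomb_rate`.
#' @export
#' @examples
#' genome_layout(c(chr1 = 100e6, chr2 = 80e6))
genome_layout <- function(chrom_lengths, marker_density = 1, recomb_rate = 0.05) {
  if (length(chrom_lengths) == 0) {
    stop("genome_layout: at least one chromosome is required")
  }
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == "")) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("genome_layout: duplicated chromosome names")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("genome_layout: chromosome lengths must be positive and finite")
  }
  if (!is.numeric(marker_density) || length(marker_density) != 1 ||
      marker_density <= 0) {
    stop("genome_layout: marker_density must be a single positive number")
  }
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1 || recomb_rate < 0) {
    stop("genome_layout: recomb_rate must be a single non-negative number")
  }
  structure(
    list(
      chrom = data.frame(
        name = names(chrom_lengths),
        length = as.numeric(chrom_lengths),
        stringsAsFactors = FALSE
      ),
      marker_density = marker_density,
      recomb_rate = recomb_rate
    ),
    class = "genome_layout"
  )
}

#' Mouse-autosome-like default genome layout
#'
#' Nineteen autosomes with approximately mouse-sized lengths (~2.5 Gb
#' total). At the default 2 markers/Mb this yields ~5,100 markers; the
#' default breakpoint density of 0.05/Mb gives on the order of 130
#' breakpoints per inbred genome, in the range reported for Collaborative
#' Cross strains.
#'
#' @inheritParams genome_layout
#' @return A `genome_layout`.
#' @export
default_genome <- function(marker_density = 2, recomb_rate = 0.05) {
  mb <- c(197, 182, 160, 156, 152, 149, 145, 132, 124, 130,
          122, 120, 120, 125, 104, 98, 95, 91, 61)
  lens <- mb * 1e6
  names(lens) <- paste0("chr", seq_along(lens))
  genome_layout(lens, marker_density = marker_density, recomb_rate = recomb_rate)
}

chrom_lengths_of <- function(layout) {
  stats::setNames(layout$chrom$length, layout$chrom$name)
}

#' Simulate founder mosaics for inbred strains
#'
#' Each strain's chromosome is partitioned into segments labeled by founder
#' of origin (0-7). Breakpoints are drawn as a homogeneous Poisson point
#' process with rate `layout$recomb_rate` per Mb; founder labels follow a
#' uniform Markov chain with no self-transition across a breakpoint, so
#' adjacent segments always differ. Segments use 0-based half-open
#' coordinates and tile `[0, chromosome length)` exactly.
#'
#' @param layout A [genome_layout()].
#' @param n_strains Number of strains to simulate (>= 1).
#' @param seed Integer seed; the same seed reproduces the mosaics exactly.
#' @param strain_ids Optional character vector of strain names (default
#'   `CC001`, `CC002`, ...).
#'
#' @return An object of class `cc_mosaics`: a named list with one element per
#'   strain, each a named list over chromosomes of
#'   `list(ends = <segment end positions in bp>, founder = <labels 0-7>)`.
#'   The layout is attached as attribute `layout`.
#' @export
#' @examples
#' m <- simulate_mosaics(genome_layout(c(chr1 = 50e6)), n_strains = 3, seed = 1)
#' m$CC001$chr1
simulate_mosaics <- function(layout, n_strains, seed, strain_ids = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(n_strains) || length(n_strains) != 1 || n_strains < 1) {
    stop("simulate_mosaics: n_strains must be >= 1")
  }
  n_strains <- as.integer(n_strains)
  if (is.null(strain_ids)) {
    strain_ids <- sprintf("CC%03d", seq_len(n_strains))
  }
  stopifnot(length(strain_ids) == n_strains, !anyDuplicated(strain_ids))
  set.seed(as.integer(seed))
  rho <- layout$recomb_rate
  chroms <- layout$chrom
  mosaics <- vector("list", n_strains)
  names(mosaics) <- strain_ids
  for (s in seq_len(n_strains)) {
    per_chrom <- vector("list", nrow(chroms))
    names(per_chrom) <- chroms$name
    for (ci in seq_len(nrow(chroms))) {
      L <- chroms$length[ci]
      n_bp <- stats::rpois(1, rho * L / 1e6)
      breaks <- sort(stats::runif(n_bp, 0, L))
      # collapse numerically coincident breakpoints (measure-zero event)
      breaks <- unique(breaks)
      k <- length(breaks) + 1L
      founder <- integer(k)
      founder[1] <- sample.int(8L, 1L) - 1L
      if (k > 1) {
        for (j in 2:k) {
          # uniform over the 7 founders other than the previous one
          founder[j] <- (founder[j - 1] + sample.int(7L, 1L)) %% 8L
        }
      }
      per_chrom[[ci]] <- list(ends = c(breaks, L), founder = founder)
    }
    mosaics[[s]] <- per_chrom
  }
  structure(mosaics, class = "cc_mosaics", layout = layout)
}

#' Founder label at given positions
#'
#' Looks up the founder of origin for 0-based positions on one chromosome of
#' one strain's mosaic.
#'
#' @param chrom_mosaic One chromosome entry of a mosaic
#'   (`list(ends, founder)`).
#' @param pos0 Numeric vector of 0-based positions in `[0, length)`.
#' @return Integer founder labels (0-7).
#' @keywords internal
founder_at <- function(chrom_mosaic, pos0) {
  ends <- chrom_mosaic$ends
  # segment i covers [ends[i-1], ends[i]); findInterval on interior ends
  idx <- findInterval(pos0, ends[-length(ends)]) + 1L
  chrom_mosaic$founder[idx]
}

#' Simulate a biallelic marker map with founder strain-distribution patterns
#'
#' Markers are placed at distinct uniform positions on each chromosome with
#' the layout's density (count per chromosome = `round(density * Mb)`, at
#' least 1). Each marker's strain-distribution pattern (SDP) is the subset
#' of the 8 founders carrying allele 1. SDPs are spatially persistent:
#' along a chromosome, each marker keeps the previous marker's SDP with
#' probability `sdp_share` (with each founder bit independently flipped
#' with probability `sdp_mut`, so tagging is strong but not exact) and
#' otherwise draws a fresh SDP uniformly among the non-empty, non-full
#' subsets. This mimics the runs of array SNPs that tag the same ancestral
#' variant, which is what makes "several adjacent significant SNPs" a
#' meaningful locus criterion; `sdp_share = 0` gives fully independent
#' markers.
#'
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @param sdp_share Probability that a marker inherits its left neighbour's
#'   SDP (default 0.9; mean tag-block of ~10 markers).
#' @param sdp_mut Per-founder bit-flip probability within an inherited SDP
#'   (default 0.05).
#' @return A data.frame of class `marker_map` with columns `id`, `chrom`,
#'   `bp` (1-based position), `sdp` (8-character 0/1 string, founders 0-7
#'   left to right). Positions strictly increase within each chromosome.
#'   Chromosome lengths are attached as attribute `chrom_lengths`.
#' @export
simulate_marker_map <- function(layout, seed, sdp_share = 0.9,
                                sdp_mut = 0.05) {
  stopifnot(inherits(layout, "genome_layout"),
            sdp_share >= 0, sdp_share < 1, sdp_mut >= 0, sdp_mut < 0.5)
  set.seed(as.integer(seed))
  fresh_sdp <- function() {
    repeat {
      bits <- stats::rbinom(8, 1, 0.5)
      if (any(bits == 1) && any(bits == 0)) return(bits)
    }
  }
  out <- vector("list", nrow(layout$chrom))
  for (ci in seq_len(nrow(layout$chrom))) {
    L <- layout$chrom$length[ci]
    n <- max(1L, as.integer(round(layout$marker_density * L / 1e6)))
    bp <- sort(sample.int(as.integer(L), n))
    sdp <- character(n)
    prev <- fresh_sdp()
    sdp[1] <- paste(prev, collapse = "")
    for (k in seq_len(n)[-1]) {
      if (stats::runif(1) < sdp_share) {
        bits <- prev
        if (sdp_mut > 0) {
          flip <- stats::runif(8) < sdp_mut
          bits[flip] <- 1L - bits[flip]
        }
        if (all(bits == 1) || all(bits == 0)) bits <- fresh_sdp()
      } else {
        bits <- fresh_sdp()
      }
      prev <- bits
      sdp[k] <- paste(bits, collapse = "")
    }
    out[[ci]] <- data.frame(
      id = sprintf("M_%s_%05d", layout$chrom$name[ci], seq_len(n)),
      chrom = layout$chrom$name[ci],
      bp = bp,
      sdp = sdp,
      stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  new_marker_map(map, chrom_lengths_of(layout))
}

new_marker_map <- function(df, chrom_lengths) {
  stopifnot(all(c("id", "chrom", "bp", "sdp") %in% names(df)))
  if (anyDuplicated(df$id)) stop("marker map: duplicated marker ids")
  if (!all(grepl("^[01]{8}$", df$sdp))) {
    stop("marker map: SDP must be an 8-character 0/1 string")
  }
  for (ch in unique(df$chrom)) {
    b <- df$bp[df$chrom == ch]
    if (any(diff(b) <= 0)) {
      stop("marker map: positions must strictly increase within chromosome ", ch)
    }
    if (!is.null(chrom_lengths) && !ch %in% names(chrom_lengths)) {
      stop("marker map: chromosome ", ch, " not in chrom_lengths")
    }
    if (!is.null(chrom_lengths) && any(b > chrom_lengths[[ch]])) {
      stop("marker map: marker beyond end of chromosome ", ch)
    }
  }
  structure(df, class = c("marker_map", "data.frame"),
            chrom_lengths = chrom_lengths)
}

sdp_matrix <- function(map) {
  m <- t(vapply(strsplit(map$sdp, ""), function(x) x == "1", logical(8)))
  colnames(m) <- paste0("F", 0:7)
  m
}

#' Project a marker map through founder mosaics to a genotype matrix
#'
#' For each strain and marker, the allele is 1 iff the founder of the mosaic
#' segment containing the marker position belongs to the marker's SDP, else
#' 0. Inbred strains carry a single allele code per marker; an optional
#' residual-heterozygosity rate emits missing codes (`NA`) at random
#' positions, defaulting to none.
#'
#' @param mosaics A `cc_mosaics` object from [simulate_mosaics()].
#' @param map A `marker_map`.
#' @param het_rate Probability that a (strain, marker) cell is masked to `NA`
#'   to mimic residual heterozygosity in an incompletely inbred line
#'   (default 0). When positive, masking consumes the current RNG stream.
#' @return An object of class `cc_geno`: `list(geno, map, strains)` where
#'   `geno` is a strains x markers integer matrix of 0/1/NA with dimnames.
#' @export
project_markers <- function(mosaics, map, het_rate = 0) {
  stopifnot(inherits(mosaics, "cc_mosaics"), inherits(map, "marker_map"))
  layout <- attr(mosaics, "layout")
  known <- layout$chrom$name
  bad <- setdiff(unique(map$chrom), known)
  if (length(bad)) {
    stop("project_markers: markers on unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  }
  strains <- names(mosaics)
  sdp <- sdp_matrix(map)
  geno <- matrix(NA_integer_, nrow = length(strains), ncol = nrow(map),
                 dimnames = list(strains, map$id))
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    pos0 <- map$bp[cols] - 1
    for (s in seq_along(strains)) {
      f <- founder_at(mosaics[[s]][[ch]], pos0)
      geno[s, cols] <- as.integer(sdp[cbind(cols, f + 1L)])
    }
  }
  if (het_rate > 0) {
    mask <- stats::runif(length(geno)) < het_rate
    geno[mask] <- NA_integer_
  }
  new_cc_geno(geno, map)
}

new_cc_geno <- function(geno, map) {
  stopifnot(is.matrix(geno), ncol(geno) == nrow(map),
            identical(colnames(geno), map$id))
  structure(
    list(geno = geno, map = map, strains = rownames(geno)),
    class = "cc_geno"
  )
}

#' @export
print.cc_geno <- function(x, ...) {
  cat(sprintf("<cc_geno> %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Find well-tagged, intermediate-frequency markers
#'
#' Selects, per requested chromosome, a marker suitable for planting a
#' simulated QTL: allele frequency within `maf` and at least one flanking
#' marker on each side within `window` bp whose allele column correlates
#' with it at `min_r` or better. Planting at such markers makes a power
#' study measure the mapping pipeline rather than array coverage: a causal
#' variant that no neighbouring marker tags can never satisfy a
#' multi-marker locus rule, whatever the caller does. Among candidates the
#' marker closest to `at` (default mid-chromosome) is returned.
#'
#' @param g A `cc_geno`.
#' @param chroms Chromosomes to pick from.
#' @param maf Length-2 allele-frequency band (default 0.35-0.65).
#' @param window Flanking search window in bp (default 2.5 Mb).
#' @param min_r Minimum absolute allele correlation with a flanking marker.
#' @param at Optional named numeric of target positions per chromosome.
#' @param max_mutual_r When > 0, successive picks must also have absolute
#'   allele correlation at most this value with every previously picked
#'   marker. Chance correlation between unlinked planted loci on a finite
#'   strain panel biases each other's effect estimates, so a power study
#'   plants at mutually near-orthogonal markers.
#' @return Named integer vector of marker row indices into `g$map` (NA when
#'   a chromosome has no qualifying marker).
#' @export
tagged_markers <- function(g, chroms, maf = c(0.35, 0.65), window = 2.5e6,
                           min_r = 0.8, at = NULL, max_mutual_r = 0) {
  stopifnot(inherits(g, "cc_geno"))
  out <- stats::setNames(rep(NA_integer_, length(chroms)), chroms)
  for (ch in chroms) {
    cols <- which(g$map$chrom == ch)
    if (!length(cols)) next
    G <- g$geno[, cols, drop = FALSE]
    f <- colMeans(G, na.rm = TRUE)
    bp <- g$map$bp[cols]
    target <- if (!is.null(at) && ch %in% names(at)) at[[ch]] else
      stats::median(bp)
    cand <- which(f >= maf[1] & f <= maf[2])
    cand <- cand[order(abs(bp[cand] - target))]
    for (j in cand) {
      near <- which(abs(bp - bp[j]) <= window & seq_along(cols) != j)
      if (!length(near)) next
      r <- suppressWarnings(abs(stats::cor(G[, j], G[, near, drop = FALSE])))
      lt <- near[bp[near] < bp[j]]; rt <- near[bp[near] > bp[j]]
      ok_l <- any(r[match(lt, near)] >= min_r, na.rm = TRUE)
      ok_r <- any(r[match(rt, near)] >= min_r, na.rm = TRUE)
      if (ok_l && ok_r) {
        if (max_mutual_r > 0) {
          prev <- out[!is.na(out)]
          if (length(prev)) {
            rp <- abs(stats::cor(g$geno[, cols[j]],
                                 g$geno[, prev, drop = FALSE]))
            if (any(rp > max_mutual_r, na.rm = TRUE)) next
          }
        }
        out[ch] <- cols[j]
        break
      }
    }
  }
  out
}

#' Drop uninformative markers
#'
#' Keeps markers whose minor allele (the rarer of 0/1 among non-missing
#' strain calls) is carried by at least `min_minor_strains` strains.
#' Monomorphic markers (minor-allele count 0) are always dropped. Marker
#' order is preserved.
#'
#' @param g A `cc_geno`.
#' @param min_minor_strains Minimum strains carrying the minor allele (>= 1).
#' @return A filtered `cc_geno`.
#' @export
filter_informative <- function(g, min_minor_strains = 1) {
  stopifnot(inherits(g, "cc_geno"))
  if (!is.numeric(min_minor_strains) || min_minor_strains < 1) {
    stop("filter_informative: min_minor_strains must be >= 1")
  }
  n1 <- colSums(g$geno == 1L, na.rm = TRUE)
  n0 <- colSums(g$geno == 0L, na.rm = TRUE)
  keep <- pmin(n1, n0) >= min_minor_strains
  map <- g$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  new_cc_geno(g$geno[, keep, drop = FALSE],
              new_marker_map(map, attr(g$map, "chrom_lengths")))
}
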