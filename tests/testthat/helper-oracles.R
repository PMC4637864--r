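# Independent oracles used across tests. These deliberately avoid the code
# paths they check: direct formulas, brute-force scans, naive recomputation.

# Benjamini-Hochberg step-up, evaluated straight from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_stepup_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by direct summation of the pmf via choose().
hyper_tail_direct <- function(kA, kB, k_both, N) {
  lo <- max(0, kA + kB - N)
  hi <- min(kA, kB)
  if (k_both > hi) return(0)
  j <- max(k_both, lo):hi
  sum(choose(kA, j) * choose(N - kA, kB - j)) / choose(N, kB)
}

# Plain maximal-run scanner over a boolean track: maximal runs of TRUE with
# length >= min_run; returns list of index vectors.
maximal_runs <- function(hit, min_run) {
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_run) {
      out[[length(out) + 1]] <- starts[i]:ends[i]
    }
  }
  out
}

# O(n*m) all-pairs half-open interval intersection checker.
brute_overlap_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out <- rbind(out, data.frame(i = i, j = j))
      }
    }
  }
  out
}

# Naive per-position genotype lookup: linear scan over segments.
brute_project <- function(mosaics, map) {
  strains <- names(mosaics)
  geno <- matrix(NA_integer_, length(strains), nrow(map),
                 dimnames = list(strains, map$id))
  for (s in seq_along(strains)) {
    for (k in seq_len(nrow(map))) {
      cm <- mosaics[[s]][[map$chrom[k]]]
      pos0 <- map$bp[k] - 1
      seg <- 1
      while (pos0 >= cm$ends[seg]) seg <- seg + 1
      f <- cm$founder[seg]
      bit <- substr(map$sdp[k], f + 1, f + 1)
      geno[s, k] <- as.integer(bit == "1")
    }
  }
  geno
}
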