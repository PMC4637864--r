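make_pheno <- function(n_strains = 6, mice = 3, seed = 1) {
  set.seed(seed)
  strains <- sprintf("CC%03d", 1:n_strains)
  df <- expand.grid(strain = strains, sex = c("F", "M"),
                    rep = seq_len(mice), stringsAsFactors = FALSE)
  df$animal_id <- sprintf("A%04d", seq_len(nrow(df)))
  df$t1 <- rnorm(nrow(df), 20, 3)
  df$t2 <- rnorm(nrow(df), 15, 4)
  df[, c("animal_id", "strain", "sex", "t1", "t2")]
}

test_that("strain summaries equal a naive recomputation", {
  ph <- make_pheno(seed = 11)
  s <- summarize_strains(ph, c("t1", "t2"))
  expect_equal(sum(s$per_strain_sex$n), nrow(ph))
  for (i in sample(nrow(s$per_strain_sex), 5)) {
    row <- s$per_strain_sex[i, ]
    sel <- ph$strain == row$strain & ph$sex == row$sex
    expect_equal(row$t1_mean, mean(ph$t1[sel]))
    expect_equal(row$t1_sd, sd(ph$t1[sel]))
    expect_equal(row$t2_mean, mean(ph$t2[sel]))
  }
  # cross-sex Pearson over strain means, recomputed by hand
  fm <- tapply(ph$t1[ph$sex == "F"], ph$strain[ph$sex == "F"], mean)
  mm <- tapply(ph$t1[ph$sex == "M"], ph$strain[ph$sex == "M"], mean)
  expect_equal(unname(s$cross_sex_pearson["t1"]),
               cor(fm, mm[names(fm)]))
  for (sx in c("F", "M")) {
    sel <- ph$sex == sx
    expect_equal(unname(s$spearman_between_traits[sx]),
                 cor(ph$t1[sel], ph$t2[sel], method = "spearman"))
  }
})

test_that("degenerate correlation patterns are reproduced exactly", {
  ph <- make_pheno(seed = 12)
  # identical male and female values per animal index -> strain means equal
  ph$t1[ph$sex == "M"] <- ph$t1[ph$sex == "F"]
  s <- summarize_strains(ph, c("t1", "t2"))
  expect_equal(unname(s$cross_sex_pearson["t1"]), 1)
  ph2 <- make_pheno(seed = 13)
  ph2$t2 <- -ph2$t1
  s2 <- summarize_strains(ph2, c("t1", "t2"))
  expect_equal(unname(s2$spearman_between_traits), c(-1, -1))
})

test_that("single-sex strains are excluded from the cross-sex statistic", {
  ph <- make_pheno(seed = 14)
  ph <- ph[!(ph$strain == "CC001" & ph$sex == "M"), ]
  s <- summarize_strains(ph, c("t1", "t2"))
  expect_equal(s$excluded_strains, "CC001")
  expect_false(anyNA(s$cross_sex_pearson))
})

test_that("interval intersection honours half-open semantics", {
  a <- toy_loci("chr1", 10, 20, trait = "tA")
  b <- toy_loci("chr1", 20, 30, trait = "tB")
  expect_equal(nrow(intersect_loci(a, b)), 0)
  b2 <- toy_loci("chr1", 19, 30, trait = "tB")
  got <- intersect_loci(a, b2)
  expect_equal(nrow(got), 1)
  expect_equal(got$int_start, 19)
  expect_equal(got$int_end, 20)
})

test_that("interval intersection matches the brute-force all-pairs checker", {
  set.seed(500)
  for (rep in 1:20) {
    nA <- sample(3:12, 1); nB <- sample(3:12, 1)
    mk <- function(n, trait) {
      start <- sample(0:90, n) * 1e5
      toy_loci(sample(paste0("chr", 1:3), n, replace = TRUE),
               start, start + sample(1:30, n) * 1e5, trait = trait)
    }
    a <- mk(nA, "tA"); b <- mk(nB, "tB")
    got <- intersect_loci(a, b)
    ref <- brute_overlap_pairs(a, b)
    expect_equal(nrow(got), if (is.null(ref)) 0 else nrow(ref))
    if (!is.null(ref)) {
      expect_setequal(paste(got$locusA, got$locusB),
                      paste(a$locus_id[ref$i], b$locus_id[ref$j]))
    }
  }
})

test_that("hypergeometric overlap test matches closed-form cases", {
  expect_equal(overlap_test(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(overlap_test(5, 5, 0, 20), 1)
  expect_error(overlap_test(3, 3, 4, 20), "k_both")
  expect_error(overlap_test(25, 3, 2, 20), "<= N")
})

test_that("overlap test is symmetric and monotone in the overlap count", {
  set.seed(501)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    kA <- sample(1:N, 1); kB <- sample(1:N, 1)
    hi <- min(kA, kB)
    k <- sample(0:hi, 1)
    expect_equal(overlap_test(kA, kB, k, N), overlap_test(kB, kA, k, N))
    p <- vapply(0:hi, function(j) overlap_test(kA, kB, j, N), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("permutation null is seeded, handles empty input, and flags oversized loci", {
  lens <- c(chr1 = 1e7, chr2 = 1e7)
  a <- toy_loci(c("chr1", "chr2"), c(1e6, 2e6), c(2e6, 3e6), trait = "tA")
  b <- toy_loci(c("chr1", "chr2"), c(1.5e6, 5e6), c(2.5e6, 6e6),
                trait = "tB")
  r1 <- permutation_overlap_null(a, b, lens, n_perm = 200, seed = 7)
  r2 <- permutation_overlap_null(a, b, lens, n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p > 0 && r1$p <= 1)

  empty <- a[0, ]; class(empty) <- c("cc_loci", "data.frame")
  expect_equal(permutation_overlap_null(empty, b, lens, 100, 1)$p, 1)

  huge <- toy_loci("chr1", 0, 2e7, trait = "tA")
  expect_error(permutation_overlap_null(huge, b, lens, 100, 1), "longer")
})

test_that("identical dense loci lists give a small permutation p", {
  lens <- c(chr1 = 200e6)
  a <- toy_loci("chr1", c(10e6, 80e6, 150e6),
                c(12e6, 82e6, 152e6), trait = "tA")
  b <- a
  b$trait <- "tB"
  r <- permutation_overlap_null(a, b, lens, n_perm = 1000, seed = 3)
  expect_equal(r$observed, 3L)
  expect_lte(r$p, 0.05)
})

test_that("permutation and hypergeometric nulls agree on a binned genome", {
  # unit-width loci on an integer chromosome of N slots make uniform
  # placement equivalent to sampling a random subset of N bins
  N <- 20
  lens <- c(chr1 = N)
  a_pos <- c(2, 5, 11, 17)
  b_pos <- c(2, 5, 9, 13, 17)
  a <- toy_loci("chr1", a_pos, a_pos + 1, trait = "tA")
  b <- toy_loci("chr1", b_pos, b_pos + 1, trait = "tB")
  obs <- length(intersect(a_pos, b_pos))
  p_hyper <- overlap_test(nrow(a), nrow(b), obs, N)
  r <- permutation_overlap_null(a, b, lens, n_perm = 4000, seed = 11)
  mc_se <- sqrt(p_hyper * (1 - p_hyper) / 4000)
  expect_lt(abs(r$p - p_hyper), 3 * mc_se + 2 / 4000)
})

test_that("direction concordance reads the sign at the shared peak", {
  classes <- c("none", rep("significant", 3), "none")
  s1 <- toy_scan(classes, neglogp = c(1, 25, 30, 25, 1),
                 effect = c(0, 2, 2, 2, 0), trait = "t1")
  s2 <- toy_scan(classes, neglogp = c(1, 24, 28, 24, 1),
                 effect = c(0, -2, -2, -2, 0), trait = "t2")
  pair <- list(chrom = "chr1", int_start = 1e6, int_end = 5e6)
  expect_equal(direction_concordance(s1, s2, pair), "discordant")
  s2$effect <- abs(s2$effect)
  expect_equal(direction_concordance(s1, s2, pair), "concordant")
  expect_error(direction_concordance(s1, s2,
                                     list(chrom = "chr9", int_start = 0,
                                          int_end = 1e6)),
               "no markers")
})

test_that("planted opposite-sign loci are called discordant end to end", {
  layout <- tiny_layout(n_chrom = 2, len = 80e6)
  arch <- trait_architecture(
    traits = list(t1 = list(mu = 0, sex_effect = 0, loci = NULL),
                  t2 = list(mu = 0, sex_effect = 0, loci = NULL)),
    shared = data.frame(chrom = "chr1", bp = 40e6, beta1 = 3, beta2 = -3),
    sigma_strain = c(t1 = 0, t2 = 0), sigma_animal = c(t1 = 1, t2 = 1),
    mice_per_strain_per_sex = 4
  )
  g <- sim_geno(layout, n_strains = 50, seed = 601)
  ph <- simulate_phenotypes(g, arch, seed = 602)
  s1 <- genome_scan(g, ph, "t1")
  s2 <- genome_scan(g, ph, "t2")
  l1 <- call_significant(s1)
  l2 <- call_significant(s2)
  pairs <- intersect_loci(l1, l2)
  expect_gte(nrow(pairs), 1)
  dirs <- vapply(seq_len(nrow(pairs)), function(i) {
    direction_concordance(s1, s2, pairs[i, ])
  }, character(1))
  expect_true(all(dirs == "discordant"))
})
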