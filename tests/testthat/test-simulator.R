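test_that("mosaic segments tile each chromosome exactly and labels are valid", {
  layout <- tiny_layout(n_chrom = 3, rho = 0.2)
  mos <- simulate_mosaics(layout, 25, seed = 11)
  for (s in seq_along(mos)) {
    for (ch in layout$chrom$name) {
      cm <- mos[[s]][[ch]]
      L <- layout$chrom$length[layout$chrom$name == ch]
      expect_equal(cm$ends[length(cm$ends)], L)
      expect_true(all(diff(cm$ends) > 0))
      expect_true(all(cm$founder %in% 0:7))
      if (length(cm$founder) > 1) {
        expect_true(all(diff(cm$founder) != 0))
      }
    }
  }
})

test_that("zero recombination gives exactly one segment per chromosome", {
  mos <- simulate_mosaics(tiny_layout(rho = 0), 10, seed = 2)
  lens <- vapply(mos, function(m) length(m$chr1$founder), integer(1))
  expect_true(all(lens == 1L))
})

test_that("mean segment count matches the Poisson expectation 1 + rho*L", {
  # rho = 0.05/Mb, L = 100 Mb -> mean 6; SE of the mean over 1000 strains
  # is sqrt(5/1000)
  layout <- genome_layout(c(chr1 = 100e6), recomb_rate = 0.05)
  mos <- simulate_mosaics(layout, 1000, seed = 3)
  segs <- vapply(mos, function(m) length(m$chr1$founder), integer(1))
  se <- sqrt(5 / 1000)
  expect_lt(abs(mean(segs) - 6), 3 * se)
})

test_that("mosaic simulation is deterministic given the seed", {
  layout <- tiny_layout()
  expect_identical(simulate_mosaics(layout, 5, seed = 9),
                   simulate_mosaics(layout, 5, seed = 9))
  expect_error(simulate_mosaics(genome_layout(c(chr1 = -1)), 5, seed = 1),
               "positive")
})

test_that("marker projection matches the brute-force segment lookup", {
  layout <- tiny_layout(n_chrom = 2, len = 20e6, density = 3, rho = 0.3)
  mos <- simulate_mosaics(layout, 12, seed = 21)
  map <- simulate_marker_map(layout, seed = 22, sdp_share = 0.5)
  g <- project_markers(mos, map)
  expect_identical(g$geno, brute_project(mos, map))
  # idempotence
  expect_identical(project_markers(mos, map)$geno, g$geno)
})

test_that("projection applies the SDP definition and rejects bad chromosomes", {
  layout <- genome_layout(c(chr1 = 10e6), recomb_rate = 0)
  mos <- simulate_mosaics(layout, 6, seed = 5)
  founders <- vapply(mos, function(m) m$chr1$founder[1], integer(1))
  target <- founders[1]
  sdp <- paste(as.integer(0:7 == target), collapse = "")
  map <- ccqtl:::new_marker_map(
    data.frame(id = "mk1", chrom = "chr1", bp = 5e6, sdp = sdp),
    c(chr1 = 10e6))
  g <- project_markers(mos, map)
  expect_identical(unname(g$geno[, 1]), as.integer(founders == target))

  bad <- ccqtl:::new_marker_map(
    data.frame(id = "mk1", chrom = "chrX", bp = 5e6, sdp = sdp), NULL)
  expect_error(project_markers(mos, bad), "unknown chromosome")
})

test_that("with rho = 0 strains sharing a founder have identical rows", {
  layout <- tiny_layout(rho = 0)
  mos <- simulate_mosaics(layout, 30, seed = 7)
  map <- simulate_marker_map(layout, seed = 8)
  g <- project_markers(mos, map)
  key <- vapply(mos, function(m) {
    paste(vapply(m, function(cm) cm$founder[1], integer(1)), collapse = "/")
  }, character(1))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) > 1) {
      for (r in rows[-1]) {
        expect_identical(g$geno[rows[1], ], g$geno[r, ])
      }
    }
  }
})

test_that("informative-marker filter equals a direct recount", {
  g <- sim_geno(n_strains = 16, seed = 31, sdp_share = 0)
  for (thr in c(1, 2, 4)) {
    kept <- filter_informative(g, thr)
    n1 <- colSums(g$geno == 1L)
    n0 <- colSums(g$geno == 0L)
    expect_identical(kept$map$id, g$map$id[pmin(n1, n0) >= thr])
  }
  # a monomorphic column is always removed
  g2 <- g
  g2$geno[, 3] <- 0L
  expect_false(g$map$id[3] %in% filter_informative(g2, 1)$map$id)
})

test_that("noiseless phenotypes are exactly additive in sex and allele", {
  g <- sim_geno(n_strains = 12, seed = 41)
  arch0 <- one_locus_arch(beta = 0, mu = 7, sex_effect = 2)
  ph <- simulate_phenotypes(g, arch0, seed = 42)
  expect_true(all(ph$t1[ph$sex == "F"] == 7))
  expect_true(all(ph$t1[ph$sex == "M"] == 9))

  arch5 <- one_locus_arch(beta = 5, mu = 0)
  ph5 <- simulate_phenotypes(g, arch5, seed = 43)
  truth <- attr(ph5, "truth")
  a <- g$geno[match(ph5$strain, g$strains), truth$marker_id[1]]
  means <- tapply(ph5$t1, a, mean)
  expect_equal(unname(means["1"] - means["0"]), 5)
})

test_that("opposite-sign shared loci force a negative strain-level correlation", {
  layout <- tiny_layout(n_chrom = 2, len = 60e6)
  arch <- trait_architecture(
    traits = list(t1 = list(mu = 0, sex_effect = 0, loci = NULL),
                  t2 = list(mu = 0, sex_effect = 0, loci = NULL)),
    shared = data.frame(chrom = c("chr1", "chr2"), bp = c(30e6, 30e6),
                        beta1 = c(3, 2.5), beta2 = c(-3, -2.5)),
    sigma_strain = c(t1 = 0.5, t2 = 0.5),
    sigma_animal = c(t1 = 1, t2 = 1),
    mice_per_strain_per_sex = 3
  )
  neg <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    g <- sim_geno(layout, n_strains = 50, seed = 5000 + 7 * s)
    ph <- simulate_phenotypes(g, arch, seed = 6000 + s)
    m1 <- tapply(ph$t1, ph$strain, mean)
    m2 <- tapply(ph$t2, ph$strain, mean)
    if (cor(m1, m2, method = "spearman") < 0) neg <- neg + 1
  }
  expect_gte(neg / n_seeds, 0.95)
})

test_that("per-strain mean variance matches sigma_u^2 + sigma_e^2 / n_mice", {
  layout <- genome_layout(c(chr1 = 10e6), marker_density = 1)
  g <- sim_geno(layout, n_strains = 40, seed = 51)
  su <- 0.7; se <- 1.2; mice <- 4
  arch <- one_locus_arch(beta = 0, sigma_strain = su, sigma_animal = se,
                         mice = mice)
  target <- su^2 + se^2 / (2 * mice)
  vs <- vapply(1:200, function(s) {
    ph <- simulate_phenotypes(g, arch, seed = 7000 + s)
    var(tapply(ph$t1, ph$strain, mean))
  }, numeric(1))
  mc_se <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - target), 3 * mc_se)
})

test_that("trial averaging shrinks replicate variance by the trial count", {
  layout <- genome_layout(c(chr1 = 10e6))
  g <- sim_geno(layout, n_strains = 30, seed = 61)
  base <- list(mu = 0, sex_effect = 0, loci = NULL)
  arch <- trait_architecture(
    traits = list(t1 = base, t2 = base),
    sigma_strain = c(t1 = 0, t2 = 0), sigma_animal = c(t1 = 0, t2 = 0),
    mice_per_strain_per_sex = 20,
    trials_range = c(4L, 4L), trial_sd = 2, averaged_trait = "t2"
  )
  vs <- vapply(1:80, function(s) {
    var(simulate_phenotypes(g, arch, seed = 8000 + s)$t2)
  }, numeric(1))
  target <- 2^2 / 4
  expect_lt(abs(mean(vs) - target), 4 * sd(vs) / sqrt(length(vs)))
})

test_that("architecture validation enforces its invariants", {
  expect_error(trait_architecture(
    traits = list(t1 = list(mu = 0, sex_effect = 0, loci = NULL),
                  t2 = list(mu = 0, sex_effect = 0, loci = NULL)),
    shared = data.frame(chrom = "chr1", bp = 1e6, beta1 = 2, beta2 = 1),
    sigma_strain = c(t1 = 1, t2 = 1), sigma_animal = c(t1 = 1, t2 = 1)),
    "opposite-sign")
  expect_error(trait_architecture(
    traits = list(t1 = list(mu = 0, sex_effect = 0, loci = NULL),
                  t2 = list(mu = 0, sex_effect = 0, loci = NULL)),
    sigma_strain = c(t1 = 0, t2 = 0), sigma_animal = c(t1 = 0, t2 = 0)),
    "empty architecture")
})

test_that("planted bp positions snap to the nearest marker, ties leftward", {
  map <- ccqtl:::new_marker_map(
    data.frame(id = c("a", "b", "c"), chrom = "chr1",
               bp = c(100, 200, 400), sdp = "10000000"),
    c(chr1 = 1000))
  expect_equal(snap_to_marker(map, "chr1", 140), 1)
  expect_equal(snap_to_marker(map, "chr1", 150), 1)  # tie -> left
  expect_equal(snap_to_marker(map, "chr1", 301), 3)
  expect_error(snap_to_marker(map, "chr9", 100), "no markers")
})
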