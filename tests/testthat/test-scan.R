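test_that("bh_fdr reproduces the step-up formula and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(101)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_direct(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("fit_marker matches a textbook two-sample t-test", {
  a <- c(0, 0, 0, 1, 1, 1)
  y <- c(1, 2, 3, 4, 5, 6)
  f <- fit_marker(a, y, sex = NULL, cfg = scan_config(sex_handling = "pooled"))
  # hand-rolled pooled-variance t statistic
  m0 <- mean(y[a == 0]); m1 <- mean(y[a == 1])
  sp <- sqrt((sum((y[a == 0] - m0)^2) + sum((y[a == 1] - m1)^2)) / 4)
  tt <- (m1 - m0) / (sp * sqrt(1 / 3 + 1 / 3))
  p_ref <- 2 * pt(-abs(tt), df = 4)
  expect_equal(f$p, p_ref, tolerance = 1e-12)
  expect_equal(f$effect, m1 - m0, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged instead of erroring", {
  f <- fit_marker(c(0, 0, 1, 1), c(5, 5, 5, 5))
  expect_equal(f$p, 1)
  expect_equal(f$note, "zero-variance")
  f2 <- fit_marker(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_equal(f2$p, 1)
  expect_equal(f2$effect, 0)
  expect_equal(f2$note, "non-informative")
})

test_that("p-values are uniform when alleles are independent of the trait", {
  set.seed(202)
  n <- 200
  m <- 10000
  A <- matrix(rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(1:m, each = n)]), n, m)
  y <- rnorm(n)
  eng <- ccqtl:::assoc_linear_engine(A, y, matrix(1, n, 1))
  D <- suppressWarnings(ks.test(eng$p, "punif"))$statistic
  expect_lt(unname(D), 1.628 / sqrt(m))  # 1% critical value
})

test_that("a pure sex shift does not distort null p-values under the covariate model", {
  set.seed(203)
  n <- 200
  m <- 5000
  sex <- rep(c("F", "M"), each = n / 2)
  A <- matrix(rbinom(n * m, 1, 0.5), n, m)
  y <- rnorm(n) + 3 * (sex == "M")
  X0 <- cbind(1, as.numeric(sex == "M"))
  eng <- ccqtl:::assoc_linear_engine(A, y, X0)
  D <- suppressWarnings(ks.test(eng$p, "punif"))$statistic
  expect_lt(unname(D), 1.628 / sqrt(m))
})

test_that("genome_scan agrees with per-marker lm fits", {
  g <- sim_geno(n_strains = 15, seed = 71)
  arch <- one_locus_arch(beta = 2, sigma_strain = 0.3, sigma_animal = 1,
                         sex_effect = 1.5, mice = 3)
  ph <- simulate_phenotypes(g, arch, seed = 72)
  sc <- genome_scan(g, ph, "t1")
  expect_identical(sc$marker_id, g$map$id)
  expect_true(all(sc$q >= sc$p - 1e-15))
  idx <- seq(1, nrow(sc), length.out = 25)
  A <- g$geno[match(ph$strain, g$strains), ]
  for (j in round(idx)) {
    ref <- fit_marker(A[, j], ph$t1, ph$sex, scan_config())
    expect_equal(sc$effect[j], ref$effect, tolerance = 1e-8)
    expect_equal(sc$p[j], max(ref$p, .Machine$double.xmin),
                 tolerance = 1e-8)
  }
})

test_that("scans are scale-equivariant", {
  g <- sim_geno(n_strains = 12, seed = 81)
  arch <- one_locus_arch(beta = 1, sigma_strain = 0.2, sigma_animal = 0.8)
  ph <- simulate_phenotypes(g, arch, seed = 82)
  s1 <- genome_scan(g, ph, "t1")
  ph2 <- ph
  ph2$t1 <- ph$t1 * 10
  s2 <- genome_scan(g, ph2, "t1")
  expect_equal(s2$p, s1$p, tolerance = 1e-9)
  expect_equal(s2$effect, 10 * s1$effect, tolerance = 1e-9)
})

test_that("missing genotypes drop animals at that marker only", {
  g <- sim_geno(n_strains = 15, seed = 91)
  g$geno[1:3, 5] <- NA_integer_
  arch <- one_locus_arch(beta = 1, sigma_animal = 1)
  ph <- simulate_phenotypes(g, arch, seed = 92)
  sc <- genome_scan(g, ph, "t1")
  n_animals <- nrow(ph)
  expect_equal(sc$n[5], n_animals - 3 * 2 * 4)
  expect_true(all(sc$n[-5] == n_animals))
  A <- g$geno[match(ph$strain, g$strains), ]
  ref <- fit_marker(A[, 5], ph$t1, ph$sex, scan_config())
  expect_equal(sc$p[5], ref$p, tolerance = 1e-8)
})

test_that("permuting trait values destroys a planted peak", {
  g <- sim_geno(n_strains = 40, seed = 93)
  arch <- one_locus_arch(beta = 3, sigma_animal = 1, mice = 5)
  ph <- simulate_phenotypes(g, arch, seed = 94)
  sc <- genome_scan(g, ph, "t1")
  expect_gt(max(sc$neglog10p), 20)
  set.seed(95)
  ph$t1 <- sample(ph$t1)
  sc_perm <- genome_scan(g, ph, "t1")
  expect_lt(max(sc_perm$neglog10p), 10)
})

test_that("animal-level scans outgun strain-mean scans on a planted effect", {
  g <- sim_geno(n_strains = 30, seed = 96)
  arch <- one_locus_arch(beta = 2, sigma_animal = 1.5, mice = 5)
  diff <- vapply(1:5, function(s) {
    ph <- simulate_phenotypes(g, arch, seed = 960 + s)
    truth <- attr(ph, "truth")
    j <- match(truth$marker_id[1], g$map$id)
    a <- genome_scan(g, ph, "t1", scan_config(unit = "animal"))
    m <- genome_scan(g, ph, "t1", scan_config(unit = "strain_mean"))
    a$neglog10p[j] - m$neglog10p[j]
  }, numeric(1))
  expect_gt(mean(diff), 0)
})

test_that("per-sex scans return one calibrated result per sex", {
  g <- sim_geno(n_strains = 15, seed = 97)
  arch <- one_locus_arch(beta = 2, sigma_animal = 1, sex_effect = 2)
  ph <- simulate_phenotypes(g, arch, seed = 98)
  out <- genome_scan(g, ph, "t1", scan_config(sex_handling = "per_sex"))
  expect_named(out, c("F", "M"))
  expect_equal(unique(out$F$n), sum(ph$sex == "F"))
  expect_equal(unique(out$M$n), sum(ph$sex == "M"))
})

test_that("logistic-on-dichotomized mode ranks a strong planted locus first", {
  g <- sim_geno(n_strains = 30, seed = 99)
  arch <- one_locus_arch(beta = 4, sigma_animal = 1, mice = 4)
  ph <- simulate_phenotypes(g, arch, seed = 100)
  sc <- genome_scan(g, ph, "t1",
                    scan_config(model = "logistic_dichotomized"))
  truth <- attr(ph, "truth")
  j <- which.max(sc$neglog10p)
  expect_equal(sc$chrom[j], truth$chrom[1])
  expect_lt(abs(sc$bp[j] - truth$marker_bp[1]), 10e6)
})

test_that("BH at q < 0.05 controls the realized false-discovery proportion", {
  set.seed(301)
  n <- 60; m <- 150
  fdp <- vapply(1:200, function(s) {
    A <- matrix(rbinom(n * m, 1, 0.5), n, m)
    y <- rnorm(n)
    eng <- ccqtl:::assoc_linear_engine(A, y, matrix(1, n, 1))
    q <- bh_fdr(eng$p)
    if (any(q < 0.05)) 1 else 0   # every discovery is false under the null
  }, numeric(1))
  mc_se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
})

test_that("significance classes follow the configured thresholds", {
  nlp <- c(25, 15, 5, 21)
  nlq <- c(22, 12, 3, 10)
  cls <- ccqtl:::classify_markers(nlp, nlq, scan_config())
  expect_equal(cls, c("significant", "suggestive", "none", "suggestive"))
  expect_error(genome_scan(sim_geno(n_strains = 5, seed = 1),
                           data.frame(strain = "CC001", sex = "F", x = 1),
                           "nope"),
               "unknown trait")
})
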