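# Small reusable simulation fixtures, built in code at test time.

tiny_layout <- function(n_chrom = 2, len = 50e6, density = 2, rho = 0.05) {
  genome_layout(stats::setNames(rep(len, n_chrom), paste0("chr", 1:n_chrom)),
                marker_density = density, recomb_rate = rho)
}

# two-trait architecture with a single configurable locus on trait 1
one_locus_arch <- function(chrom = "chr1", bp = 25e6, beta = 3,
                           sigma_strain = 0, sigma_animal = 0,
                           mice = 4, sex_effect = 0, mu = 10) {
  trait_architecture(
    traits = list(
      t1 = list(mu = mu, sex_effect = sex_effect,
                loci = data.frame(chrom = chrom, bp = bp, beta = beta)),
      t2 = list(mu = mu, sex_effect = 0, loci = NULL)
    ),
    sigma_strain = c(t1 = sigma_strain, t2 = sigma_strain),
    sigma_animal = c(t1 = sigma_animal, t2 = sigma_animal),
    mice_per_strain_per_sex = mice
  )
}

sim_geno <- function(layout = tiny_layout(), n_strains = 20, seed = 1,
                     min_minor = 1, sdp_share = 0.9) {
  mos <- simulate_mosaics(layout, n_strains, seed = seed)
  map <- simulate_marker_map(layout, seed = seed + 1, sdp_share = sdp_share)
  filter_informative(project_markers(mos, map), min_minor)
}

# hand-built scan data.frame for caller tests: one chromosome, evenly
# spaced markers, classes given directly
toy_scan <- function(classes, chrom = "chr1", spacing = 1e6,
                     neglogp = NULL, effect = NULL, trait = "t1",
                     chrom_len = (length(classes) + 1) * spacing) {
  n <- length(classes)
  if (is.null(neglogp)) {
    neglogp <- ifelse(classes == "significant", 25,
                      ifelse(classes == "suggestive", 12, 1))
  }
  if (is.null(effect)) effect <- rep(1, n)
  df <- data.frame(
    marker_id = sprintf("m%03d", seq_len(n)), chrom = chrom,
    bp = spacing * seq_len(n), trait = trait, n = 100,
    effect = effect, p = 10^(-neglogp), q = 10^(-neglogp),
    neglog10p = neglogp, neglog10q = neglogp, class = classes,
    note = "ok", stringsAsFactors = FALSE
  )
  structure(df, class = c("cc_scan", "data.frame"),
            config = scan_config(), trait = trait,
            chrom_lengths = stats::setNames(chrom_len, chrom),
            p_floor = .Machine$double.xmin)
}

# loci table builder for cross-trait / enrichment tests
toy_loci <- function(chrom, start, end, trait = "tA",
                     class = "significant") {
  n <- max(length(chrom), length(start))
  df <- data.frame(
    trait = trait, chrom = chrom, start = start, end = end,
    n_markers = 3L, peak_marker = sprintf("pk%02d", seq_len(n)),
    peak_bp = (start + end) / 2, peak_neglog10p = 25,
    peak_effect = 1, effect_sign = 1, class = class,
    locus_id = sprintf("%s_%02d", trait, seq_len(n)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("cc_loci", "data.frame"))
}
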