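#' Two-trait genetic architecture for phenotype simulation
#'
#' Encodes the generative model for a pair of quantitative traits measured
#' on a recombinant inbred panel: per-trait intercept, additive sex effect,
#' trait-specific planted loci, a shared set of pleiotropic loci constrained
#' to opposite-sign effects on the two traits, a strain-level random effect,
#' animal-level replicate noise, and (for the trait named in
#' `averaged_trait`) trial-level noise averaged over a random number of
#' trials per animal.
#'
#' @param traits Named list of exactly two per-trait specifications, each a
#'   list with `mu` (intercept, trait units), `sex_effect` (additive shift
#'   for males), and `loci` (data.frame with `chrom`, `bp`, `beta`; may have
#'   zero rows).
#' @param shared data.frame of pleiotropic loci with columns `chrom`, `bp`,
#'   `beta1`, `beta2` (effects on the first and second trait); every row
#'   must satisfy `beta1 * beta2 < 0` (opposite sign). May have zero rows.
#' @param sigma_strain Named numeric, per-trait strain random-effect SD
#'   (>= 0).
#' @param sigma_animal Named numeric, per-trait animal-level noise SD (>= 0).
#' @param mice_per_strain_per_sex Animals simulated per strain per sex.
#' @param trials_range Integer length-2 range for the number of trials per
#'   animal of the averaged trait (default 3-5, mean ~3.3 matching common
#'   accelerating-rotarod protocols).
#' @param trial_sd Trial-level noise SD for the averaged trait.
#' @param averaged_trait Name of the trait reported as a mean over trials,
#'   or `NA` for none.
#'
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(traits, shared = NULL,
                               sigma_strain, sigma_animal,
                               mice_per_strain_per_sex = 11,
                               trials_range = c(3L, 5L),
                               trial_sd = 0,
                               averaged_trait = NA_character_) {
  if (length(traits) != 2 || is.null(names(traits))) {
    stop("trait_architecture: exactly two named traits are required")
  }
  tn <- names(traits)
  for (t in tn) {
    tr <- traits[[t]]
    stopifnot(is.numeric(tr$mu), is.numeric(tr$sex_effect))
    if (is.null(tr$loci)) {
      traits[[t]]$loci <- data.frame(chrom = character(), bp = numeric(),
                                     beta = numeric())
    } else {
      stopifnot(all(c("chrom", "bp", "beta") %in% names(tr$loci)))
    }
  }
  if (is.null(shared)) {
    shared <- data.frame(chrom = character(), bp = numeric(),
                         beta1 = numeric(), beta2 = numeric())
  }
  stopifnot(all(c("chrom", "bp", "beta1", "beta2") %in% names(shared)))
  if (nrow(shared) && any(shared$beta1 * shared$beta2 >= 0)) {
    stop("trait_architecture: shared pleiotropic loci must have ",
         "opposite-sign effects on the two traits")
  }
  sigma_strain <- sigma_strain[tn]
  sigma_animal <- sigma_animal[tn]
  if (anyNA(sigma_strain) || anyNA(sigma_animal) ||
      any(sigma_strain < 0) || any(sigma_animal < 0)) {
    stop("trait_architecture: sigma_strain/sigma_animal must be named, ",
         "non-negative, and cover both traits")
  }
  stopifnot(length(trials_range) == 2, trials_range[1] >= 1,
            trials_range[2] >= trials_range[1], trial_sd >= 0,
            mice_per_strain_per_sex >= 1)
  if (!is.na(averaged_trait) && !averaged_trait %in% tn) {
    stop("trait_architecture: averaged_trait must be one of the trait names")
  }
  if (nrow(shared) + nrow(traits[[1]]$loci) + nrow(traits[[2]]$loci) == 0 &&
      all(sigma_strain == 0) && all(sigma_animal == 0) && trial_sd == 0 &&
      all(vapply(traits, function(x) x$mu == 0 && x$sex_effect == 0,
                 logical(1)))) {
    stop("trait_architecture: empty architecture (no effects, no noise)")
  }
  structure(
    list(traits = traits, shared = shared,
         sigma_strain = sigma_strain, sigma_animal = sigma_animal,
         mice_per_strain_per_sex = as.integer(mice_per_strain_per_sex),
         trials_range = as.integer(trials_range), trial_sd = trial_sd,
         averaged_trait = averaged_trait),
    class = "trait_architecture"
  )
}

#' Default body-weight / rotarod architecture
#'
#' A two-trait architecture emulating a Collaborative Cross cohort: body
#' weight (g) and rotarod speed at fall (rpm), two shared pleiotropic loci
#' with opposite-sign effects (heavier allele, slower fall speed), two
#' weight-only and three rotarod-only loci, a male weight shift, strain and
#' animal noise on realistic scales, and rotarod reported as the mean of 3-5
#' trials. Loci are placed mid-chromosome on distinct chromosomes so called
#' intervals are unambiguous. The residual strain-level SD is kept modest
#' relative to the animal-level SD so that planted loci, not chance
#' correlations between markers and strain background, dominate an
#' animal-level scan on panels of a few dozen strains; the vignette
#' discusses how larger strain variance reproduces the ghost-peak
#' inflation seen in small panels.
#'
#' @param layout A [genome_layout()]; loci are placed on its chromosomes.
#' @param mice_per_strain_per_sex Animals per strain per sex (default 11,
#'   i.e. ~22 mice/strain).
#' @return A `trait_architecture`.
#' @export
default_architecture <- function(layout = default_genome(),
                                 mice_per_strain_per_sex = 11) {
  ch <- layout$chrom$name
  mid <- function(i) round(layout$chrom$length[i] / 2)
  pick <- function(k) ch[pmin(k, length(ch))]
  shared <- data.frame(
    chrom = pick(c(1, 4)), bp = c(mid(1), mid(min(4, length(ch)))),
    beta1 = c(3.5, 3.0), beta2 = c(-5.5, -5.0)
  )
  # deliberately sub-threshold: flavour loci that shape the strain means
  # without competing with the shared loci for genome-wide significance
  w_only <- data.frame(
    chrom = pick(c(11, 18)), bp = c(mid(min(11, length(ch))),
                                    mid(min(18, length(ch)))),
    beta = c(1.2, 1.2)
  )
  r_only <- data.frame(
    chrom = pick(c(5, 13)),
    bp = c(mid(min(5, length(ch))), mid(min(13, length(ch)))),
    beta = c(2.0, 2.0)
  )
  trait_architecture(
    traits = list(
      weight_g = list(mu = 20, sex_effect = 5, loci = w_only),
      rotarod_rpm = list(mu = 18, sex_effect = 0, loci = r_only)
    ),
    shared = shared,
    sigma_strain = c(weight_g = 0.5, rotarod_rpm = 0.8),
    sigma_animal = c(weight_g = 1.5, rotarod_rpm = 2.5),
    mice_per_strain_per_sex = mice_per_strain_per_sex,
    trials_range = c(3L, 5L),
    trial_sd = 3,
    averaged_trait = "rotarod_rpm"
  )
}

#' Snap genomic positions to the nearest marker
#'
#' Ties (equidistant markers) snap to the left (smaller-bp) marker.
#'
#' @param map A `marker_map`.
#' @param chrom,bp Parallel vectors of target positions.
#' @return Integer row indices into `map`.
#' @export
snap_to_marker <- function(map, chrom, bp) {
  stopifnot(length(chrom) == length(bp))
  vapply(seq_along(chrom), function(i) {
    rows <- which(map$chrom == chrom[i])
    if (!length(rows)) {
      stop("snap_to_marker: no markers on chromosome ", chrom[i])
    }
    d <- abs(map$bp[rows] - bp[i])
    rows[which(d == min(d))[1]]   # ties -> leftmost (rows are bp-sorted)
  }, integer(1))
}

#' Planted truth table of an architecture
#'
#' @param arch A `trait_architecture`.
#' @return data.frame with `trait`, `chrom`, `bp`, `beta` — one row per
#'   planted (trait, locus) effect, shared loci expanded to both traits.
#' @export
planted_truth <- function(arch) {
  tn <- names(arch$traits)
  rows <- list()
  for (t in tn) {
    l <- arch$traits[[t]]$loci
    if (nrow(l)) {
      rows[[length(rows) + 1]] <- data.frame(trait = t, chrom = l$chrom,
                                             bp = l$bp, beta = l$beta)
    }
  }
  if (nrow(arch$shared)) {
    rows[[length(rows) + 1]] <- data.frame(trait = tn[1],
                                           chrom = arch$shared$chrom,
                                           bp = arch$shared$bp,
                                           beta = arch$shared$beta1)
    rows[[length(rows) + 1]] <- data.frame(trait = tn[2],
                                           chrom = arch$shared$chrom,
                                           bp = arch$shared$bp,
                                           beta = arch$shared$beta2)
  }
  if (!length(rows)) {
    return(data.frame(trait = character(), chrom = character(),
                      bp = numeric(), beta = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a phenotype table from genotypes and an architecture
#'
#' Generates one record per animal. For each trait the animal-level value is
#' `mu + sex_effect * I(male) + sum_k beta_k * allele(strain, k) + u_strain +
#' eps_animal`, with `u ~ N(0, sigma_strain^2)` drawn once per strain per
#' trait and `eps ~ N(0, sigma_animal^2)` per animal. The trait named in
#' `averaged_trait` is reported as the mean of `k` independent trial draws
#' (each the animal value plus `N(0, trial_sd^2)` noise), with `k` uniform
#' on `trials_range`.
#'
#' Planted loci given as (chrom, bp) are snapped to the nearest marker (ties
#' left). Draw order under the single seed: per-strain random effects for
#' each trait (in trait order), then per-animal noise for each trait, then
#' trial counts and trial noise.
#'
#' @param g A `cc_geno`.
#' @param arch A `trait_architecture`.
#' @param seed Integer seed.
#' @return data.frame of class `cc_pheno` with columns `animal_id`,
#'   `strain`, `sex` ("F"/"M") and one column per trait. The architecture
#'   and the marker-resolved truth table are attached as attributes
#'   `architecture` and `truth`.
#' @export
simulate_phenotypes <- function(g, arch, seed) {
  stopifnot(inherits(g, "cc_geno"), inherits(arch, "trait_architecture"))
  set.seed(as.integer(seed))
  tn <- names(arch$traits)
  strains <- g$strains
  n_str <- length(strains)

  # resolve planted loci to markers and build per-strain genetic values
  genetic <- matrix(0, nrow = n_str, ncol = 2, dimnames = list(strains, tn))
  truth <- planted_truth(arch)
  if (nrow(truth)) {
    idx <- snap_to_marker(g$map, truth$chrom, truth$bp)
    truth$marker_id <- g$map$id[idx]
    truth$marker_bp <- g$map$bp[idx]
    for (r in seq_len(nrow(truth))) {
      a <- g$geno[, idx[r]]
      a[is.na(a)] <- 0L
      genetic[, truth$trait[r]] <- genetic[, truth$trait[r]] +
        truth$beta[r] * a
    }
  }

  u <- sapply(tn, function(t) stats::rnorm(n_str, 0, arch$sigma_strain[[t]]))
  dimnames(u) <- list(strains, tn)

  m <- arch$mice_per_strain_per_sex
  n_animals <- n_str * 2L * m
  strain_col <- rep(strains, each = 2L * m)
  sex_col <- rep(rep(c("F", "M"), each = m), times = n_str)
  ph <- data.frame(
    animal_id = sprintf("A%05d", seq_len(n_animals)),
    strain = strain_col,
    sex = sex_col,
    stringsAsFactors = FALSE
  )
  si <- match(strain_col, strains)
  male <- as.numeric(sex_col == "M")
  for (t in tn) {
    tr <- arch$traits[[t]]
    val <- tr$mu + tr$sex_effect * male + genetic[si, t] + u[si, t] +
      stats::rnorm(n_animals, 0, arch$sigma_animal[[t]])
    ph[[t]] <- val
  }
  if (!is.na(arch$averaged_trait)) {
    t <- arch$averaged_trait
    kvals <- seq(arch$trials_range[1], arch$trials_range[2])
    k <- kvals[sample.int(length(kvals), n_animals, replace = TRUE)]
    trial_mean <- stats::rnorm(n_animals, 0, arch$trial_sd / sqrt(k))
    ph[[t]] <- ph[[t]] + trial_mean
    ph$n_trials <- k
  }
  structure(ph, class = c("cc_pheno", "data.frame"),
            architecture = arch, truth = truth)
}
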