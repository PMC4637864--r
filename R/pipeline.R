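# End-to-end pipeline: simulate -> scan (both traits) -> call -> suggestive
# -> cross-trait overlap -> enrichment -> summaries, driven by a single
# nested configuration (YAML file or list).

layout_from_config <- function(sim) {
  g <- sim$genome
  if (is.null(g) || identical(g, "default")) {
    return(default_genome(
      marker_density = sim$marker_density %||% 2,
      recomb_rate = sim$recomb_rate %||% 0.05))
  }
  lens <- unlist(g$chromosomes)
  genome_layout(lens,
                marker_density = g$marker_density %||% 2,
                recomb_rate = g$recomb_rate %||% 0.05)
}

arch_from_config <- function(sim, layout) {
  a <- sim$architecture
  mice <- sim$mice_per_strain_per_sex %||% 11
  if (is.null(a) || identical(a, "default")) {
    return(default_architecture(layout, mice_per_strain_per_sex = mice))
  }
  loci_df <- function(x) {
    if (is.null(x) || !length(x)) {
      return(data.frame(chrom = character(), bp = numeric(),
                        beta = numeric()))
    }
    do.call(rbind, lapply(x, function(l) {
      data.frame(chrom = l$chrom, bp = l$bp, beta = l$beta)
    }))
  }
  traits <- lapply(a$traits, function(tr) {
    list(mu = tr$mu, sex_effect = tr$sex_effect %||% 0,
         loci = loci_df(tr$loci))
  })
  shared <- if (is.null(a$shared) || !length(a$shared)) NULL else {
    do.call(rbind, lapply(a$shared, function(l) {
      data.frame(chrom = l$chrom, bp = l$bp, beta1 = l$beta1,
                 beta2 = l$beta2)
    }))
  }
  trait_architecture(
    traits = traits, shared = shared,
    sigma_strain = unlist(a$sigma_strain),
    sigma_animal = unlist(a$sigma_animal),
    mice_per_strain_per_sex = mice,
    trials_range = unlist(a$trials_range %||% c(3L, 5L)),
    trial_sd = a$trial_sd %||% 0,
    averaged_trait = a$averaged_trait %||% NA_character_
  )
}

scan_config_from <- function(sc) {
  if (is.null(sc)) return(scan_config())
  scan_config(
    model = sc$model %||% "linear",
    sex_handling = sc$sex_handling %||% "covariate",
    unit = sc$unit %||% "animal",
    sig_neglogp = sc$sig_neglogp %||% 20,
    sig_neglogfdr = sc$sig_neglogfdr %||% 18,
    sugg_neglogp = sc$sugg_neglogp %||% 10,
    sugg_neglogfdr = sc$sugg_neglogfdr %||% 8
  )
}

caller_config_from <- function(cc) {
  if (is.null(cc)) return(caller_config())
  caller_config(min_run = cc$min_run %||% 3,
                gap_tolerance = cc$gap_tolerance %||% 2,
                boundary_rule = cc$boundary_rule %||% "flanking_marker")
}

#' Built-in demonstration configuration
#'
#' A recombinant-inbred cohort of 60 strains with 4 mice per strain per sex
#' (mouse-autosome-like genome at 1 marker/Mb) under the default
#' opposite-sign shared-locus architecture — large enough that the planted
#' loci, including the pleiotropic ones, are reliably recovered — plus a
#' simulated gene annotation and a disease gene list spiked with genes near
#' the planted loci so the enrichment stage has signal. For a paper-scale
#' cohort use `n_strains = 16`, `mice_per_strain_per_sex = 11` (and expect
#' the small-panel peak inflation discussed in the vignette).
#'
#' @param seed Master seed recorded in the configuration.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 42) {
  list(
    simulation = list(
      genome = "default",
      marker_density = 2,
      recomb_rate = 0.05,
      sdp_share = 0.9,
      n_strains = 60,
      mice_per_strain_per_sex = 4,
      architecture = "default",
      min_minor_strains = 2,
      seed = seed
    ),
    scan = list(model = "linear", sex_handling = "covariate",
                unit = "animal"),
    caller = list(min_run = 3, gap_tolerance = 2),
    overlap = list(bin_width = 5e6, n_perm = 1000),
    enrichment = list(mode = "simulate", n_genes = 2000, n_list = 200,
                      spike = 30, spike_window = 2e6),
    log_level = "info"
  )
}

log_stage <- function(level, ...) {
  if (identical(level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the full QTL pipeline
#'
#' Executes simulate -> scan (both traits) -> call significant ->
#' call suggestive -> cross-trait overlap -> gene enrichment -> strain
#' summaries, writes every artifact (genotype CSV + marker map TSV,
#' phenotype TSV, per-trait scan TSVs, locus BED + TSV, overlap report,
#' enrichment report) under `out_dir`, and finishes with a flat key-value
#' run manifest (`manifest.txt`) holding the config hash, seeds, package
#' version and headline numbers. Identical configuration and seeds give
#' identical outputs.
#'
#' @param config A configuration list (see [demo_config()]) or the path of
#'   a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$simulation$seed`.
#' @return Invisibly, a list with all in-memory results: `genotypes`,
#'   `phenotypes`, `scans`, `significant`, `suggestive`, `overlap`,
#'   `enrichment`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (!is.null(seed)) cfg$simulation$seed <- seed
  if (is.null(cfg$simulation$seed)) {
    stop("run_pipeline: simulation seed must be explicit")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lvl <- cfg$log_level %||% "info"
  master_seed <- as.integer(cfg$simulation$seed)

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs in ", out_dir, ")", call. = FALSE)
    })
    log_stage(lvl, sprintf("stage %-12s done in %.2fs", name,
                           proc.time()[["elapsed"]] - t0))
    res
  }

  # --- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    layout <- layout_from_config(cfg$simulation)
    arch <- arch_from_config(cfg$simulation, layout)
    mos <- simulate_mosaics(layout, cfg$simulation$n_strains %||% 16,
                            seed = master_seed)
    map <- simulate_marker_map(layout, seed = master_seed + 1L,
                               sdp_share = cfg$simulation$sdp_share %||% 0.9)
    g <- project_markers(mos, map)
    g <- filter_informative(g, cfg$simulation$min_minor_strains %||% 1)
    ph <- simulate_phenotypes(g, arch, seed = master_seed + 2L)
    list(layout = layout, arch = arch, g = g, ph = ph)
  })
  g <- sim$g; ph <- sim$ph
  traits <- names(sim$arch$traits)
  log_stage(lvl, sprintf("simulated %d strains, %d informative markers, %d animals",
                         length(g$strains), ncol(g$geno), nrow(ph)))
  write_genotypes(g, file.path(out_dir, "genotypes.csv"),
                  file.path(out_dir, "marker_map.tsv"))
  write_phenotypes(ph, file.path(out_dir, "phenotypes.tsv"))

  # --- scan -----------------------------------------------------------
  scans <- run_stage("scan", {
    scfg <- scan_config_from(cfg$scan)
    stats::setNames(lapply(traits, function(t) genome_scan(g, ph, t, scfg)),
                    traits)
  })
  for (t in traits) {
    write_scan_tsv(scans[[t]], file.path(out_dir, paste0("scan_", t, ".tsv")))
  }

  # --- call -----------------------------------------------------------
  ccfg <- caller_config_from(cfg$caller)
  sig <- run_stage("call", {
    stats::setNames(lapply(traits, function(t) {
      call_significant(scans[[t]], ccfg)
    }), traits)
  })
  sugg <- run_stage("suggestive", {
    stats::setNames(lapply(seq_along(traits), function(i) {
      call_suggestive(scans[[traits[i]]], sig[[traits[3 - i]]], ccfg)
    }), traits)
  })
  for (t in traits) {
    all_loci <- rbind(as.data.frame(sig[[t]]), as.data.frame(sugg[[t]]))
    class(all_loci) <- c("cc_loci", "data.frame")
    write_loci(all_loci, file.path(out_dir, paste0("loci_", t, ".bed")),
               file.path(out_dir, paste0("loci_", t, ".tsv")))
  }

  # --- cross-trait ----------------------------------------------------
  lens <- chrom_lengths_of(sim$layout)
  overlap <- run_stage("overlap", {
    qtl_overlap(sig[[traits[1]]], sig[[traits[2]]],
                scans[[traits[1]]], scans[[traits[2]]],
                lens,
                bin_width = cfg$overlap$bin_width %||% 5e6,
                n_perm = cfg$overlap$n_perm %||% 1000,
                seed = master_seed + 3L)
  })
  write_overlap_report(overlap, file.path(out_dir, "overlap.tsv"),
                       seed = master_seed + 3L)
  summ <- run_stage("summarize", summarize_strains(ph, traits))

  # --- enrichment -----------------------------------------------------
  enr <- run_stage("enrich", {
    ecfg <- cfg$enrichment
    if (is.null(ecfg)) return(NULL)
    both_loci <- rbind(as.data.frame(sig[[traits[1]]]),
                       as.data.frame(sig[[traits[2]]]))
    class(both_loci) <- c("cc_loci", "data.frame")
    if (identical(ecfg$mode %||% "simulate", "simulate")) {
      ann <- simulate_gene_annotation(sim$layout, ecfg$n_genes %||% 2000,
                                      seed = master_seed + 4L)
      glist <- spiked_gene_list(ann, attr(ph, "truth"),
                                n_list = ecfg$n_list %||% 200,
                                spike = ecfg$spike %||% 30,
                                window = ecfg$spike_window %||% 2e6,
                                seed = master_seed + 5L)
      write_annotation_bed(ann, file.path(out_dir, "annotation.bed"))
      writeLines(c("# simulated disease gene list", glist),
                 file.path(out_dir, "disease_genes.txt"))
    } else {
      ann <- read_annotation(ecfg$annotation)
      glist <- read_gene_list(ecfg$gene_list)
    }
    gq <- genes_in_qtl(ann, both_loci)
    res <- enrich(gq$genes, glist, universe = ann$symbol)
    list(result = res, genes_in_qtl = gq, annotation = ann,
         gene_list = glist)
  })
  if (!is.null(enr)) {
    writeLines(c(
      sprintf("n_qtl_genes\t%d", enr$result$n_qtl_genes),
      sprintf("n_list_genes\t%d", enr$result$n_list_genes),
      sprintf("n_overlap\t%d", enr$result$n_overlap),
      sprintf("universe_size\t%d", enr$result$universe_size),
      sprintf("p\t%s", fmt_num(enr$result$p))
    ), file.path(out_dir, "enrichment.tsv"))
  }

  # --- manifest -------------------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(cfg, cfg_path)
  manifest <- c(
    package = "ccqtl",
    version = as.character(utils::packageVersion("ccqtl")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = master_seed,
    n_strains = length(g$strains),
    n_markers = ncol(g$geno),
    n_animals = nrow(ph),
    trait1 = traits[1], trait2 = traits[2],
    n_sig_loci_trait1 = nrow(sig[[traits[1]]]),
    n_sig_loci_trait2 = nrow(sig[[traits[2]]]),
    n_overlapping = overlap$n_overlapping,
    n_discordant = sum(overlap$pairs$direction == "discordant",
                       na.rm = TRUE),
    overlap_hypergeom_p = fmt_num(overlap$hypergeom_p),
    spearman_F = fmt_num(unname(summ$spearman_between_traits["F"])),
    spearman_M = fmt_num(unname(summ$spearman_between_traits["M"]))
  )
  writeLines(paste(names(manifest), manifest, sep = "="),
             file.path(out_dir, "manifest.txt"))
  log_stage(lvl, "pipeline complete: ", out_dir)
  invisible(list(genotypes = g, phenotypes = ph, scans = scans,
                 significant = sig, suggestive = sugg, overlap = overlap,
                 enrichment = enr, summary = summ, manifest = manifest,
                 layout = sim$layout, architecture = sim$arch))
}

write_overlap_report <- function(overlap, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_lociA\t%d", overlap$n_lociA),
    sprintf("# n_lociB\t%d", overlap$n_lociB),
    sprintf("# n_overlapping\t%d", overlap$n_overlapping),
    sprintf("# universe_N\t%d", overlap$N),
    sprintf("# bin_width\t%.0f", overlap$bin_width),
    sprintf("# hypergeom_p\t%s", fmt_num(overlap$hypergeom_p)),
    sprintf("# permutation_p\t%s", fmt_num(overlap$permutation$p)),
    sprintf("# n_perm\t%d", overlap$permutation$n_perm),
    sprintf("# seed\t%d", seed)
  ), con)
  df <- overlap$pairs
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
}

# pick a disease gene list: `spike` genes within `window` of planted loci
# plus random fillers, deterministic given seed
spiked_gene_list <- function(ann, truth, n_list, spike, window, seed) {
  set.seed(as.integer(seed))
  near <- character(0)
  if (!is.null(truth) && nrow(truth)) {
    pos <- if ("marker_bp" %in% names(truth)) truth$marker_bp else truth$bp
    for (i in seq_len(nrow(truth))) {
      hit <- ann$chrom == truth$chrom[i] &
        ann$start < pos[i] + window & ann$end > pos[i] - window
      near <- c(near, ann$symbol[hit])
    }
    near <- unique(near)
  }
  spiked <- utils::head(near, spike)
  filler <- sample(setdiff(ann$symbol, spiked),
                   max(0, n_list - length(spiked)))
  sort(unique(c(spiked, filler)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
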