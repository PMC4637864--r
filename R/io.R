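# Plain-text readers and writers. All files use 1-based bp coordinates
# except BED output (0-based half-open per the format). Numeric trait values
# are serialized with 17 significant digits so write/read round-trips are
# exact.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a genotype matrix and its marker map
#'
#' The genotype CSV has one row per strain (first column `strain`, then one
#' 0/1/NA column per marker, header = marker ids). The companion map TSV
#' has columns `id`, `chrom`, `bp`, `sdp` (8-character 0/1 string) and
#' carries chromosome lengths as `##chrom <name> <length>` header lines.
#'
#' @param g A `cc_geno`.
#' @param geno_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes <- function(g, geno_path, map_path) {
  stopifnot(inherits(g, "cc_geno"))
  df <- data.frame(strain = g$strains, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(g$geno))
  utils::write.csv(df, geno_path, row.names = FALSE, quote = FALSE)
  con <- file(map_path, "w")
  on.exit(close(con))
  lens <- attr(g$map, "chrom_lengths")
  if (!is.null(lens)) {
    writeLines(sprintf("##chrom\t%s\t%.0f", names(lens), lens), con)
  }
  writeLines("id\tchrom\tbp\tsdp", con)
  writeLines(sprintf("%s\t%s\t%d\t%s", g$map$id, g$map$chrom,
                     as.integer(g$map$bp), g$map$sdp), con)
  invisible(c(geno_path, map_path))
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param geno_path,map_path Input paths.
#' @return A `cc_geno`.
#' @export
read_genotypes <- function(geno_path, map_path) {
  lines <- readLines(map_path)
  is_len <- startsWith(lines, "##chrom")
  lens <- NULL
  if (any(is_len)) {
    parts <- strsplit(lines[is_len], "\t")
    lens <- stats::setNames(
      vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
      vapply(parts, function(p) p[2], character(1)))
  }
  body <- lines[!is_len]
  if (!length(body) || body[1] != "id\tchrom\tbp\tsdp") {
    stop("read_genotypes: malformed map header at line ",
         sum(is_len) + 1, " of ", map_path)
  }
  map <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = c("id", "chrom", "bp", "sdp"),
                           colClasses = c("character", "character",
                                          "integer", "character"))
  map <- new_marker_map(map, lens)
  geno_df <- utils::read.csv(geno_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (names(geno_df)[1] != "strain") {
    stop("read_genotypes: malformed genotype header (line 1): first ",
         "column must be 'strain'")
  }
  if (anyDuplicated(geno_df$strain)) {
    stop("read_genotypes: duplicate strain ids")
  }
  geno <- as.matrix(geno_df[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- geno_df$strain
  if (!identical(colnames(geno), map$id)) {
    stop("read_genotypes: genotype columns do not match the marker map")
  }
  if (any(!geno %in% c(0L, 1L, NA_integer_))) {
    stop("read_genotypes: allele codes must be 0, 1 or NA")
  }
  new_cc_geno(geno, map)
}

#' Write a phenotype table
#'
#' Tab-separated, one row per animal: `animal_id`, `strain`, `sex`, then
#' the trait columns (and `n_trials` when present).
#'
#' @param ph A `cc_pheno` or compatible data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_phenotypes <- function(ph, path) {
  df <- as.data.frame(ph)
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#'
#' @param path Input path.
#' @param strains Optional character vector of known strain ids; rows with
#'   other strains are rejected with a line-numbered message.
#' @return A `cc_pheno` data.frame.
#' @export
read_phenotypes <- function(path, strains = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("animal_id", "strain", "sex")
  if (!all(need %in% names(df))) {
    stop("read_phenotypes: malformed header (line 1): need columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$animal_id)) {
    stop("read_phenotypes: duplicate animal ids")
  }
  if (!all(df$sex %in% c("F", "M"))) {
    bad <- which(!df$sex %in% c("F", "M"))[1]
    stop("read_phenotypes: invalid sex code at line ", bad + 1)
  }
  if (!is.null(strains)) {
    unknown <- which(!df$strain %in% strains)
    if (length(unknown)) {
      stop("read_phenotypes: unknown strain '", df$strain[unknown[1]],
           "' at line ", unknown[1] + 1)
    }
  }
  structure(df, class = c("cc_pheno", "data.frame"))
}

#' Read a gene annotation from BED or GFF3
#'
#' BED input is 0-based half-open (used as is; the `name` field supplies
#' the symbol). GFF3 input is 1-based closed and is converted to the
#' internal 0-based half-open convention; features of type `gene` are used
#' when present (all features otherwise), symbols come from the `Name`
#' attribute falling back to `ID`, and an `ortholog` attribute is carried
#' through when present.
#'
#' @param path Input path ending in `.bed`, `.gff` or `.gff3`.
#' @return data.frame with `symbol`, `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `ortholog`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene")) {
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    }
  } else {
    stop("read_annotation: unsupported extension '", ext,
         "' (use .bed, .gff or .gff3)")
  }
  mc <- S4Vectors::mcols(gr)
  symbol <- if ("name" %in% names(mc)) as.character(mc$name) else
    if ("Name" %in% names(mc)) as.character(mc$Name) else
      if ("ID" %in% names(mc)) as.character(mc$ID) else
        sprintf("FEATURE%05d", seq_along(gr))
  symbol[is.na(symbol)] <- sprintf("FEATURE%05d", which(is.na(symbol)))
  ann <- data.frame(
    symbol = symbol,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if ("ortholog" %in% names(mc)) {
    ann$ortholog <- as.character(mc$ortholog)
  }
  if (anyDuplicated(toupper(ann$symbol))) {
    stop("read_annotation: duplicated gene symbols (case-folded)")
  }
  if (any(ann$start >= ann$end)) {
    stop("read_annotation: empty or inverted gene interval")
  }
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Write a gene annotation as BED
#'
#' @param ann Annotation data.frame (0-based half-open).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation_bed <- function(ann, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t.", ann$chrom, ann$start,
                     ann$end, ann$symbol), path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Input path.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write a genome scan as TSV
#'
#' Columns: `marker_id`, `chrom`, `bp` (1-based), `trait`, `n`, `effect`,
#' `p`, `q`, `neglog10p`, `class`.
#'
#' @param scan A `cc_scan`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- as.data.frame(scan)[, c("marker_id", "chrom", "bp", "trait", "n",
                                "effect", "p", "q", "neglog10p", "class")]
  for (col in c("effect", "p", "q", "neglog10p")) {
    df[[col]] <- fmt_num(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write called loci as BED6 and as a full TSV report
#'
#' BED uses the internal 0-based half-open coordinates directly; the report
#' TSV uses 1-based closed coordinates (`start + 1`, `end`). BED scores are
#' the peak -log10 p rounded and capped at 1000.
#'
#' @param loci A `cc_loci`.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_loci <- function(loci, bed_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(bed_path)) {
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s:%s\t%d\t.",
                       loci$chrom, loci$start, loci$end,
                       loci$trait, loci$locus_id,
                       pmin(1000L, as.integer(round(loci$peak_neglog10p)))),
               bed_path)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    df <- as.data.frame(loci)
    df$start_1based <- df$start + 1
    df$end_1based <- df$end
    df <- df[, c("locus_id", "trait", "chrom", "start_1based", "end_1based",
                 "n_markers", "peak_marker", "peak_bp", "peak_neglog10p",
                 "peak_effect", "effect_sign", "class")]
    df$peak_neglog10p <- fmt_num(df$peak_neglog10p)
    df$peak_effect <- fmt_num(df$peak_effect)
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

#' Read a genome scan TSV written by [write_scan_tsv()]
#'
#' @param path Input path.
#' @param chrom_lengths Optional named chromosome lengths to attach (e.g.
#'   from a marker map read with [read_genotypes()]), required for
#'   chromosome-end truncation in the caller.
#' @return A `cc_scan` data.frame.
#' @export
read_scan_tsv <- function(path, chrom_lengths = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "bp", "trait", "n", "effect", "p", "q",
            "neglog10p", "class")
  if (!all(need %in% names(df))) {
    stop("read_scan_tsv: malformed header (line 1): need columns ",
         paste(need, collapse = ", "))
  }
  df$neglog10q <- -log10(pmax(df$q, .Machine$double.xmin))
  df$note <- "ok"
  structure(df, class = c("cc_scan", "data.frame"),
            config = scan_config(), trait = df$trait[1],
            chrom_lengths = chrom_lengths,
            p_floor = .Machine$double.xmin)
}

#' Read a locus report TSV written by [write_loci()]
#'
#' Converts the report's 1-based closed coordinates back to the internal
#' 0-based half-open convention.
#'
#' @param path Input path.
#' @return A `cc_loci` data.frame.
#' @export
read_loci_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$start <- df$start_1based - 1
  df$end <- df$end_1based
  df$start_1based <- NULL
  df$end_1based <- NULL
  structure(df, class = c("cc_loci", "data.frame"))
}

#' Read and write pipeline configuration (YAML)
#'
#' @param path Config file path.
#' @return For `read_config`, the configuration as a nested list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
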