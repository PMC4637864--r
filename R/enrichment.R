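#' Assign genes to QTL intervals
#'
#' A gene is assigned to a locus iff the two intervals intersect — partial
#' overlap suffices; a gene can belong to several loci. Both annotations
#' and loci use 0-based half-open coordinates internally.
#'
#' @param ann A gene annotation data.frame (see [read_annotation()]):
#'   columns `symbol`, `chrom`, `start`, `end`, optional `ortholog`.
#' @param loci A `cc_loci`.
#' @return `list(assignments, by_locus, genes)`: `assignments` is a
#'   data.frame of (locus_id, symbol) pairs, `by_locus` a named list of
#'   symbol vectors, `genes` the unique assigned symbols.
#' @export
genes_in_qtl <- function(ann, loci) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(ann)))
  empty <- list(
    assignments = data.frame(locus_id = character(), symbol = character(),
                             stringsAsFactors = FALSE),
    by_locus = stats::setNames(list(), character(0)),
    genes = character(0))
  if (!nrow(ann) || !nrow(loci)) return(empty)
  lv <- union(ann$chrom, loci$chrom)
  gr_g <- GenomicRanges::GRanges(factor(ann$chrom, levels = lv),
                                 IRanges::IRanges(ann$start + 1, ann$end))
  gr_l <- GenomicRanges::GRanges(factor(loci$chrom, levels = lv),
                                 IRanges::IRanges(loci$start + 1, loci$end))
  ov <- GenomicRanges::findOverlaps(gr_l, gr_g)
  if (!length(ov)) return(empty)
  assignments <- data.frame(
    locus_id = loci$locus_id[S4Vectors::queryHits(ov)],
    symbol = ann$symbol[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  by_locus <- split(assignments$symbol, assignments$locus_id)
  list(assignments = assignments, by_locus = by_locus,
       genes = unique(assignments$symbol))
}

#' Hypergeometric gene-set overlap test
#'
#' Tests whether the candidate genes inside QTL intervals overlap an
#' external gene list (e.g. genes flagged by human GWAS) more than expected
#' for random subsets of the universe. Symbols are matched
#' case-insensitively; optional ortholog symbols (a named map from
#' annotation symbol to cross-species symbol) are applied to the QTL gene
#' set before matching. Overlap counts unique symbols.
#'
#' @param qtl_genes Character vector of candidate symbols (e.g.
#'   `genes_in_qtl(...)$genes`).
#' @param disease_genes Character vector of external-list symbols.
#' @param universe Either a single count (universe size) or a character
#'   vector of symbols; when a set, both gene sets are required to be
#'   subsets of it (after case folding) and are intersected with it.
#' @param ortholog_map Optional named character vector mapping annotation
#'   symbols to ortholog symbols.
#' @return An object of class `enrichment_result`: list with `n_qtl_genes`,
#'   `n_list_genes`, `n_overlap`, `universe_size`, `p`, `overlap_genes`.
#' @export
enrich <- function(qtl_genes, disease_genes, universe,
                   ortholog_map = NULL) {
  fold <- function(x) toupper(trimws(x))
  q <- fold(qtl_genes)
  if (!is.null(ortholog_map)) {
    names(ortholog_map) <- fold(names(ortholog_map))
    mapped <- ortholog_map[q]
    q <- ifelse(is.na(mapped), q, fold(mapped))
  }
  q <- unique(q)
  d <- unique(fold(disease_genes))
  if (is.character(universe)) {
    u <- unique(fold(universe))
    if (!length(u)) stop("enrich: empty universe")
    extra <- setdiff(c(q, d), u)
    if (length(extra)) {
      stop("enrich: gene sets must be subsets of the universe; missing: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    N <- length(u)
  } else {
    N <- as.integer(universe)
    if (length(N) != 1 || is.na(N) || N < 1) stop("enrich: empty universe")
    if (length(q) > N || length(d) > N) {
      stop("enrich: gene sets larger than the universe")
    }
  }
  ov <- intersect(q, d)
  p <- stats::phyper(length(ov) - 1, length(q), N - length(q), length(d),
                     lower.tail = FALSE)
  structure(
    list(n_qtl_genes = length(q), n_list_genes = length(d),
         n_overlap = length(ov), universe_size = N, p = p,
         overlap_genes = sort(ov)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d of %d QTL genes in external list of %d (universe %d): p = %.3g\n",
    x$n_overlap, x$n_qtl_genes, x$n_list_genes, x$universe_size, x$p))
  invisible(x)
}

#' Simulate a gene annotation over a genome layout
#'
#' Utility for self-contained demonstrations and tests: places `n_genes`
#' non-descript genes of the given length range uniformly across the
#' genome (synthetic symbols `GENE00001`, ...).
#'
#' @param layout A [genome_layout()].
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param length_range Gene length range in bp.
#' @return A gene annotation data.frame (`symbol`, `chrom`, `start`, `end`),
#'   0-based half-open, sorted by (chrom, start).
#' @export
simulate_gene_annotation <- function(layout, n_genes, seed,
                                     length_range = c(1e4, 2e5)) {
  set.seed(as.integer(seed))
  lens <- chrom_lengths_of(layout)
  ch <- sample(names(lens), n_genes, replace = TRUE,
               prob = lens / sum(lens))
  glen <- round(stats::runif(n_genes, length_range[1], length_range[2]))
  start <- floor(stats::runif(n_genes, 0, pmax(1, lens[ch] - glen)))
  ann <- data.frame(symbol = sprintf("GENE%05d", seq_len(n_genes)),
                    chrom = ch, start = start, end = start + glen,
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom, ann$start), ]
  rownames(ann) <- NULL
  ann
}
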