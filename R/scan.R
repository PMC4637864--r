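#' Configuration of the single-marker genome scan
#'
#' Thresholds follow the convention of defining genome-wide significance on
#' the -log10 p scale with a matching FDR condition: significant when
#' -log10(p) > `sig_neglogp` and -log10(q) > `sig_neglogfdr`; suggestive
#' when not significant but -log10(p) >= `sugg_neglogp` and -log10(q) >=
#' `sugg_neglogfdr`. Defaults are 20/18 and 10/8. The upper end of each
#' suggestive band is the corresponding significant threshold by
#' construction.
#'
#' @param model `"linear"` (least squares on the trait, default) or
#'   `"logistic_dichotomized"` (trait dichotomized at its median, logistic
#'   regression on the indicator).
#' @param sex_handling `"covariate"` (additive sex term, default),
#'   `"pooled"` (sexes combined with no sex term), or `"per_sex"`
#'   (separate scans per sex).
#' @param unit `"animal"` (default; every mouse is an observation, so
#'   within-strain replication inflates evidence at strain-level loci —
#'   see the vignette) or `"strain_mean"` (one observation per strain,
#'   sexes averaged, statistically conservative).
#' @param sig_neglogp,sig_neglogfdr Significance thresholds on -log10 p and
#'   -log10 q.
#' @param sugg_neglogp,sugg_neglogfdr Lower bounds of the suggestive band.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(model = c("linear", "logistic_dichotomized"),
                        sex_handling = c("covariate", "pooled", "per_sex"),
                        unit = c("animal", "strain_mean"),
                        sig_neglogp = 20, sig_neglogfdr = 18,
                        sugg_neglogp = 10, sugg_neglogfdr = 8) {
  model <- match.arg(model)
  sex_handling <- match.arg(sex_handling)
  unit <- match.arg(unit)
  stopifnot(sig_neglogp > 0, sig_neglogfdr > 0,
            sugg_neglogp > 0, sugg_neglogfdr > 0,
            sugg_neglogp <= sig_neglogp, sugg_neglogfdr <= sig_neglogfdr)
  structure(list(model = model, sex_handling = sex_handling, unit = unit,
                 sig_neglogp = sig_neglogp, sig_neglogfdr = sig_neglogfdr,
                 sugg_neglogp = sugg_neglogp, sugg_neglogfdr = sugg_neglogfdr),
            class = "scan_config")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back
#' to input order and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("bh_fdr: p-values must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Single-marker association fit
#'
#' Reference (per-marker) fit used both directly and as the model behind
#' [genome_scan()]. Animals with missing genotype are dropped. A marker
#' monomorphic in the analysis subset, or a trait with zero variance, yields
#' `effect = 0`, `p = 1` and a descriptive flag rather than an error, so
#' scans stream over such markers.
#'
#' @param alleles Per-animal allele codes (0/1/NA).
#' @param values Per-animal trait values.
#' @param sex Per-animal sex labels (`"F"`/`"M"`), or `NULL` for no sex term.
#' @param cfg A [scan_config()]; `model` and `sex_handling` are honoured
#'   (`"per_sex"` is not meaningful for a single fit and is treated as
#'   `"pooled"`).
#' @return `list(effect, p, n, note)` with `note` one of `"ok"`,
#'   `"non-informative"`, `"zero-variance"`.
#' @export
fit_marker <- function(alleles, values, sex = NULL, cfg = scan_config()) {
  stopifnot(length(alleles) == length(values),
            is.null(sex) || length(sex) == length(values))
  keep <- !is.na(alleles) & !is.na(values)
  a <- as.numeric(alleles[keep])
  y <- as.numeric(values[keep])
  n <- length(y)
  if (n == 0 || length(unique(a)) < 2) {
    return(list(effect = 0, p = 1, n = n, note = "non-informative"))
  }
  if (stats::var(y) == 0 && cfg$model == "linear") {
    return(list(effect = 0, p = 1, n = n, note = "zero-variance"))
  }
  use_sex <- !is.null(sex) && cfg$sex_handling == "covariate" &&
    length(unique(sex[keep])) > 1
  dat <- data.frame(y = y, a = a)
  form <- y ~ a
  if (use_sex) {
    dat$male <- as.numeric(sex[keep] == "M")
    form <- y ~ a + male
  }
  if (cfg$model == "linear") {
    fit <- stats::lm(form, data = dat)
    co <- summary(fit)$coefficients
    if (!"a" %in% rownames(co) || is.na(co["a", 4])) {
      return(list(effect = 0, p = 1, n = n, note = "non-informative"))
    }
    list(effect = unname(co["a", 1]), p = unname(co["a", 4]), n = n,
         note = "ok")
  } else {
    dat$y <- as.numeric(y > stats::median(y))
    if (length(unique(dat$y)) < 2) {
      return(list(effect = 0, p = 1, n = n, note = "zero-variance"))
    }
    fit <- suppressWarnings(stats::glm(form, data = dat,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (!"a" %in% rownames(co) || is.na(co["a", 4])) {
      return(list(effect = 0, p = 1, n = n, note = "non-informative"))
    }
    list(effect = unname(co["a", 1]), p = unname(co["a", 4]), n = n,
         note = "ok")
  }
}

# Vectorized least-squares scan over an allele matrix with optional
# covariates; exact per-marker OLS via the Frisch-Waugh decomposition.
# A: n x m allele matrix (no NAs in the fast path), y: response, X0:
# covariate matrix including intercept.
assoc_linear_engine <- function(A, y, X0) {
  n <- length(y)
  m <- ncol(A)
  effect <- numeric(m)
  p <- rep(1, m)
  note <- rep("ok", m)
  df <- n - ncol(X0) - 1L
  if (df < 1) stop("genome_scan: not enough observations for the model")
  qrX <- qr(X0)
  yr <- qr.resid(qrX, y)
  syy <- sum(yr^2)
  if (syy <= 0) {
    return(list(effect = effect, p = p, note = rep("zero-variance", m)))
  }
  has_na <- colSums(is.na(A)) > 0L
  if (any(!has_na)) {
    cols <- which(!has_na)
    Ar <- qr.resid(qrX, A[, cols, drop = FALSE])
    sxx <- colSums(Ar^2)
    sxy <- colSums(Ar * yr)
    ok <- sxx > n * 1e-12
    b <- ifelse(ok, sxy / sxx, 0)
    rss <- pmax(syy - b * sxy, 0)
    se2 <- rss / df / sxx
    tval <- b / sqrt(pmax(se2, 1e-300))   # se2 = 0 (perfect fit) -> huge |t|
    pv <- ifelse(ok, 2 * stats::pt(-abs(tval), df), 1)
    effect[cols] <- ifelse(ok, b, 0)
    p[cols] <- pv
    note[cols][!ok] <- "non-informative"
  }
  for (j in which(has_na)) {       # markers with missing calls: exact refit
    keep <- !is.na(A[, j])
    if (sum(keep) <= ncol(X0) + 1L || length(unique(A[keep, j])) < 2) {
      note[j] <- "non-informative"
      next
    }
    Xj <- cbind(X0[keep, , drop = FALSE], A[keep, j])
    fit <- stats::lm.fit(Xj, y[keep])
    r <- fit$residuals
    dfj <- sum(keep) - ncol(Xj)
    XtXinv <- chol2inv(chol(crossprod(Xj)))
    se <- sqrt(sum(r^2) / dfj * XtXinv[ncol(Xj), ncol(Xj)])
    b <- fit$coefficients[ncol(Xj)]
    tval <- b / se
    effect[j] <- b
    p[j] <- 2 * stats::pt(-abs(tval), dfj)
  }
  list(effect = effect, p = p, note = note)
}

#' Genome-wide single-marker scan of one trait
#'
#' Regresses the trait on the allele code at every marker (animals inherit
#' their strain's allele), applies Benjamini-Hochberg FDR across all tested
#' markers, and classifies each marker as significant / suggestive / none
#' per the thresholds in `cfg`. p-values of exactly zero (numerical
#' underflow) are floored at the smallest positive double before taking
#' logs; the floor is recorded in the result's attributes.
#'
#' With `sex_handling = "per_sex"` a named list of two scans (`F`, `M`) is
#' returned, each fitted within one sex without a sex term.
#'
#' @param g A `cc_geno`.
#' @param ph A `cc_pheno` (or any data.frame with `strain`, `sex` and the
#'   trait column). Strains must be a subset of the genotyped strains.
#' @param trait Trait column name in `ph`.
#' @param cfg A [scan_config()].
#' @return A data.frame of class `cc_scan` with columns `marker_id`,
#'   `chrom`, `bp`, `trait`, `n`, `effect`, `p`, `q`, `neglog10p`,
#'   `neglog10q`, `class`, `note`, in marker-map order. Attributes: `config`,
#'   `trait`, `chrom_lengths`, `p_floor`.
#' @export
genome_scan <- function(g, ph, trait, cfg = scan_config()) {
  stopifnot(inherits(g, "cc_geno"))
  if (!trait %in% names(ph)) {
    stop("genome_scan: unknown trait '", trait, "'")
  }
  missing_strains <- setdiff(unique(ph$strain), g$strains)
  if (length(missing_strains)) {
    stop("genome_scan: phenotype strains not in genotype matrix: ",
         paste(missing_strains, collapse = ", "))
  }
  if (cfg$sex_handling == "per_sex") {
    sub_cfg <- cfg
    sub_cfg$sex_handling <- "pooled"
    return(lapply(stats::setNames(nm = sort(unique(ph$sex))), function(s) {
      genome_scan(g, ph[ph$sex == s, , drop = FALSE], trait, sub_cfg)
    }))
  }

  if (cfg$unit == "strain_mean") {
    vals <- tapply(ph[[trait]], ph$strain, mean)
    dat <- data.frame(strain = names(vals), y = as.numeric(vals),
                      stringsAsFactors = FALSE)
    sex_vec <- NULL
  } else {
    dat <- data.frame(strain = ph$strain, y = ph[[trait]],
                      stringsAsFactors = FALSE)
    sex_vec <- ph$sex
  }
  si <- match(dat$strain, g$strains)
  A <- g$geno[si, , drop = FALSE]
  storage.mode(A) <- "double"
  n <- nrow(dat)

  use_sex <- !is.null(sex_vec) && cfg$sex_handling == "covariate" &&
    length(unique(sex_vec)) > 1
  X0 <- if (use_sex) cbind(1, as.numeric(sex_vec == "M")) else
    matrix(1, n, 1)

  if (cfg$model == "linear") {
    eng <- assoc_linear_engine(A, dat$y, X0)
    effect <- eng$effect
    p <- eng$p
    note <- eng$note
    nn <- colSums(!is.na(A))
  } else {
    m <- ncol(A)
    effect <- numeric(m); p <- rep(1, m); note <- character(m)
    nn <- integer(m)
    for (j in seq_len(m)) {
      f <- fit_marker(A[, j], dat$y, sex_vec, cfg)
      effect[j] <- f$effect; p[j] <- f$p; note[j] <- f$note; nn[j] <- f$n
    }
  }

  p_floor <- .Machine$double.xmin
  p_rep <- pmax(p, p_floor)
  q <- bh_fdr(p_rep)
  neglog10p <- -log10(p_rep)
  neglog10q <- -log10(pmax(q, p_floor))
  cls <- classify_markers(neglog10p, neglog10q, cfg)

  out <- data.frame(
    marker_id = g$map$id, chrom = g$map$chrom, bp = g$map$bp,
    trait = trait, n = nn, effect = effect, p = p_rep, q = q,
    neglog10p = neglog10p, neglog10q = neglog10q, class = cls, note = note,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("cc_scan", "data.frame"),
            config = cfg, trait = trait,
            chrom_lengths = attr(g$map, "chrom_lengths"),
            p_floor = p_floor)
}

classify_markers <- function(neglog10p, neglog10q, cfg) {
  cls <- rep("none", length(neglog10p))
  sugg <- neglog10p >= cfg$sugg_neglogp & neglog10q >= cfg$sugg_neglogfdr
  sig <- neglog10p > cfg$sig_neglogp & neglog10q > cfg$sig_neglogfdr
  cls[sugg] <- "suggestive"
  cls[sig] <- "significant"
  cls
}

#' Manhattan-style diagnostic plot of a scan
#'
#' @param x A `cc_scan`.
#' @param threshold Horizontal reference line on the -log10 p scale
#'   (default the configured significance threshold).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cc_scan <- function(x, threshold = attr(x, "config")$sig_neglogp, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(x$bp[x$chrom == ch]),
                             numeric(1))))
  names(offs) <- c(chroms, "end")
  pos <- x$bp + offs[x$chrom]
  col <- ifelse(match(x$chrom, chroms) %% 2 == 0, "grey40", "grey70")
  graphics::plot(pos, x$neglog10p, pch = 16, cex = 0.4, col = col,
                 xlab = "genome position (bp)",
                 ylab = expression(-log[10](p)),
                 main = attr(x, "trait"), ...)
  graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}
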