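#' Quantify signal over regions into a count-like matrix
#'
#' Per region and sample, the rounded sum of per-base signal (floored at 0).
#' Summation at 1 bp preserves region-width information, which a per-region
#' mean would discard. Row labels are `chrom:start-end`.
#'
#' @param tracks Named list of `signal_track`s (names = sample ids).
#' @param regions Region data frame; must lie within the tracks' genome.
#' @return Integer-valued matrix, regions x samples.
#' @export
quantify_regions <- function(tracks, regions) {
  stopifnot(length(tracks) >= 1L)
  genome <- check_same_genome(tracks)
  regions <- canonical_regions(regions, genome)
  labels <- sprintf("%s:%d-%d", regions$chrom, as.integer(regions$start),
                    as.integer(regions$end))
  m <- matrix(0, nrow = nrow(regions), ncol = length(tracks),
              dimnames = list(labels, names(tracks)))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    for (s in seq_along(tracks)) {
      v <- IRanges::Views(tracks[[s]]$cov[[chr]],
                          start = regions$start[ri] + 1,
                          end = regions$end[ri])
      m[ri, s] <- as.numeric(IRanges::viewSums(v))
    }
  }
  m <- pmax(round(m), 0)
  storage.mode(m) <- "double"
  attr(m, "regions") <- regions[, c("chrom", "start", "end")]
  m
}

#' Composition scaling factors for a count matrix
#'
#' * `none`: all factors 1.
#' * `upperquartile`: each sample's 75th percentile of its non-zero region
#'   counts; depth-absorbing.
#' * `rle`: median-of-ratios to the per-region geometric mean (computed over
#'   regions with all-positive counts); depth-absorbing.
#' * `tmm`: trimmed mean of M-values against the reference column whose
#'   upper quartile is closest to the mean upper quartile, with the standard
#'   recipe (30% two-sided trim on M, 5% on A, precision weighting);
#'   library-size-relative.
#'
#' All factors are rescaled to geometric mean 1. The attribute
#' `libsize_relative` records whether the factors must be combined with
#' column sums to form effective library sizes (`tmm`, `none`) or already
#' are effective sizes (`rle`, `upperquartile`); [nb_test()] uses it to
#' build coherent offsets.
#'
#' @param m Count matrix (regions x samples, >= 2 samples).
#' @param method One of `"rle"`, `"tmm"`, `"upperquartile"`, `"none"`.
#' @return Named positive numeric vector with attribute `libsize_relative`.
#' @export
norm_factors <- function(m, method = c("rle", "tmm", "upperquartile", "none")) {
  method <- match.arg(method)
  if (ncol(m) < 2L) stop("norm_factors needs >= 2 samples")
  f <- switch(method,
    none = rep(1, ncol(m)),
    upperquartile = {
      uq <- apply(m, 2L, function(y) {
        y <- y[y > 0]
        if (!length(y)) stop("a sample has no non-zero regions")
        stats::quantile(y, 0.75, names = FALSE)
      })
      uq
    },
    rle = {
      pos <- rowSums(m > 0) == ncol(m)
      if (!any(pos))
        stop("rle scaling needs at least one region with all-positive counts; ",
             "consider upperquartile or tmm")
      lg <- log(m[pos, , drop = FALSE])
      geo <- rowMeans(lg)
      apply(lg, 2L, function(col) exp(stats::median(col - geo)))
    },
    tmm = {
      lib <- colSums(m)
      uq_rel <- vapply(seq_len(ncol(m)), function(j) {
        y <- m[, j]; y <- y[y > 0]
        if (!length(y)) stop("a sample has no non-zero regions")
        stats::quantile(y, 0.75, names = FALSE) / lib[j]
      }, 0)
      ref <- which.min(abs(uq_rel - mean(uq_rel)))
      vapply(seq_len(ncol(m)), function(j)
        tmm_pair(m[, j], m[, ref], lib[j], lib[ref]), 0)
    })
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  attr(f, "libsize_relative") <- method %in% c("tmm", "none")
  attr(f, "method") <- method
  f
}

# Standard precision-weighted TMM factor of sample y against reference r.
tmm_pair <- function(y, r, ny, nr, trim_m = 0.3, trim_a = 0.05) {
  keep <- y > 0 & r > 0
  y <- y[keep]; r <- r[keep]
  if (!length(y)) return(1)
  M <- log2((y / ny) / (r / nr))
  A <- 0.5 * log2((y / ny) * (r / nr))
  w <- 1 / ((ny - y) / (ny * y) + (nr - r) / (nr * r))
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0L) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M, ties.method = "first") >= loM &
          rank(M, ties.method = "first") <= hiM &
          rank(A, ties.method = "first") >= loA &
          rank(A, ties.method = "first") <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

#' Drop regions with low total counts
#'
#' Keeps regions whose row sum across all samples reaches `min_total`
#' (row-total convention).
#'
#' @param m Count matrix.
#' @param min_total Non-negative integer.
#' @export
filter_low_counts <- function(m, min_total) {
  stopifnot(min_total >= 0)
  keep <- rowSums(m) >= min_total
  out <- m[keep, , drop = FALSE]
  r <- attr(m, "regions")
  if (!is.null(r)) attr(out, "regions") <- r[keep, , drop = FALSE]
  out
}

# Effective library sizes from factors + column sums, geometric mean 1.
effective_sizes <- function(m, factors) {
  if (is.null(factors)) factors <- rep(1, ncol(m))
  rel <- attr(factors, "libsize_relative")
  if (is.null(rel)) rel <- TRUE
  eff <- if (rel) as.numeric(factors) * colSums(m) else as.numeric(factors)
  if (any(!is.finite(eff) | eff <= 0))
    stop("effective library sizes must be positive")
  eff / exp(mean(log(eff)))
}

# Vectorized per-group NB log-mean fit with known dispersion and offsets.
# Returns beta (log mean at unit effective size) and Fisher information.
nb_group_fit <- function(Y, eff, phi, iter = 50L, tol = 1e-10) {
  tot <- rowSums(Y)
  S <- sum(eff)
  zero <- tot == 0
  beta <- log(pmax(tot, 0.5) / S)
  for (i in seq_len(iter)) {
    mu <- exp(beta) %o% eff
    denom <- 1 + mu * phi
    score <- rowSums((Y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / info
    step[zero] <- 0
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% eff
  info <- rowSums(mu / (1 + mu * phi))
  list(beta = beta, info = info, zero = zero)
}

#' Negative binomial Wald test for differential binding
#'
#' Per region, fits the NB log-linear model
#' `mean = exp(beta0 + beta1 * 1[condition B]) * effective_size_s` and Wald-
#' tests `beta1 = 0`; `log2FC = beta1 / ln 2` is the B-over-A contrast.
#' Dispersion is a per-region method-of-moments estimate shrunk toward the
#' common (mean) dispersion with precision-based weight
#' `df / (df + prior_df)` (residual df over prior df, the empirical-Bayes
#' moderation convention), floored at 1e-6 — a deliberately simple, fully
#' reproducible estimator rather than a replica of any external engine's
#' shrinkage. At typical replicate counts the per-region moment estimate
#' has only a handful of degrees of freedom; the prior-df weighting keeps
#' its sampling noise from understating Wald standard errors (with
#' `prior_df = 0` the raw per-region estimate is used unshrunk).
#' P-values are BH-adjusted and regions are
#' classified `gain` / `loss` / `ns` against `alpha` and the `lfc` cutoff
#' (applied post hoc to the point estimate).
#'
#' @param m Count matrix (regions x samples; rownames `chrom:start-end`).
#' @param sheet Sample sheet (conditions looked up by sample_id).
#' @param contrast Length-2 character: `c(condA, condB)`; fold changes are B
#'   over A. Each condition needs >= 2 replicates.
#' @param factors Output of [norm_factors()] (or `NULL` for none).
#' @param offsets `"effective"`: offsets from effective library sizes
#'   (factors combined with column sums as recorded by [norm_factors()]);
#'   `"none"`: no offsets at all — for expected near-complete unidirectional
#'   signal loss, where depth itself carries the biology.
#' @param alpha BH-adjusted significance threshold in (0,1).
#' @param lfc Absolute log2 fold-change cutoff (>= 0).
#' @param prior_df Prior degrees of freedom of the common dispersion in the
#'   moderation weight (default 20).
#' @return Data frame of class `diff_result`: `region`, `chrom`, `start`,
#'   `end`, `base_mean`, `log2fc`, `lfc_se`, `stat`, `pvalue`, `padj`,
#'   `class`.
#' @export
nb_test <- function(m, sheet, contrast, factors = NULL,
                    offsets = c("effective", "none"),
                    alpha = 0.05, lfc = 0, prior_df = 20) {
  offsets <- match.arg(offsets)
  stopifnot(length(contrast) == 2L, alpha > 0, alpha < 1, lfc >= 0,
            prior_df >= 0)
  cond <- sheet$condition[match(colnames(m), sheet$sample_id)]
  if (any(is.na(cond)))
    stop("matrix columns missing from sample sheet: ",
         paste(colnames(m)[is.na(cond)], collapse = ", "))
  selA <- cond == contrast[1L]
  selB <- cond == contrast[2L]
  if (sum(selA) < 2L || sum(selB) < 2L)
    stop("replicates required: each contrast condition needs >= 2 samples")
  sub <- m[, selA | selB, drop = FALSE]
  eff <- if (offsets == "effective") {
    e <- effective_sizes(m, factors)[selA | selB]
    e / exp(mean(log(e)))
  } else rep(1, ncol(sub))
  gA <- cond[selA | selB] == contrast[1L]

  # dispersion: MoM on depth-normalized counts, pooled within-group variance
  z <- sweep(sub, 2L, eff, "/")
  vg <- function(x) {
    mu <- rowMeans(x)
    v <- rowSums((x - mu)^2) / (ncol(x) - 1L)
    list(mu = mu, v = v, df = ncol(x) - 1L)
  }
  a <- vg(z[, gA, drop = FALSE]); b <- vg(z[, !gA, drop = FALSE])
  v_pool <- (a$v * a$df + b$v * b$df) / (a$df + b$df)
  m_bar <- rowMeans(z)
  phi_raw <- ifelse(m_bar > 0, pmax((v_pool - m_bar) / m_bar^2, 0), 0)
  phi_common <- if (any(m_bar > 0)) mean(phi_raw[m_bar > 0]) else 0
  df_resid <- a$df + b$df
  w_obs <- df_resid / (df_resid + prior_df)
  phi <- pmax(w_obs * phi_raw + (1 - w_obs) * phi_common, 1e-6)

  fa <- nb_group_fit(sub[, gA, drop = FALSE], eff[gA], phi)
  fb <- nb_group_fit(sub[, !gA, drop = FALSE], eff[!gA], phi)
  both_zero <- fa$zero & fb$zero
  lfc_ln <- fb$beta - fa$beta
  se_ln <- sqrt(1 / fa$info + 1 / fb$info)
  stat <- lfc_ln / se_ln
  pvalue <- 2 * stats::pnorm(-abs(stat))
  lfc_ln[both_zero] <- 0
  pvalue[both_zero] <- NA_real_
  padj <- rep(NA_real_, length(pvalue))
  padj[!is.na(pvalue)] <- stats::p.adjust(pvalue[!is.na(pvalue)], "BH")

  reg <- attr(m, "regions")
  if (is.null(reg)) reg <- parse_region_labels(rownames(m))
  out <- data.frame(region = rownames(sub),
                    chrom = reg$chrom, start = reg$start, end = reg$end,
                    base_mean = m_bar,
                    log2fc = lfc_ln / log(2),
                    lfc_se = se_ln / log(2),
                    stat = stat, pvalue = pvalue, padj = padj)
  out$class <- classify_regions(out$padj, out$log2fc, alpha, lfc)
  attr(out, "contrast") <- contrast
  attr(out, "alpha") <- alpha
  attr(out, "lfc") <- lfc
  attr(out, "dispersion_common") <- phi_common
  class(out) <- c("diff_result", "data.frame")
  rownames(out) <- NULL
  out
}

parse_region_labels <- function(labels) {
  mt <- regmatches(labels, regexec("^(.*):([0-9]+)-([0-9]+)$", labels))
  data.frame(chrom = vapply(mt, `[`, "", 2L),
             start = as.numeric(vapply(mt, `[`, "", 3L)),
             end = as.numeric(vapply(mt, `[`, "", 4L)))
}

classify_regions <- function(padj, log2fc, alpha, lfc) {
  cls <- rep("ns", length(padj))
  sig <- !is.na(padj) & padj < alpha
  # at lfc == 0 a fold change of exactly 0 stays ns (cannot be both classes)
  cls[sig & log2fc >= lfc & log2fc > 0] <- "gain"
  cls[sig & log2fc <= -lfc & log2fc < 0] <- "loss"
  cls
}

#' Classify regions and export gain/loss BEDs
#'
#' Re-applies the `alpha`/`lfc` rule to a [nb_test()] table and, when an
#' output directory is given, writes sorted `gain.bed` and `loss.bed` plus
#' the full tab-separated results table.
#'
#' @param results A `diff_result` data frame.
#' @param alpha Adjusted-p threshold.
#' @param lfc Absolute log2FC cutoff.
#' @param out_dir Optional output directory.
#' @param prefix File name prefix (default `"diff"`).
#' @param header Optional `#`-comment lines for the files.
#' @return List with `gain`, `loss` (region data frames) and `table` (the
#'   reclassified results).
#' @export
classify_and_export <- function(results, alpha = 0.05, lfc = 0,
                                out_dir = NULL, prefix = "diff",
                                header = NULL) {
  results$class <- classify_regions(results$padj, results$log2fc, alpha, lfc)
  pick <- function(cls) {
    r <- results[results$class == cls,
                 c("chrom", "start", "end", "region", "log2fc", "padj")]
    canonical_regions(r)
  }
  gain <- pick("gain"); loss <- pick("loss")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_regions(gain, file.path(out_dir, paste0(prefix, "_gain.bed")),
                  header = header)
    write_regions(loss, file.path(out_dir, paste0(prefix, "_loss.bed")),
                  header = header)
    write_tsv(results, file.path(out_dir, paste0(prefix, "_results.tsv")),
              header = header)
  }
  list(gain = gain, loss = loss, table = results)
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- lapply(df, function(v) if (is.numeric(v)) format_signal_na(v)
                 else as.character(v))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

format_signal_na <- function(v) {
  out <- rep("NA", length(v))
  ok <- !is.na(v)
  out[ok] <- format_signal(v[ok])
  out
}

read_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  utils::read.table(text = lines, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
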