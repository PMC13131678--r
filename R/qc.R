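#' Bin genome-wide signal into a matrix
#'
#' Tiles every chromosome into fixed-width bins (the terminal bin of a
#' chromosome keeps its true, shorter width) and records the mean per-base
#' signal of each sample in each bin. The binned matrix feeds the PCA and
#' correlation diagnostics run before and after normalization.
#'
#' @param tracks Named list of `signal_track`s.
#' @param genome Genome index (defaults to the tracks' genome).
#' @param bin_width Bin width in bp (default 10 kb).
#' @return A `bin_matrix`: list with `bins` (region data frame) and `values`
#'   (bins x samples numeric matrix).
#' @export
bin_signal <- function(tracks, genome = NULL, bin_width = 10000L) {
  stopifnot(bin_width >= 1)
  if (is.null(genome)) genome <- check_same_genome(tracks) else {
    genome <- validate_genome(genome)
    check_same_genome(tracks)
  }
  bins <- do.call(rbind, lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = chr, start = starts, end = pmin(starts + bin_width, len))
  }))
  values <- vapply(tracks, function(t) {
    unlist(lapply(names(genome), function(chr) {
      b <- bins[bins$chrom == chr, , drop = FALSE]
      as.numeric(IRanges::viewMeans(IRanges::Views(t$cov[[chr]],
                                                   start = b$start + 1,
                                                   end = b$end)))
    }), use.names = FALSE)
  }, numeric(nrow(bins)))
  if (is.null(dim(values))) values <- matrix(values, nrow = nrow(bins),
                                             dimnames = list(NULL, names(tracks)))
  structure(list(bins = bins, values = values), class = "bin_matrix")
}

#' PCA of binned signal
#'
#' Samples are observations, bins are features; the matrix is optionally
#' log2(x+1)-transformed (default, to tame the heavy right tail of coverage)
#' and centered. PC signs are fixed by forcing the largest-magnitude loading
#' of each component to be positive, so output is deterministic.
#'
#' @param bm A [bin_signal()] matrix.
#' @param log_transform Apply log2(x+1) before PCA.
#' @return List with `coordinates` (samples x PCs data frame),
#'   `variance_fraction` (non-increasing, sums to <= 1) and `loadings`.
#' @export
pca_coordinates <- function(bm, log_transform = TRUE) {
  stopifnot(inherits(bm, "bin_matrix"))
  x <- t(bm$values)
  if (nrow(x) < 2L) stop("PCA needs >= 2 samples")
  if (log_transform) x <- log2(x + 1)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as.data.frame(pc$x)
  coords <- cbind(sample_id = rownames(x), coords)
  rownames(coords) <- NULL
  list(coordinates = coords,
       variance_fraction = vf[seq_len(ncol(pc$x))],
       loadings = pc$rotation)
}

#' Sample-sample correlation of binned signal
#'
#' @param bm A [bin_signal()] matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric matrix with unit diagonal; a zero-variance sample gets
#'   `NA` against every other sample.
#' @export
correlation_matrix <- function(bm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(bm, "bin_matrix"))
  if (ncol(bm$values) < 2L) stop("correlation needs >= 2 samples")
  cm <- suppressWarnings(stats::cor(bm$values, method = method))
  diag(cm) <- 1
  cm
}
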