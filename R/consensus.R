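#' Pool replicate tracks of one condition
#'
#' Per-base sum of the member tracks; the pooled track is what the built-in
#' caller (or an external caller run per condition) sees.
#'
#' @param tracks Non-empty list of `signal_track`s on the same genome.
#' @export
pool_condition_signal <- function(tracks) {
  if (length(tracks) == 0L) stop("pool_condition_signal needs at least one track")
  genome <- check_same_genome(tracks)
  cov <- S4Vectors::SimpleList(lapply(names(genome), function(chr)
    Reduce(`+`, lapply(tracks, function(t) t$cov[[chr]]))))
  names(cov) <- names(genome)
  new_signal_track(cov, genome)
}

# Window sums of an Rle in fixed tiles (last tile may be short).
window_sums <- function(r, w) {
  len <- length(r)
  n <- ceiling(len / w)
  starts <- seq(1L, by = w, length.out = n)
  ends <- pmin(starts + w - 1L, len)
  list(starts = starts, ends = ends,
       sums = as.numeric(IRanges::viewSums(IRanges::Views(r, start = starts,
                                                          end = ends))))
}

#' Minimal Poisson window peak caller
#'
#' A self-contained caller for testing and for users without external peak
#' files; ENCODE narrowPeak/broadPeak ingestion via [read_peaks()] is the
#' first-class path for externally called peaks. The genome is tiled into
#' non-overlapping windows; each window's (rounded) summed signal is tested
#' against a Poisson upper tail with rate `lambda = max(genome-wide mean
#' window signal, scaled control window mean)`; p-values are BH-adjusted
#' across all windows; significant windows (q at or below the loosest grid
#' threshold) are merged into peaks whose `neg_log10_q` is the max over
#' member windows.
#'
#' @param pooled Pooled condition `signal_track`.
#' @param control Optional control `signal_track` (scaled to the pooled
#'   track's total before use as a local rate).
#' @param genome Genome index (defaults to the track's).
#' @param mode `"narrow"` (200 bp windows, adjacent-window merge) or
#'   `"broad"` (500 bp windows, merge across gaps of up to two windows).
#' @param window Window width in bp (overrides the mode default).
#' @param merge_gap Max gap (bp) between significant windows merged into one
#'   peak (overrides the mode default).
#' @param q_max Retain windows with BH-adjusted q at or below this; use the
#'   loosest threshold of the downstream grid.
#' @return Peak data frame: `chrom`, `start`, `end`, `name`, `score`,
#'   `neg_log10_q` (score duplicates `neg_log10_q`).
#' @export
call_peaks_builtin <- function(pooled, control = NULL, genome = NULL,
                               mode = c("narrow", "broad"), window = NULL,
                               merge_gap = NULL, q_max = 0.1) {
  mode <- match.arg(mode)
  if (is.null(genome)) genome <- track_genome(pooled)
  if (is.null(window)) window <- if (mode == "narrow") 200L else 500L
  if (is.null(merge_gap)) merge_gap <- if (mode == "narrow") 0L else 2L * window
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (all(genome < window))
    stop("window (", window, " bp) larger than every chromosome")
  if (!is.null(control)) {
    check_same_genome(list(pooled, control))
    ctrl_total <- track_total(control)
    ratio <- if (ctrl_total > 0) track_total(pooled) / ctrl_total else 0
  }
  per_chrom <- lapply(names(genome), function(chr) {
    ws <- window_sums(pooled$cov[[chr]], window)
    lam_ctrl <- if (!is.null(control))
      as.numeric(IRanges::viewMeans(IRanges::Views(control$cov[[chr]],
                                                   start = ws$starts,
                                                   end = ws$ends))) * window * ratio
    else 0
    data.frame(chrom = chr, start = ws$starts - 1, end = ws$ends,
               count = round(ws$sums), raw = ws$sums, lam_ctrl = lam_ctrl)
  })
  win <- do.call(rbind, per_chrom)
  lambda_global <- mean(win$raw)
  lambda <- pmax(lambda_global, win$lam_ctrl)
  p <- stats::ppois(win$count - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= q_max & win$count > 0
  if (!any(sig))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      neg_log10_q = numeric()))
  sw <- win[sig, c("chrom", "start", "end")]
  sw$neg_log10_q <- -log10(pmax(q[sig], 1e-300))
  sw <- canonical_regions(sw, genome)
  peaks <- merge_regions(sw, merge_gap)
  # assign each significant window to its merged peak, take max -log10(q)
  idx <- region_membership(sw, peaks)
  peak_q <- vapply(seq_len(nrow(peaks)), function(i)
    max(sw$neg_log10_q[idx == i]), 0)
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  peaks$score <- peak_q
  peaks$neg_log10_q <- peak_q
  peaks
}

# For each query region (subset of merged output), the index of the merged
# region containing it. Both canonical, merged regions disjoint.
region_membership <- function(queries, merged) {
  idx <- integer(nrow(queries))
  for (chr in unique(queries$chrom)) {
    qi <- which(queries$chrom == chr)
    mi <- which(merged$chrom == chr)
    idx[qi] <- mi[findInterval(queries$start[qi], merged$start[mi])]
  }
  idx
}

#' Filter peaks at a q-value threshold
#'
#' Keeps peaks with q-value at or below the threshold, i.e.
#' `neg_log10_q >= -log10(q_threshold)`. Peaks whose q-value is unknown
#' (`NA`, the narrowPeak `-1` sentinel) are always dropped.
#'
#' @param peaks Peak data frame with a `neg_log10_q` column.
#' @param q_threshold Threshold in (0, 1].
#' @export
filter_peaks_by_q <- function(peaks, q_threshold) {
  stopifnot(q_threshold > 0, q_threshold <= 1)
  keep <- !is.na(peaks$neg_log10_q) & peaks$neg_log10_q >= -log10(q_threshold)
  peaks[keep, , drop = FALSE]
}

#' Merge nearby regions
#'
#' Regions on the same chromosome separated by a gap of at most `d` bp are
#' combined transitively into single intervals (the external interval
#' toolkit's `-d` semantics: a gap exactly equal to `d` merges; `d = 0`
#' merges overlapping and book-ended regions). Idempotent at fixed `d`;
#' output regions are pairwise separated by gaps greater than `d`.
#'
#' @param regions Region data frame (`chrom`, `start`, `end`).
#' @param d Non-negative merge distance in bp.
#' @export
merge_regions <- function(regions, d) {
  stopifnot(d >= 0)
  if (nrow(regions) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  regions <- canonical_regions(regions[, c("chrom", "start", "end")])
  out <- lapply(unique(regions$chrom), function(chr) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(r$start + 1, r$end),
                          min.gapwidth = d + 1)
    data.frame(chrom = chr, start = IRanges::start(ir) - 1,
               end = IRanges::end(ir))
  })
  do.call(rbind, out)
}

#' Build the consensus-region grid
#'
#' For every combination of q-value threshold and merge distance: filter
#' each condition's peaks at q, concatenate across conditions, sort, and
#' merge at d. The defaults (five thresholds x five distances) give 25
#' candidate consensus sets; both lists are fully configurable. Stricter q
#' reduces false-positive regions; larger d combines nearby enrichments
#' into broader intervals.
#'
#' @param per_condition_peaks Named list (condition -> peak data frame).
#' @param q_list q-value thresholds in (0, 1].
#' @param d_list Non-negative merge distances (bp).
#' @return A `consensus_grid` object: list with `q_thresholds`,
#'   `merge_distances` and `cells` (named `q{q}_d{d}`, each with `q`, `d`,
#'   `regions`).
#' @export
build_consensus_grid <- function(per_condition_peaks,
                                 q_list = c(0.1, 0.05, 0.01, 0.001, 1e-04),
                                 d_list = c(0L, 50L, 100L, 250L, 500L)) {
  if (length(per_condition_peaks) == 0L) stop("need at least one condition")
  if (length(q_list) == 0L || length(d_list) == 0L)
    stop("q_list and d_list must be non-empty")
  stopifnot(all(q_list > 0), all(q_list <= 1), all(d_list >= 0))
  cells <- list()
  for (q in q_list) {
    filt <- lapply(per_condition_peaks, filter_peaks_by_q, q_threshold = q)
    pooled <- do.call(rbind, lapply(filt, function(p)
      if (nrow(p)) p[, c("chrom", "start", "end")] else NULL))
    if (is.null(pooled))
      pooled <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
    for (d in d_list) {
      cells[[cell_name(q, d)]] <-
        list(q = q, d = d, regions = merge_regions(pooled, d))
    }
  }
  structure(list(q_thresholds = q_list, merge_distances = d_list,
                 cells = cells),
            class = "consensus_grid")
}

cell_name <- function(q, d) sprintf("q%s_d%d", format(q, scientific = FALSE,
                                                      drop0trailing = TRUE),
                                    as.integer(d))

#' @export
print.consensus_grid <- function(x, ...) {
  cat(sprintf("<consensus_grid> %d q-threshold(s) x %d merge distance(s) = %d cells\n",
              length(x$q_thresholds), length(x$merge_distances),
              length(x$cells)))
  invisible(x)
}

#' Summarize a consensus grid
#'
#' One row per cell: thresholds, number of regions, width min / median /
#' mean / max and total covered bp (widths `NA` for empty cells).
#'
#' @param grid A [build_consensus_grid()] result.
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "consensus_grid"))
  rows <- lapply(grid$cells, function(cell) {
    w <- cell$regions$end - cell$regions$start
    data.frame(q = cell$q, d = cell$d, n_regions = length(w),
               width_min = if (length(w)) min(w) else NA_real_,
               width_median = if (length(w)) stats::median(w) else NA_real_,
               width_mean = if (length(w)) mean(w) else NA_real_,
               width_max = if (length(w)) max(w) else NA_real_,
               total_bp = sum(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
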