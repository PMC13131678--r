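#' Detect local maxima of a signal track
#'
#' A local maximum is a maximal constant-value plateau whose value strictly
#' exceeds the signal immediately flanking it on both sides; the flank value
#' beyond the first/last covered base of a chromosome — and across any
#' zero-coverage gap — is 0, so isolated plateaus qualify. On a track whose
#' runs are all 1 bp wide this degenerates to the per-bin rule (a bin higher
#' than both neighbouring bins); evaluating at plateau level is what makes
#' the rule well-defined on integer-valued coverage with flat peak tops.
#'
#' Detection is invariant under multiplication of the track by a positive
#' constant: the same plateaus are found, with scaled values.
#'
#' @param track A [signal_track()].
#' @return Data frame `chrom`, `start`, `end`, `value` (0-based half-open
#'   plateaus), sorted by genome order then start. Empty track gives zero
#'   rows.
#' @export
find_local_maxima <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  out <- lapply(names(track$genome), function(chr) {
    r <- track$cov[[chr]]
    v <- S4Vectors::runValue(r)
    l <- as.numeric(S4Vectors::runLength(r))
    n <- length(v)
    if (n == 0L) return(NULL)
    left <- c(0, v[-n])   # chromosome ends flank with 0
    right <- c(v[-1L], 0)
    keep <- v > left & v > right & v > 0
    if (!any(keep)) return(NULL)
    e <- cumsum(l)
    s <- e - l
    data.frame(chrom = chr, start = s[keep], end = e[keep], value = v[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  rownames(out) <- NULL
  out
}

#' Percentile of local-maxima values
#'
#' The per-sample summary used for scaling: the p-th percentile (linear
#' interpolation between closest ranks, the common default estimator) of the
#' multiset of local-maximum values. Each plateau contributes exactly one
#' value regardless of its width.
#'
#' @param maxima Output of [find_local_maxima()], or a numeric vector of
#'   plateau values.
#' @param p Percentile in (0, 100]; default 99 — high enough to sit in the
#'   enriched upper tail, below the outlier-dominated 100th.
#' @export
p99_of_maxima <- function(maxima, p = 99) {
  v <- if (is.data.frame(maxima)) maxima$value else as.numeric(maxima)
  if (length(v) == 0L)
    stop("no signal maxima; sample unusable for normalization")
  stats::quantile(v, probs = p / 100, type = 7, names = FALSE)
}

#' Derive per-sample scaling multipliers against a reference
#'
#' For one target group, the reference is the first sample of that group in
#' the sample sheet. The applied multiplier is
#' `m_sample = P99_reference / P99_sample`, so that after [scale_track()]
#' every sample's P99 of local maxima equals the reference's. The
#' conventional printed scaling factor `SF = P99_sample / P99_reference` is
#' also reported; `literal_sf = TRUE` applies that ratio as the multiplier
#' instead (which amplifies rather than removes scale differences — kept as
#' an explicit opt-in only).
#'
#' @param p99_by_sample Named numeric vector, P99 per sample_id.
#' @param sheet A [parse_sample_sheet()] sample sheet.
#' @param target Target group (antibody / mark) to scale.
#' @param n_maxima Optional named vector of local-maxima counts, recorded in
#'   the report.
#' @param literal_sf Apply the printed SF instead of its reciprocal.
#' @return A data frame of class `normalization_report` with columns
#'   `sample_id`, `n_maxima`, `p99`, `sf` (printed), `multiplier` (applied),
#'   `reference` (logical); attribute `reference_sample_id`.
#' @export
compute_scaling <- function(p99_by_sample, sheet, target, n_maxima = NULL,
                            literal_sf = FALSE) {
  stopifnot(inherits(sheet, "sample_sheet"))
  grp <- sheet[sheet$target == target, , drop = FALSE]
  if (nrow(grp) == 0L) stop("no samples with target '", target, "'")
  ids <- grp$sample_id
  missing <- setdiff(ids, names(p99_by_sample))
  if (length(missing))
    stop("no P99 supplied for sample(s): ", paste(missing, collapse = ", "))
  p99 <- as.numeric(p99_by_sample[ids])
  bad <- ids[!is.finite(p99) | p99 <= 0]
  if (length(bad))
    stop("P99 must be positive; offending sample(s): ",
         paste(bad, collapse = ", "))
  ref <- ids[1L]
  sf <- p99 / p99[1L]
  mult <- if (literal_sf) sf else 1 / sf
  mult[1L] <- 1  # reference multiplier is exactly 1
  rep_df <- data.frame(
    sample_id = ids,
    n_maxima = if (is.null(n_maxima)) NA_integer_ else as.integer(n_maxima[ids]),
    p99 = p99, sf = sf, multiplier = mult,
    reference = ids == ref
  )
  attr(rep_df, "reference_sample_id") <- ref
  attr(rep_df, "percentile_estimator") <- "linear interpolation (type 7)"
  class(rep_df) <- c("normalization_report", "data.frame")
  rep_df
}

#' Multiply a track by a positive scaling multiplier
#'
#' @param track A `signal_track`.
#' @param multiplier Positive real.
#' @export
scale_track <- function(track, multiplier) {
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be positive")
  track_map(function(r, chr) r * multiplier, track)
}

# Exact branchless median of three numeric vectors.
median3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

#' Per-base median across tracks
#'
#' Computed by sweeping the union of run breakpoints; bases absent from a
#' track contribute 0. With an even number of tracks the median is the mean
#' of the two middle values. Used to build per-condition median tracks.
#'
#' @param tracks Non-empty list of `signal_track`s on the same genome.
#' @export
median_track <- function(tracks) {
  if (length(tracks) == 0L) stop("median_track needs at least one track")
  if (length(tracks) == 1L) return(tracks[[1L]])
  genome <- check_same_genome(tracks)
  k <- length(tracks)
  cov <- S4Vectors::SimpleList(lapply(names(genome), function(chr) {
    rles <- lapply(tracks, function(t) t$cov[[chr]])
    ends <- sort(unique(unlist(lapply(rles, function(r)
      cumsum(as.numeric(S4Vectors::runLength(r)))))))
    starts <- c(0, ends[-length(ends)])
    V <- vapply(rles, function(r) {
      run_starts <- cumsum(as.numeric(S4Vectors::runLength(r)))
      run_starts <- c(0, run_starts[-length(run_starts)])
      S4Vectors::runValue(r)[findInterval(starts, run_starts)]
    }, numeric(length(starts)))
    if (is.null(dim(V))) V <- matrix(V, nrow = length(starts))
    m <- if (k == 2L) (V[, 1L] + V[, 2L]) / 2
         else if (k == 3L) median3(V[, 1L], V[, 2L], V[, 3L])
         else apply(V, 1L, stats::median)
    S4Vectors::Rle(m, ends - starts)
  }))
  names(cov) <- names(genome)
  new_signal_track(cov, genome)
}

#' Normalize one target group of tracks
#'
#' Convenience orchestrator over [find_local_maxima()], [p99_of_maxima()],
#' [compute_scaling()] and [scale_track()]: detects maxima for every sample
#' of a target group, derives multipliers against the group's first sample,
#' and returns scaled tracks plus the report.
#'
#' @param tracks Named list of `signal_track`s (names are sample_ids).
#' @param sheet Sample sheet.
#' @param target Target group.
#' @param p Percentile (default 99).
#' @param literal_sf See [compute_scaling()].
#' @return List with `report` (a `normalization_report`), `tracks` (scaled,
#'   same names), and `maxima` (per-sample local maxima tables).
#' @export
normalize_target <- function(tracks, sheet, target, p = 99,
                             literal_sf = FALSE) {
  grp <- sheet[sheet$target == target, , drop = FALSE]
  ids <- grp$sample_id
  missing <- setdiff(ids, names(tracks))
  if (length(missing))
    stop("no track supplied for sample(s): ", paste(missing, collapse = ", "))
  maxima <- lapply(stats::setNames(ids, ids), function(id)
    find_local_maxima(tracks[[id]]))
  p99 <- vapply(maxima, p99_of_maxima, 0, p = p)
  n_max <- vapply(maxima, nrow, 0L)
  report <- compute_scaling(p99, sheet, target, n_maxima = n_max,
                            literal_sf = literal_sf)
  scaled <- lapply(stats::setNames(ids, ids), function(id)
    scale_track(tracks[[id]], report$multiplier[report$sample_id == id]))
  list(report = report, tracks = scaled, maxima = maxima)
}
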