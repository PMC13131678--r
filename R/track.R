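#' Run-length encoded genomic signal tracks
#'
#' A `signal_track` stores one non-negative real value per base of a genome,
#' run-length encoded per chromosome ([S4Vectors::Rle]). Bases not covered by
#' any stored run have value 0. Tracks are the common currency of the whole
#' pipeline: coverage, control subtraction, blacklist masking, normalization,
#' pooling, median tracks, region quantification and binning all operate on
#' them.
#'
#' The canonical form guarantees that adjacent runs never share a value
#' (automatic with `Rle`) and that exported runs (see [track_runs()]) omit
#' zero-valued stretches. Coordinates at the interface are 0-based half-open,
#' the BED/bedGraph convention.
#'
#' @param runs A data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals). Intervals must not overlap. Zero-valued
#'   rows are accepted and dropped.
#' @param genome Named numeric vector of chromosome lengths (a genome index,
#'   see [parse_chrom_sizes()]).
#' @return A `signal_track` object.
#' @examples
#' g <- c(chrA = 100)
#' t <- signal_track(data.frame(chrom = "chrA", start = 10, end = 20, value = 2),
#'                   genome = g)
#' track_runs(t)
#' @export
signal_track <- function(runs = NULL, genome) {
  genome <- validate_genome(genome)
  if (is.null(runs) || nrow(runs) == 0L) {
    return(new_signal_track(empty_cov(genome), genome))
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(runs)))
  runs$chrom <- as.character(runs$chrom)
  bad_chrom <- setdiff(unique(runs$chrom), names(genome))
  if (length(bad_chrom))
    stop("chromosomes not in genome index: ", paste(bad_chrom, collapse = ", "))
  if (any(!is.finite(runs$value)))
    stop("track values must be finite")
  cov <- lapply(names(genome), function(chr) {
    r <- runs[runs$chrom == chr, , drop = FALSE]
    runs_to_rle(r$start, r$end, r$value, genome[[chr]], chr)
  })
  names(cov) <- names(genome)
  new_signal_track(S4Vectors::SimpleList(cov), genome)
}

new_signal_track <- function(cov, genome) {
  structure(list(cov = cov, genome = genome), class = "signal_track")
}

empty_cov <- function(genome) {
  cov <- lapply(genome, function(len) S4Vectors::Rle(0, len))
  S4Vectors::SimpleList(cov)
}

#' @export
print.signal_track <- function(x, ...) {
  r <- track_runs(x)
  cat(sprintf("<signal_track> %d chromosome(s), %d non-zero run(s), total signal %.6g\n",
              length(x$genome), nrow(r), track_total(x)))
  invisible(x)
}

# Build a full-chromosome Rle from 0-based half-open runs, checking bounds
# and overlap. Gaps are filled with zeros.
runs_to_rle <- function(start, end, value, len, chrom = "?") {
  if (length(start) == 0L) return(S4Vectors::Rle(0, len))
  if (any(start < 0) || any(end > len) || any(start >= end))
    stop(sprintf("invalid interval on %s: need 0 <= start < end <= %d", chrom, len))
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- as.numeric(value[o])
  if (any(end[-length(end)] > start[-1L]))
    stop(sprintf("overlapping intervals on %s", chrom))
  gap_before <- start - c(0, end[-length(end)])
  lens <- as.vector(rbind(gap_before, end - start))
  vals <- as.vector(rbind(numeric(length(start)), value))
  tail_gap <- len - end[length(end)]
  if (tail_gap > 0) { lens <- c(lens, tail_gap); vals <- c(vals, 0) }
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' Extract the non-zero runs of a track
#'
#' @param x A `signal_track`.
#' @param drop_zero Drop zero-valued runs (the canonical export form).
#' @return Data frame with columns `chrom`, `start`, `end`, `value`, 0-based
#'   half-open, ordered by genome chromosome order then start.
#' @export
track_runs <- function(x, drop_zero = TRUE) {
  stopifnot(inherits(x, "signal_track"))
  out <- lapply(names(x$genome), function(chr) {
    r <- x$cov[[chr]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l))
    s <- e - l
    keep <- if (drop_zero) v != 0 else rep(TRUE, length(v))
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = s[keep], end = e[keep], value = v[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  rownames(out) <- NULL
  out
}

#' @rdname track_runs
#' @export
track_genome <- function(x) x$genome

#' Total signal of a track (sum of value x run length over the genome)
#' @param x A `signal_track`.
#' @export
track_total <- function(x) {
  sum(vapply(x$cov, function(r)
    sum(S4Vectors::runValue(r) * as.numeric(S4Vectors::runLength(r))), 0))
}

# Internal: apply a function over the per-chromosome Rle list(s) of one or
# more tracks sharing a genome, returning a new track.
track_map <- function(f, x, ...) {
  cov <- S4Vectors::SimpleList(lapply(names(x$genome), function(chr) f(x$cov[[chr]], chr)))
  names(cov) <- names(x$genome)
  new_signal_track(cov, x$genome)
}

same_genome <- function(x, y) {
  identical(names(x$genome), names(y$genome)) &&
    all(x$genome == y$genome)
}

check_same_genome <- function(tracks) {
  ref <- tracks[[1L]]
  for (t in tracks[-1L])
    if (!same_genome(ref, t)) stop("tracks are not on the same genome")
  invisible(ref$genome)
}

#' @export
all.equal.signal_track <- function(target, current, ...) {
  if (!same_genome(target, current)) return("different genomes")
  all.equal(track_runs(target), track_runs(current), ...)
}

# Shortest decimal representation that round-trips through as.numeric().
format_signal <- function(v) {
  out <- sprintf("%.6g", v)
  for (fmt in c("%.12g", "%.17g")) {
    bad <- which(as.numeric(out) != v)
    if (!length(bad)) break
    out[bad] <- sprintf(fmt, v[bad])
  }
  out
}

#' Read and write bedGraph signal files
#'
#' `read_bedgraph()` parses a 4-column bedGraph into a canonical
#' [signal_track()]: zero-valued lines are dropped, adjacent equal-valued
#' runs are merged, overlapping or out-of-bounds intervals are an error.
#' `write_bedgraph()` emits the non-zero runs sorted by genome order;
#' reading the result back yields an identical track.
#'
#' @param path File path.
#' @param genome Named numeric vector of chromosome lengths.
#' @param x A `signal_track`.
#' @param header Optional character vector of comment lines written with a
#'   leading `#` (readers skip `#`, `track` and `browser` lines).
#' @return `read_bedgraph()` a `signal_track`; `write_bedgraph()` the path,
#'   invisibly.
#' @export
read_bedgraph <- function(path, genome) {
  genome <- validate_genome(genome)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(signal_track(NULL, genome))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) stop("bedGraph requires 4 tab-separated columns")
  df <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                   start = as.numeric(vapply(f, `[[`, "", 2L)),
                   end   = as.numeric(vapply(f, `[[`, "", 3L)),
                   value = as.numeric(vapply(f, `[[`, "", 4L)))
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$value)))
    stop("malformed bedGraph numeric fields")
  signal_track(df, genome)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path, header = NULL) {
  r <- track_runs(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(r))
    writeLines(sprintf("%s\t%d\t%d\t%s", r$chrom, as.integer(r$start),
                       as.integer(r$end), format_signal(r$value)), con)
  invisible(path)
}

#' Optional bigWig interface
#'
#' Thin wrappers over rtracklayer for users who prefer bigWig; bedGraph is
#' the reference (bit-exact) format of the pipeline. Requires the
#' `rtracklayer` package.
#'
#' @param path File path.
#' @param genome Named numeric vector of chromosome lengths.
#' @param x A `signal_track`.
#' @export
read_bigwig <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("bigWig support requires the rtracklayer package")
  genome <- validate_genome(genome)
  gr <- rtracklayer::import.bw(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  signal_track(df[df$value != 0, , drop = FALSE], genome)
}

#' @rdname read_bigwig
#' @export
write_bigwig <- function(x, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("bigWig support requires the rtracklayer package")
  r <- track_runs(x)
  gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end),
                               score = r$value,
                               seqlengths = stats::setNames(as.integer(x$genome),
                                                            names(x$genome)))
  rtracklayer::export.bw(gr, path)
  invisible(path)
}
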