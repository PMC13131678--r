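#' Read-filtering and counting options for coverage
#'
#' @param mapq_min Minimum mapping quality (reads below are skipped).
#'   Thorough read filtering (duplicates, multimappers) is expected to have
#'   happened upstream; this is a convenience only.
#' @param mode `"SE"`: each primary mapped read contributes its aligned
#'   reference span. `"PE"`: each properly paired fragment is counted once,
#'   from the leftmost mate, over `[fragment_start, fragment_start + |TLEN|)`.
#' @param se_extend Optional fixed extension (bp) of SE reads from their 5'
#'   end, strand-aware. Ignored in PE mode.
#' @param clamp_negative Clamp negative values to zero after control
#'   subtraction (see [subtract_control()]).
#' @export
coverage_options <- function(mapq_min = 0L, mode = c("SE", "PE"),
                             se_extend = NULL, clamp_negative = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(se_extend) && mode == "PE")
    warning("se_extend is ignored in PE mode")
  stopifnot(mapq_min >= 0, is.null(se_extend) || se_extend >= 1)
  structure(list(mapq_min = as.integer(mapq_min), mode = mode,
                 se_extend = se_extend, clamp_negative = isTRUE(clamp_negative)),
            class = "coverage_options")
}

#' Per-base coverage from aligned reads
#'
#' Builds a 1 bp resolution [signal_track()] from a coordinate-sorted,
#' indexed BAM. In SE mode every primary, mapped, MAPQ-passing read
#' contributes its aligned span (optionally extended to a fixed fragment
#' length from its 5' end); in PE mode each properly paired fragment is
#' counted once via the leftmost mate and its TLEN. Pairs with TLEN 0 are
#' skipped (and counted in the returned attributes).
#'
#' @param bam_path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param genome Genome index; every chromosome seen in the BAM must be
#'   present.
#' @param opts A [coverage_options()] object.
#' @return A `signal_track`; attribute `n_units` holds the number of counted
#'   reads/fragments, `n_skipped` the skipped pair candidates (PE).
#' @export
coverage_from_alignments <- function(bam_path, genome,
                                     opts = coverage_options()) {
  genome <- validate_genome(genome)
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  idx <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(idx)))
    stop("BAM index (.bai) not found for ", bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  bad <- setdiff(names(hdr), names(genome))
  if (length(bad))
    stop("BAM chromosomes absent from genome index: ",
         paste(bad, collapse = ", "))
  n_skipped <- 0L
  if (opts$mode == "SE") {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = opts$mapq_min)
    ga <- GenomicAlignments::readGAlignments(bam_path, param = param)
    gr <- GenomicRanges::granges(ga)
    if (!is.null(opts$se_extend))
      gr <- GenomicRanges::resize(gr, width = opts$se_extend, fix = "start")
    frag <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr))
    if (!is.null(opts$se_extend)) {
      # extension may run off either chromosome end; clip to bounds
      frag$start <- pmax(frag$start, 1L)
      frag$end <- pmin(frag$end, as.integer(genome[frag$chrom]))
    }
  } else {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isProperPair = TRUE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = opts$mapq_min,
                                     what = c("rname", "pos", "isize"))
    b <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
    keep <- !is.na(b$isize) & b$isize > 0L
    n_skipped <- sum(!is.na(b$isize) & b$isize == 0L)
    frag <- data.frame(chrom = as.character(b$rname[keep]),
                       start = b$pos[keep],
                       end = b$pos[keep] + b$isize[keep] - 1L)
  }
  cov <- lapply(names(genome), function(chr) {
    f <- frag[frag$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0L) return(S4Vectors::Rle(0, genome[[chr]]))
    if (any(f$end > genome[[chr]]))
      stop("alignment beyond chromosome length on ", chr)
    r <- IRanges::coverage(IRanges::IRanges(f$start, f$end),
                           width = genome[[chr]])
    S4Vectors::Rle(as.numeric(S4Vectors::runValue(r)), S4Vectors::runLength(r))
  })
  names(cov) <- names(genome)
  out <- new_signal_track(S4Vectors::SimpleList(cov), genome)
  attr(out, "n_units") <- nrow(frag)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Subtract a scaled control track from an IP track
#'
#' The control is scaled to the IP's depth by the ratio of counted units
#' (`ip_total / control_total`) before per-base subtraction. Negative values
#' are clamped to zero by default, since downstream local-maxima and peak
#' statistics assume non-negative coverage.
#'
#' @param ip,control `signal_track`s on the same genome.
#' @param ip_total,control_total Counted units per sample (default: total
#'   signal of each track). `control_total` must be positive.
#' @param clamp Clamp negative differences to zero.
#' @export
subtract_control <- function(ip, control, ip_total = NULL,
                             control_total = NULL, clamp = TRUE) {
  check_same_genome(list(ip, control))
  if (is.null(ip_total)) ip_total <- track_total(ip)
  if (is.null(control_total)) control_total <- track_total(control)
  if (control_total == 0) stop("control_total must be positive")
  ratio <- ip_total / control_total
  cov <- S4Vectors::SimpleList(lapply(names(ip$genome), function(chr) {
    r <- ip$cov[[chr]] - control$cov[[chr]] * ratio
    if (clamp) r <- S4Vectors::Rle(pmax(S4Vectors::runValue(r), 0),
                                   S4Vectors::runLength(r))
    r
  }))
  names(cov) <- names(ip$genome)
  new_signal_track(cov, ip$genome)
}

#' Zero out signal inside blacklist regions
#'
#' Every base inside a blacklist region is set to 0 (runs are truncated at
#' region boundaries); all other bases are unchanged. An empty blacklist is
#' the identity. The operation is idempotent.
#'
#' @param track A `signal_track`.
#' @param blacklist Region data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @export
apply_blacklist <- function(track, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(track)
  blacklist <- canonical_regions(blacklist, track_genome(track))
  bl <- merge_regions(blacklist, 0L)
  track_map(function(r, chr) {
    b <- bl[bl$chrom == chr, , drop = FALSE]
    if (nrow(b) == 0L) return(r)
    mask_runs <- runs_to_rle(b$start, b$end, rep(1, nrow(b)),
                             length(r), chr)
    r * (1 - mask_runs)
  }, track)
}
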