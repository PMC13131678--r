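#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the normalization model
#' assumes: a peak landscape shared by all samples, per-sample global
#' depth/scale multipliers, negative-binomially over-dispersed fragment
#' counts per region, and (optionally) condition-specific fold changes in a
#' known subset of peaks. It does not model read sequences, mappability or
#' GC structure.
#'
#' Defaults describe a realistic small study: one 1 Mb chromosome, 300
#' peaks with lognormal widths (median 1 kb), background 0.02 fragments per
#' bp (~3x mean coverage at 150 bp fragments), 10x peak enrichment and NB
#' dispersion 0.05.
#'
#' @param genome Named vector of chromosome lengths.
#' @param n_peaks Number of non-overlapping peaks to place.
#' @param peak_width_median,peak_width_sdlog Lognormal width distribution
#'   (bp).
#' @param background_rate Expected background fragments per bp at unit
#'   depth.
#' @param enrichment Per-peak fragment-rate fold over background.
#' @param diff_fraction Fraction of peaks given a condition-B fold change.
#' @param diff_fold Magnitude of that fold (gains get `diff_fold`, losses
#'   `1/diff_fold`, split evenly).
#' @param nb_dispersion NB dispersion of per-region fragment counts.
#' @param fragment_length,read_length Fixed fragment and read lengths (bp).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @export
sim_config <- function(genome = c(chr_sim = 1e6), n_peaks = 300L,
                       peak_width_median = 1000, peak_width_sdlog = 0.4,
                       background_rate = 0.02, enrichment = 10,
                       diff_fraction = 0, diff_fold = 4,
                       nb_dispersion = 0.05, fragment_length = 150L,
                       read_length = 50L, seed = 1L) {
  genome <- validate_genome(genome)
  stopifnot(n_peaks >= 0, peak_width_median > 0, peak_width_sdlog >= 0,
            background_rate >= 0, enrichment > 0,
            diff_fraction >= 0, diff_fraction <= 1, diff_fold > 0,
            nb_dispersion > 0, fragment_length >= 1,
            read_length >= 1, read_length <= fragment_length)
  structure(list(genome = genome, n_peaks = as.integer(n_peaks),
                 peak_width_median = peak_width_median,
                 peak_width_sdlog = peak_width_sdlog,
                 background_rate = background_rate, enrichment = enrichment,
                 diff_fraction = diff_fraction, diff_fold = diff_fold,
                 nb_dispersion = nb_dispersion,
                 fragment_length = as.integer(fragment_length),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the ground-truth peak landscape
#'
#' Places `n_peaks` non-overlapping regions uniformly at random (rejection
#' sampling with a minimum gap of two fragment lengths, so fragment smear
#' cannot fuse adjacent truth peaks), then assigns a seeded subset
#' condition-B fold changes, alternating gain and loss.
#'
#' @param config A [sim_config()].
#' @return List with `regions` (canonical region data frame with `name`)
#'   and `folds` (data frame `name`, `fold`; fold applies to condition B).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gap <- 2L * config$fragment_length
  placed <- list()
  if (config$n_peaks > 0L) {
    chrom_p <- config$genome / sum(config$genome)
    occupied <- lapply(config$genome, function(len) IRanges::IRanges())
    tries <- 0L
    max_tries <- 200L * config$n_peaks
    while (length(placed) < config$n_peaks) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", config$n_peaks,
             " non-overlapping peaks; reduce n_peaks or widths")
      chr <- sample(names(config$genome), 1L, prob = chrom_p)
      w <- max(50L, round(stats::rlnorm(1L, log(config$peak_width_median),
                                        config$peak_width_sdlog)))
      len <- config$genome[[chr]]
      if (w + 2L * gap >= len) next
      s <- sample.int(len - w - gap, 1L) + gap %/% 2L  # 1-based start
      cand <- IRanges::IRanges(s - gap, s + w - 1L + gap)
      if (length(IRanges::findOverlaps(cand, occupied[[chr]])) > 0L) next
      occupied[[chr]] <- c(occupied[[chr]], cand)
      placed[[length(placed) + 1L]] <- data.frame(chrom = chr, start = s - 1L,
                                                  end = s - 1L + w)
    }
  }
  regions <- if (length(placed)) do.call(rbind, placed)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric())
  regions <- canonical_regions(regions, config$genome)
  if (nrow(regions))
    regions$name <- sprintf("peak_%04d", seq_len(nrow(regions)))
  else regions$name <- character()
  n_diff <- round(config$diff_fraction * nrow(regions))
  folds <- if (n_diff > 0) {
    ids <- sort(sample.int(nrow(regions), n_diff))
    data.frame(name = regions$name[ids],
               fold = rep_len(c(config$diff_fold, 1 / config$diff_fold),
                              n_diff))
  } else data.frame(name = character(), fold = numeric())
  list(regions = regions, folds = folds)
}

#' Simulate aligned fragments for one sample
#'
#' Per truth region, a fragment count drawn from
#' `NB(mean = background_rate * width * enrichment * multiplier * fold,
#' dispersion)` with starts uniform inside the region; background fragments
#' likewise across each chromosome. Fragments have fixed length and are
#' emitted as properly paired SAM records (coordinate-sorted, dummy
#' sequence), convertible to BAM with standard tooling
#' (e.g. [Rsamtools::asBam()], see [sam_to_bam()]).
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] result.
#' @param condition `"A"` or `"B"` (folds apply to B).
#' @param multiplier Per-sample global depth/scale multiplier.
#' @param multiplier_mode `"depth"`: the multiplier thins/amplifies fragment
#'   counts (sequencing-depth realism; note that count-noise extremes then
#'   grow like the square root of depth, not linearly). `"scale"`: fragments
#'   are sampled at the unit rate and the coverage track is multiplied by
#'   the factor afterwards — the "shared landscape times per-sample
#'   amplitude" structure the percentile normalization model assumes. SAM
#'   output is only available in depth mode (SAM records are raw
#'   fragments).
#' @param sample_id Used in read names only.
#' @param seed Seed for this sample (default the config seed; give each
#'   sample its own derived seed).
#' @param emit_sam Build the SAM text (skip for track-only studies).
#' @return List with `sam` (character lines or `NULL`), `track` (the
#'   realized fragment-coverage `signal_track`), `n_fragments`.
#' @export
simulate_alignments <- function(config, truth, condition = c("A", "B"),
                                multiplier = 1,
                                multiplier_mode = c("depth", "scale"),
                                sample_id = "sim",
                                seed = config$seed, emit_sam = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  multiplier_mode <- match.arg(multiplier_mode)
  if (multiplier_mode == "scale") {
    if (emit_sam && multiplier != 1)
      stop("SAM output represents raw fragments; use emit_sam = FALSE with ",
           "scale-mode multipliers")
    scale_by <- multiplier
    multiplier <- 1
  } else scale_by <- 1
  set.seed(as.integer(seed))
  fl <- config$fragment_length
  size <- 1 / config$nb_dispersion
  frags <- list()
  for (chr in names(config$genome)) {
    len <- config$genome[[chr]]
    max_start <- len - fl + 1L
    if (max_start < 1L) next
    # background over-dispersion is local: NB counts per 1 kb tile, like the
    # per-region counts below, rather than one draw per chromosome
    if (config$background_rate > 0) {
      tile <- 1000L
      tile_starts <- seq(0L, len - 1L, by = tile)
      tile_w <- pmin(tile_starts + tile, len) - tile_starts
      n_bg <- stats::rnbinom(length(tile_starts), size = size,
                             mu = config$background_rate * tile_w * multiplier)
      if (sum(n_bg) > 0) {
        ts <- rep(tile_starts, n_bg)
        tw <- rep(tile_w, n_bg)
        pos <- ts + ceiling(stats::runif(length(ts)) * tw)
        frags[[length(frags) + 1L]] <-
          data.frame(chrom = chr, start = pmin(as.integer(pos), max_start))
      }
    }
    reg <- truth$regions[truth$regions$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      fold <- 1
      if (condition == "B") {
        j <- match(reg$name[i], truth$folds$name)
        if (!is.na(j)) fold <- truth$folds$fold[j]
      }
      w <- reg$end[i] - reg$start[i]
      mu <- config$background_rate * w * config$enrichment * multiplier * fold
      n <- stats::rnbinom(1L, size = size, mu = mu)
      if (n > 0) {
        s <- reg$start[i] + sample.int(w, n, replace = TRUE)  # 1-based
        frags[[length(frags) + 1L]] <-
          data.frame(chrom = chr, start = pmin(s, max_start))
      }
    }
  }
  frags <- if (length(frags)) do.call(rbind, frags)
           else data.frame(chrom = character(), start = integer())
  frags <- frags[order(match(frags$chrom, names(config$genome)), frags$start), ,
                 drop = FALSE]
  cov <- lapply(names(config$genome), function(chr) {
    f <- frags[frags$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0L) return(S4Vectors::Rle(0, config$genome[[chr]]))
    r <- IRanges::coverage(IRanges::IRanges(f$start, width = fl),
                           width = config$genome[[chr]])
    S4Vectors::Rle(as.numeric(S4Vectors::runValue(r)), S4Vectors::runLength(r))
  })
  names(cov) <- names(config$genome)
  track <- new_signal_track(S4Vectors::SimpleList(cov), config$genome)
  if (scale_by != 1) track <- scale_track(track, scale_by)
  sam <- if (emit_sam) fragments_to_sam(frags, config, sample_id) else NULL
  list(sam = sam, track = track, n_fragments = nrow(frags))
}

fragments_to_sam <- function(frags, config, sample_id) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(config$genome),
                      as.integer(config$genome)))
  if (nrow(frags) == 0L) return(header)
  fl <- config$fragment_length
  rl <- config$read_length
  cigar <- sprintf("%dM", rl)
  seqd <- strrep("A", rl)
  quald <- strrep("I", rl)
  name <- sprintf("%s_frag_%07d", sample_id, seq_len(nrow(frags)))
  p1 <- frags$start
  p2 <- frags$start + fl - rl
  r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                name, frags$chrom, p1, cigar, p2, fl, seqd, quald)
  r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                name, frags$chrom, p2, cigar, p1, -fl, seqd, quald)
  recs <- data.frame(chrom = rep(frags$chrom, 2L), pos = c(p1, p2),
                     line = c(r1, r2))
  recs <- recs[order(match(recs$chrom, names(config$genome)), recs$pos), ]
  c(header, recs$line)
}

#' Convert SAM text lines to an indexed BAM
#'
#' @param sam_lines Character vector of SAM lines (with header).
#' @param prefix Output path prefix; writes `prefix.sam` then
#'   `prefix.bam` + `.bai`.
#' @return Path to the BAM.
#' @export
sam_to_bam <- function(sam_lines, prefix) {
  sam_path <- paste0(prefix, ".sam")
  writeLines(sam_lines, sam_path)
  bam <- Rsamtools::asBam(sam_path, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Simulate a full cohort with known truth
#'
#' Convenience wrapper producing the truth landscape and one sample per row
#' of `design`, each with its own derived seed (`config$seed + row index`).
#'
#' @param config A [sim_config()].
#' @param design Data frame with columns `sample_id`, `condition` (`"A"` or
#'   `"B"`) and `multiplier`.
#' @param multiplier_mode See [simulate_alignments()].
#' @param emit_sam Build SAM text per sample.
#' @return List with `truth`, `samples` (named list of
#'   [simulate_alignments()] results) and `design`.
#' @export
simulate_experiment <- function(config, design,
                                multiplier_mode = c("depth", "scale"),
                                emit_sam = TRUE) {
  stopifnot(all(c("sample_id", "condition", "multiplier") %in% names(design)))
  multiplier_mode <- match.arg(multiplier_mode)
  truth <- simulate_truth(config)
  # scale mode realizes the "shared latent landscape times per-sample
  # amplitude factor" structure: every sample reuses the same sampling seed,
  # so tracks are exact multiples of one latent track. Depth mode gives each
  # sample its own derived seed (independent sampling noise).
  samples <- lapply(seq_len(nrow(design)), function(i)
    simulate_alignments(config, truth,
                        condition = design$condition[i],
                        multiplier = design$multiplier[i],
                        multiplier_mode = multiplier_mode,
                        sample_id = design$sample_id[i],
                        seed = if (multiplier_mode == "scale") config$seed + 1L
                               else config$seed + i,
                        emit_sam = emit_sam))
  names(samples) <- design$sample_id
  list(truth = truth, samples = samples, design = design)
}
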