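pkg_version <- function() as.character(utils::packageVersion("epinorm"))

file_header <- function(stage, params) {
  sprintf("epinorm %s | %s | %s", pkg_version(), stage,
          paste(sprintf("%s=%s", names(params),
                        vapply(params, function(p) paste(format(p), collapse = ","),
                               "")),
                collapse = " "))
}

write_manifest <- function(out_dir, stage, params, outputs) {
  manifest <- list(tool = "epinorm", version = pkg_version(), stage = stage,
                   parameters = params, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Coverage (with optional control subtraction) for the samples of a sheet.
build_sample_tracks <- function(sheet, genome, opts, blacklist = NULL) {
  tracks <- list()
  for (i in seq_len(nrow(sheet))) {
    ip <- coverage_from_alignments(sheet$bam[i], genome, opts)
    if (!is.na(sheet$bam_control[i])) {
      ctrl <- coverage_from_alignments(sheet$bam_control[i], genome, opts)
      ip <- subtract_control(ip, ctrl,
                             ip_total = attr(ip, "n_units"),
                             control_total = attr(ctrl, "n_units"),
                             clamp = opts$clamp_negative)
    }
    if (!is.null(blacklist)) ip <- apply_blacklist(ip, blacklist)
    tracks[[sheet$sample_id[i]]] <- ip
  }
  tracks
}

write_qc_tables <- function(tracks, genome, out_dir, tag, bin_width, hdr) {
  bm <- bin_signal(tracks, genome, bin_width)
  pca <- pca_coordinates(bm)
  cm <- correlation_matrix(bm)
  write_tsv(pca$coordinates, file.path(out_dir, sprintf("qc_pca_%s.tsv", tag)),
            header = hdr)
  write_tsv(data.frame(component = paste0("PC", seq_along(pca$variance_fraction)),
                       variance_fraction = pca$variance_fraction),
            file.path(out_dir, sprintf("qc_pca_variance_%s.tsv", tag)),
            header = hdr)
  cm_df <- cbind(data.frame(sample_id = rownames(cm)), as.data.frame(cm))
  write_tsv(cm_df, file.path(out_dir, sprintf("qc_correlation_%s.tsv", tag)),
            header = hdr)
  invisible(NULL)
}

#' Run the normalization workflow
#'
#' For every chromatin target in the sample sheet (or the subset in
#' `targets`): build per-base coverage from the BAMs (control-subtracted
#' when a control is given, blacklist-masked when a blacklist is given),
#' detect local maxima, scale every sample so its P99 matches the target
#' group's first sample, and write per-sample normalized bedGraphs,
#' per-condition median tracks, the normalization report and binned-signal
#' PCA/correlation QC before and after scaling. Each target gets its own
#' output subdirectory.
#'
#' @param sheet Sample sheet (see [parse_sample_sheet()]).
#' @param genome Genome index.
#' @param out_dir Output directory.
#' @param blacklist Optional region data frame (or BED path) removed before
#'   normalization.
#' @param targets Targets to process (default: all in the sheet).
#' @param opts [coverage_options()].
#' @param p Percentile of local maxima (default 99).
#' @param literal_sf See [compute_scaling()].
#' @param keep_temp Also write raw (pre-scaling) bedGraphs and local-maxima
#'   BEDs, otherwise discarded.
#' @param bin_width QC bin width (default 10 kb).
#' @param tracks Optional named list of precomputed `signal_track`s keyed by
#'   sample_id, bypassing BAM reading (control subtraction and blacklist are
#'   then the caller's responsibility).
#' @return Invisibly, a named list per target with `report` and `tracks`.
#' @export
run_norm <- function(sheet, genome, out_dir, blacklist = NULL, targets = NULL,
                     opts = coverage_options(), p = 99, literal_sf = FALSE,
                     keep_temp = FALSE, bin_width = 10000L, tracks = NULL) {
  stopifnot(inherits(sheet, "sample_sheet"))
  genome <- validate_genome(genome)
  if (length(genome) == 0L) stop("genome index is empty")
  if (is.character(blacklist)) blacklist <- read_regions(blacklist, genome)
  if (is.null(targets)) targets <- unique(sheet$target)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (tg in targets) {
    grp <- sheet[sheet$target == tg, , drop = FALSE]
    if (nrow(grp) == 0L) stop("no samples with target '", tg, "'")
    tdir <- file.path(out_dir, tg)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    raw <- if (is.null(tracks)) build_sample_tracks(grp, genome, opts, blacklist)
           else {
             missing <- setdiff(grp$sample_id, names(tracks))
             if (length(missing))
               stop("no track supplied for sample(s): ",
                    paste(missing, collapse = ", "))
             tracks[grp$sample_id]
           }
    params <- list(target = tg, percentile = p, literal_sf = literal_sf,
                   mode = opts$mode, mapq_min = opts$mapq_min,
                   bin_width = bin_width)
    hdr <- file_header("norm", params)
    norm <- normalize_target(raw, grp, tg, p = p, literal_sf = literal_sf)
    outputs <- character()
    for (id in grp$sample_id) {
      f <- file.path(tdir, paste0(id, ".norm.bedGraph"))
      write_bedgraph(norm$tracks[[id]], f, header = hdr)
      outputs <- c(outputs, f)
      if (keep_temp) {
        write_bedgraph(raw[[id]], file.path(tdir, paste0(id, ".raw.bedGraph")),
                       header = hdr)
        mx <- norm$maxima[[id]]
        write_regions(mx, file.path(tdir, paste0(id, ".maxima.bed")),
                      header = hdr)
      }
    }
    for (cn in unique(grp$condition)) {
      ids <- grp$sample_id[grp$condition == cn]
      f <- file.path(tdir, sprintf("median_%s.bedGraph", cn))
      write_bedgraph(median_track(norm$tracks[ids]), f, header = hdr)
      outputs <- c(outputs, f)
    }
    write_tsv(as.data.frame(norm$report),
              file.path(tdir, "normalization_report.tsv"), header = hdr)
    write_qc_tables(raw, genome, tdir, "raw", bin_width, hdr)
    write_qc_tables(norm$tracks, genome, tdir, "normalized", bin_width, hdr)
    write_manifest(tdir, "norm", params, basename(outputs))
    results[[tg]] <- list(report = norm$report, tracks = norm$tracks)
  }
  invisible(results)
}

#' Run the consensus-region workflow
#'
#' Builds the q-threshold x merge-distance grid of candidate consensus
#' regions and writes one BED per cell (`consensus_q{q}_d{d}.bed`) plus a
#' summary table. Per-condition peaks come either from externally called
#' narrowPeak/broadPeak files (`peak_files`, the faithful path) or from the
#' built-in Poisson window caller run on pooled per-condition coverage
#' (`tracks` + `sheet` + `target`).
#'
#' @param genome Genome index.
#' @param out_dir Output directory.
#' @param peak_files Named list/vector, condition -> peak file path (or
#'   already-read peak data frames).
#' @param sheet,target,tracks Used when `peak_files` is absent: samples of
#'   `target` are grouped by condition, their tracks pooled and passed to
#'   [call_peaks_builtin()].
#' @param controls Optional named list, condition -> control `signal_track`
#'   for the built-in caller.
#' @param q_list,d_list Grid axes (defaults: five q-values x five merge
#'   distances = 25 sets).
#' @param mode,window Built-in caller settings (see [call_peaks_builtin()]).
#' @return Invisibly, the `consensus_grid`.
#' @export
run_consensus <- function(genome, out_dir, peak_files = NULL, sheet = NULL,
                          target = NULL, tracks = NULL, controls = NULL,
                          q_list = c(0.1, 0.05, 0.01, 0.001, 1e-04),
                          d_list = c(0L, 50L, 100L, 250L, 500L),
                          mode = c("narrow", "broad"), window = NULL) {
  mode <- match.arg(mode)
  genome <- validate_genome(genome)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(peak_files)) {
    per_cond <- lapply(peak_files, function(p)
      if (is.character(p)) read_peaks(p, genome) else p)
  } else {
    if (is.null(sheet) || is.null(tracks) || is.null(target))
      stop("either peak_files or sheet+target+tracks must be supplied")
    grp <- sheet[sheet$target == target, , drop = FALSE]
    if (nrow(grp) == 0L) stop("no samples with target '", target, "'")
    per_cond <- lapply(split(grp$sample_id, grp$condition), function(ids) {
      pooled <- pool_condition_signal(tracks[ids])
      call_peaks_builtin(pooled, control = controls[[grp$condition[1L]]],
                         genome = genome, mode = mode, window = window,
                         q_max = max(q_list))
    })
  }
  params <- list(q_list = q_list, d_list = d_list, mode = mode,
                 conditions = names(per_cond))
  hdr <- file_header("consensus", params)
  grid <- build_consensus_grid(per_cond, q_list = q_list, d_list = d_list)
  if (all(vapply(grid$cells, function(c) nrow(c$regions) == 0L, TRUE)))
    warning("no peaks passed any threshold; consensus sets are empty")
  outputs <- character()
  for (nm in names(grid$cells)) {
    f <- file.path(out_dir, sprintf("consensus_%s.bed", nm))
    write_regions(grid$cells[[nm]]$regions, f, header = hdr)
    outputs <- c(outputs, f)
  }
  write_tsv(grid_summary(grid), file.path(out_dir, "consensus_summary.tsv"),
            header = hdr)
  write_manifest(out_dir, "consensus", params, basename(outputs))
  invisible(grid)
}

#' Run the differential binding workflow
#'
#' Quantifies normalized signal over candidate regions, filters low-count
#' regions, derives composition scaling factors, runs the NB Wald test for
#' the requested contrast and writes the results table plus gain/loss BEDs
#' and a count-correlation QC table.
#'
#' @param sheet Sample sheet.
#' @param genome Genome index.
#' @param target Chromatin target to analyse (required).
#' @param contrast `c(condA, condB)`; fold changes are B over A.
#' @param regions Region data frame, or a BED path (a consensus grid cell
#'   or any user-provided interval set).
#' @param tracks Named list of normalized `signal_track`s keyed by
#'   sample_id, or `NULL` to read `{sample}.norm.bedGraph` files from
#'   `tracks_dir`.
#' @param tracks_dir Directory holding `{sample_id}.norm.bedGraph` files
#'   (a [run_norm()] target directory).
#' @param method `"deseq2-like"` (default scaling rle) or `"edger-like"`
#'   (default scaling upperquartile); both run the same NB engine.
#' @param scaling Override the method's default scaling
#'   (`rle`/`tmm`/`upperquartile`/`none`).
#' @param min_counts Row-total low-count filter.
#' @param alpha,lfc Significance and fold-change cutoffs.
#' @param offsets See [nb_test()].
#' @param out_dir Output directory.
#' @return Invisibly, list with `table`, `gain`, `loss`, `factors`,
#'   `counts`.
#' @export
run_diff <- function(sheet, genome, target, contrast, regions, tracks = NULL,
                     tracks_dir = NULL, method = c("deseq2-like", "edger-like"),
                     scaling = NULL, min_counts = 0L, alpha = 0.05, lfc = 0,
                     offsets = c("effective", "none"), out_dir) {
  method <- match.arg(method)
  offsets <- match.arg(offsets)
  genome <- validate_genome(genome)
  if (is.null(target)) stop("target must be specified for differential analysis")
  if (is.null(scaling))
    scaling <- if (method == "deseq2-like") "rle" else "upperquartile"
  grp <- sheet[sheet$target == target & sheet$condition %in% contrast, ,
               drop = FALSE]
  if (nrow(grp) == 0L) stop("no samples with target '", target,
                            "' in the contrast conditions")
  if (is.character(regions)) regions <- read_regions(regions, genome)
  regions <- canonical_regions(regions, genome)
  if (is.null(tracks)) {
    if (is.null(tracks_dir)) stop("supply tracks or tracks_dir")
    tracks <- lapply(stats::setNames(grp$sample_id, grp$sample_id),
                     function(id)
                       read_bedgraph(file.path(tracks_dir,
                                               paste0(id, ".norm.bedGraph")),
                                     genome))
  } else tracks <- tracks[grp$sample_id]
  params <- list(target = target, contrast = contrast, method = method,
                 scaling = scaling, min_counts = min_counts, alpha = alpha,
                 lfc = lfc, offsets = offsets)
  hdr <- file_header("diff", params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- quantify_regions(tracks, regions)
  counts <- filter_low_counts(counts, min_counts)
  if (nrow(counts) == 0L) stop("no regions left after low-count filtering")
  factors <- if (scaling == "none") NULL else norm_factors(counts, scaling)
  res <- nb_test(counts, grp, contrast, factors = factors, offsets = offsets,
                 alpha = alpha, lfc = lfc)
  exp <- classify_and_export(res, alpha = alpha, lfc = lfc, out_dir = out_dir,
                             header = hdr)
  cm <- suppressWarnings(stats::cor(counts))
  diag(cm) <- 1
  write_tsv(cbind(data.frame(sample_id = rownames(cm)), as.data.frame(cm)),
            file.path(out_dir, "qc_count_correlation.tsv"), header = hdr)
  write_manifest(out_dir, "diff", params,
                 c("diff_results.tsv", "diff_gain.bed", "diff_loss.bed"))
  invisible(list(table = exp$table, gain = exp$gain, loss = exp$loss,
                 factors = factors, counts = counts))
}
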