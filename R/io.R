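#' Parse the tab-separated sample sheet
#'
#' The experimental design is a tab-separated table with a header row naming
#' at least `sample_id`, `bam`, `condition` and `target` (the antibody /
#' chromatin mark); an optional `bam_control` column points at matched input
#' or IgG alignments. Row order is preserved exactly: the first sample of a
#' target group is the normalization reference.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @param path Path to a sample sheet file.
#' @return A data frame of class `sample_sheet` with columns `sample_id`,
#'   `bam`, `condition`, `target`, `bam_control` (`NA` when absent).
#' @export
parse_sample_sheet <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- text[nzchar(trimws(text))]
  if (length(text) < 1L) stop("sample sheet is empty")
  cells <- strsplit(text, "\t", fixed = TRUE)
  header <- trimws(cells[[1L]])
  required <- c("sample_id", "bam", "condition", "target")
  missing <- setdiff(required, header)
  if (length(missing))
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  rows <- cells[-1L]
  get <- function(row, col) {
    i <- match(col, header)
    if (is.na(i) || i > length(row)) NA_character_ else {
      v <- trimws(row[[i]])
      if (nzchar(v)) v else NA_character_
    }
  }
  df <- data.frame(
    sample_id   = vapply(rows, get, "", col = "sample_id"),
    bam         = vapply(rows, get, "", col = "bam"),
    condition   = vapply(rows, get, "", col = "condition"),
    target      = vapply(rows, get, "", col = "target"),
    bam_control = vapply(rows, get, "", col = "bam_control"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$sample_id)) || any(is.na(df$condition)) || any(is.na(df$target)))
    stop("sample_id, condition and target must be non-empty for every row")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname parse_sample_sheet
#' @export
read_sample_sheet <- function(path) parse_sample_sheet(readLines(path))

#' Parse a chromosome-sizes file into a genome index
#'
#' Two tab-separated columns without a header: chromosome name and length in
#' base pairs. Chromosome order in the file defines the canonical ordering
#' of every interval output of the pipeline.
#'
#' @param text Character vector of lines (or one string with newlines).
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
parse_chrom_sizes <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  cells <- strsplit(text, "\t", fixed = TRUE)
  if (any(lengths(cells) < 2L))
    stop("chrom.sizes requires two tab-separated columns")
  nm <- vapply(cells, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 2L)))
  if (any(is.na(len)) || any(len != floor(len)))
    stop("chromosome lengths must be integers")
  if (any(len < 1)) stop("chromosome lengths must be >= 1")
  if (anyDuplicated(nm)) stop("duplicate chromosome names")
  stats::setNames(len, nm)
}

#' @rdname parse_chrom_sizes
#' @export
read_chrom_sizes <- function(path) parse_chrom_sizes(readLines(path))

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome index must be a named vector of chromosome lengths")
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names")
  if (length(genome) && (any(!is.finite(genome)) || any(genome < 1) ||
                         any(genome != floor(genome))))
    stop("chromosome lengths must be positive integers")
  genome
}

#' Canonicalize a region set
#'
#' Regions are plain data frames with 0-based half-open `chrom`, `start`,
#' `end` columns (extra columns are carried along untouched). Canonical form
#' is sorted by chromosome (genome-index order when a genome is supplied,
#' C-locale lexicographic otherwise) then start then end.
#'
#' @param regions Data frame with at least `chrom`, `start`, `end`.
#' @param genome Optional genome index; when given, regions must lie within
#'   chromosome bounds.
#' @export
canonical_regions <- function(regions, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  if (any(regions$start < 0) || any(regions$start >= regions$end))
    stop("regions need 0 <= start < end")
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    bad <- setdiff(unique(regions$chrom), names(genome))
    if (length(bad))
      stop("chromosomes not in genome index: ", paste(bad, collapse = ", "))
    if (any(regions$end > genome[regions$chrom]))
      stop("region end beyond chromosome length")
    lev <- names(genome)
  } else {
    lev <- sort(unique(regions$chrom), method = "radix")
  }
  o <- order(match(regions$chrom, lev), regions$start, regions$end)
  regions <- regions[o, , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Read a BED file of regions
#'
#' Accepts BED3 and wider; columns beyond the third are retained as opaque
#' annotation columns (`name`, `score`, `strand`, `extra1`, ...). Output is
#' canonical (see [canonical_regions()]).
#'
#' @param path BED file path.
#' @param genome Optional genome index for bounds checking and chromosome
#'   ordering.
#' @export
read_regions <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(canonical_regions(data.frame(chrom = character(), start = numeric(),
                                        end = numeric()), genome))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  n <- min(lengths(cells))
  if (n < 3L) stop("BED requires at least 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- as.data.frame(lapply(seq_len(n), function(i) vapply(cells, `[[`, "", i)),
                      col.names = c(cols, paste0("extra", seq_len(max(0, n - 6))))[seq_len(n)],
                      stringsAsFactors = FALSE)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(is.na(df$start) | is.na(df$end))) stop("malformed BED coordinates")
  canonical_regions(df, genome)
}

#' Write regions as BED
#'
#' @param regions Region data frame (`chrom`, `start`, `end`, optional extra
#'   columns written in order).
#' @param path Output path.
#' @param header Optional `#`-comment lines.
#' @export
write_regions <- function(regions, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(regions)) {
    cols <- lapply(names(regions), function(nm) {
      v <- regions[[nm]]
      if (nm %in% c("start", "end")) sprintf("%d", as.integer(v))
      else if (is.numeric(v)) format_signal(v)
      else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read ENCODE narrowPeak / broadPeak files
#'
#' broadPeak is BED6+3 (9 columns), narrowPeak BED6+4 (10 columns, the last
#' being the summit offset). Column 9 carries -log10(q-value); the sentinel
#' `-1` means the q-value was not computed, in which case `neg_log10_q` is
#' `NA` and the peak is excluded from any q-filtered set (a message reports
#' how many).
#'
#' @param path Peak file path.
#' @param genome Optional genome index.
#' @return Canonical data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `neg_log10_q` (and `summit` for narrowPeak).
#' @export
read_peaks <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(canonical_regions(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), score = numeric(),
                 neg_log10_q = numeric()), genome))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nc <- unique(lengths(cells))
  if (length(nc) != 1L || !nc %in% c(9L, 10L))
    stop("expected 9-column broadPeak or 10-column narrowPeak rows")
  col <- function(i) vapply(cells, `[[`, "", i)
  df <- data.frame(chrom = col(1), start = as.numeric(col(2)),
                   end = as.numeric(col(3)), name = col(4),
                   score = as.numeric(col(5)),
                   neg_log10_q = as.numeric(col(9)),
                   stringsAsFactors = FALSE)
  if (nc == 10L) df$summit <- as.numeric(col(10))
  unknown <- df$neg_log10_q < 0
  if (any(unknown)) {
    message(sum(unknown), " peak(s) without a computed q-value (column 9 == -1);",
            " excluded from q-filtered sets")
    df$neg_log10_q[unknown] <- NA_real_
  }
  canonical_regions(df, genome)
}
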