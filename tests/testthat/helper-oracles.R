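# Naive per-base / brute-force reference implementations used as oracles.
# They work on dense numeric vectors and plain loops, independent of the
# run-length machinery in the package.

# Expand a track to one dense numeric vector per chromosome.
track_vec <- function(track, chrom) {
  g <- track_genome(track)
  v <- numeric(g[[chrom]])
  r <- track_runs(track)
  r <- r[r$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) v[(r$start[i] + 1):r$end[i]] <- r$value[i]
  v
}

# Dense vector -> canonical run data frame (for building expectations).
vec_to_runs <- function(v, chrom) {
  if (!length(v)) return(data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), value = numeric()))
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values != 0
  data.frame(chrom = rep(chrom, sum(keep)), start = s[keep], end = e[keep],
             value = r$values[keep], row.names = NULL)
}

track_from_vec <- function(v, chrom, genome) {
  signal_track(vec_to_runs(v, chrom), genome)
}

# Random canonical track on one chromosome: a few random-value intervals
# summed per base (so overlaps become legitimate pile-ups).
rand_vec <- function(len, n_intervals = 8, max_value = 5, integer_values = TRUE) {
  v <- numeric(len)
  if (n_intervals > 0) for (i in seq_len(n_intervals)) {
    s <- sample.int(len, 1L)
    w <- sample.int(max(2L, len %/% 4L), 1L)
    e <- min(len, s + w - 1L)
    val <- if (integer_values) sample.int(max_value, 1L) else stats::runif(1, 0.1, max_value)
    v[s:e] <- v[s:e] + val
  }
  v
}

# Plateau-level local maxima on a dense vector (zero-padded flanks).
oracle_local_maxima <- function(v, chrom) {
  r <- rle(c(0, v, 0))
  vals <- r$values
  n <- length(vals)
  if (n < 3) return(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), value = numeric()))
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- logical(n)
  for (i in 2:(n - 1))
    keep[i] <- vals[i] > vals[i - 1] && vals[i] > vals[i + 1] && vals[i] > 0
  data.frame(chrom = rep(chrom, sum(keep)), start = s[keep] - 1,
             end = e[keep] - 1, value = vals[keep], row.names = NULL)
}

# O(n^2) transitive merge of regions on one chromosome.
oracle_merge_chrom <- function(df, d) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  merged <- list(c(df$start[1], df$end[1]))
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    placed <- FALSE
    for (j in seq_along(merged)) {
      gap <- max(df$start[i], merged[[j]][1]) - min(df$end[i], merged[[j]][2])
      if (gap <= d) {
        merged[[j]] <- c(min(merged[[j]][1], df$start[i]),
                         max(merged[[j]][2], df$end[i]))
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1]] <- c(df$start[i], df$end[i])
  }
  # repeat until stable (transitive closure)
  repeat {
    changed <- FALSE
    for (j in seq_along(merged)) for (k in seq_along(merged)) {
      if (j >= k || is.null(merged[[j]]) || is.null(merged[[k]])) next
      gap <- max(merged[[j]][1], merged[[k]][1]) - min(merged[[j]][2], merged[[k]][2])
      if (gap <= d) {
        merged[[j]] <- c(min(merged[[j]][1], merged[[k]][1]),
                         max(merged[[j]][2], merged[[k]][2]))
        merged[[k]] <- NULL
        changed <- TRUE
      }
    }
    merged <- Filter(Negate(is.null), merged)
    if (!changed) break
  }
  out <- do.call(rbind, merged)
  out <- out[order(out[, 1]), , drop = FALSE]
  data.frame(chrom = df$chrom[1], start = out[, 1], end = out[, 2],
             row.names = NULL)
}

# Small two-condition sample sheet (s1..s(nA) condition A, rest condition B).
toy_sheet <- function(nA = 4, nB = 4, target = "H3K27me3") {
  parse_sample_sheet(c(
    "sample_id\tbam\tcondition\ttarget",
    sprintf("s%d\t/dev/null\t%s\t%s", seq_len(nA + nB),
            rep(c("A", "B"), c(nA, nB)), target)))
}

# Simulated NB count matrix; optional balanced 4-fold effects in condition B.
sim_counts <- function(n, nA = 4, nB = 4, mu = 200, phi = 0.05,
                       diff_fraction = 0, fold = 4) {
  idx <- if (diff_fraction > 0) sort(sample(n, round(n * diff_fraction))) else integer()
  gains <- idx[seq_along(idx) %% 2 == 1]
  losses <- setdiff(idx, gains)
  mu_m <- matrix(mu, n, nA + nB)
  if (length(gains)) mu_m[gains, (nA + 1):(nA + nB)] <- mu * fold
  if (length(losses)) mu_m[losses, (nA + 1):(nA + nB)] <- mu / fold
  m <- matrix(stats::rnbinom(n * (nA + nB), size = 1 / phi, mu = mu_m),
              n, nA + nB,
              dimnames = list(sprintf("chr1:%d-%d", seq_len(n) * 1000L,
                                      seq_len(n) * 1000L + 500L),
                              sprintf("s%d", seq_len(nA + nB))))
  list(m = m, diff = idx, gains = gains, losses = losses)
}

# Write SAM lines for a set of SE reads and convert to indexed BAM.
se_sam_lines <- function(genome, reads) {
  # reads: data.frame(chrom, pos (1-based), len, mapq, flag)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome)))
  if (nrow(reads) == 0) return(header)
  o <- order(match(reads$chrom, names(genome)), reads$pos)
  reads <- reads[o, , drop = FALSE]
  body <- sprintf("r%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(reads)), reads$flag, reads$chrom, reads$pos,
                  reads$mapq, reads$len,
                  vapply(reads$len, function(l) strrep("A", l), ""),
                  vapply(reads$len, function(l) strrep("I", l), ""))
  c(header, body)
}

make_bam <- function(sam_lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  prefix <- tempfile("aln", tmpdir = dir)
  sam_to_bam(sam_lines, prefix)
}
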