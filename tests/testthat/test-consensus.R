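test_that("pooling sums member tracks per base", {
  g <- c(chrA = 100)
  t1 <- signal_track(data.frame(chrom = "chrA", start = 0, end = 10, value = 1), g)
  t2 <- signal_track(data.frame(chrom = "chrA", start = 5, end = 15, value = 2), g)
  expect_equal(track_runs(pool_condition_signal(list(t1))), track_runs(t1))
  expect_equal(track_runs(pool_condition_signal(list(t1, t2))),
               data.frame(chrom = "chrA", start = c(0, 5, 10),
                          end = c(5, 10, 15), value = c(1, 3, 2)))
  expect_equal(track_runs(pool_condition_signal(list(t1, t1, t1)))$value, 3)
  set.seed(3)
  for (rep in 1:15) {
    len <- sample(50:200, 1)
    gg <- c(chrR = len)
    vs <- replicate(sample(2:4, 1), rand_vec(len, sample(0:6, 1)),
                    simplify = FALSE)
    got <- pool_condition_signal(lapply(vs, track_from_vec, chrom = "chrR",
                                        genome = gg))
    expect_equal(track_vec(got, "chrR"), Reduce(`+`, vs))
  }
})

test_that("the builtin Poisson caller finds enrichment blocks and nothing under the null", {
  set.seed(101)
  len <- 50000L
  g <- c(chrS = len)
  # uniform Poisson background, ~3x coverage
  bg <- rpois(len, 3)
  t_null <- track_from_vec(bg, "chrS", g)
  pk_null <- call_peaks_builtin(t_null, genome = g, mode = "narrow", q_max = 0.1)
  expect_equal(nrow(pk_null), 0L)

  # one 10x block of 1 kb over the same background
  v <- bg
  block <- 20001:21000
  v[block] <- rpois(1000, 30)
  pk <- call_peaks_builtin(track_from_vec(v, "chrS", g), genome = g,
                           mode = "narrow", window = 200, q_max = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$start - 20000), 200)
  expect_lte(abs(pk$end - 21000), 200)
  expect_gt(pk$neg_log10_q, 1)

  # empty track -> no peaks; oversized window -> error
  expect_equal(nrow(call_peaks_builtin(signal_track(NULL, g), genome = g)), 0L)
  expect_error(call_peaks_builtin(t_null, genome = c(chrS = 100), window = 500),
               "larger than every chromosome")
})

test_that("control signal raises the local background of the builtin caller", {
  set.seed(113)
  len <- 20000L
  g <- c(chrS = len)
  v <- rpois(len, 2)
  v[5001:6000] <- rpois(1000, 20)
  ctrl <- rpois(len, 2)
  ctrl[5001:6000] <- rpois(1000, 40)  # artifact region, hot in the control
  with_ctrl <- call_peaks_builtin(track_from_vec(v, "chrS", g),
                                  control = track_from_vec(ctrl, "chrS", g),
                                  genome = g, mode = "narrow")
  without <- call_peaks_builtin(track_from_vec(v, "chrS", g), genome = g,
                                mode = "narrow")
  expect_gt(nrow(without), 0L)
  expect_equal(nrow(with_ctrl), 0L)
})

test_that("q filtering matches brute force and handles edge thresholds", {
  pk <- data.frame(chrom = "chrA", start = c(0, 10, 20), end = c(5, 15, 25),
                   neg_log10_q = -log10(c(0.2, 0.04, 0.001)))
  expect_equal(nrow(filter_peaks_by_q(pk, 0.05)), 2L)
  expect_equal(nrow(filter_peaks_by_q(pk, 1.0)), 3L)
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(0:30, 1)
    p <- data.frame(chrom = "chrA", start = seq_len(n) * 10,
                    end = seq_len(n) * 10 + 5,
                    neg_log10_q = ifelse(runif(n) < 0.1, NA,
                                         runif(n, 0, 6)))
    q <- runif(1, 1e-4, 1)
    got <- filter_peaks_by_q(p, q)
    want <- p[!is.na(p$neg_log10_q) & 10^(-p$neg_log10_q) <= q, ]
    expect_equal(nrow(got), nrow(want))
  }
})

test_that("region merging follows gap<=d semantics and matches brute force", {
  expect_equal(merge_regions(data.frame(chrom = "chrA", start = c(0, 15),
                                        end = c(10, 20)), 5)$end, 20)
  expect_equal(nrow(merge_regions(data.frame(chrom = "chrA", start = c(0, 10),
                                             end = c(10, 20)), 0)), 1L)
  got <- merge_regions(data.frame(chrom = "chrA", start = c(0, 16),
                                  end = c(10, 20)), 5)
  expect_equal(nrow(got), 2L)  # gap 6 > d 5 stays apart

  set.seed(17)
  for (rep in 1:40) {
    n <- sample(1:50, 1)
    s <- sample.int(2000, n)
    df <- data.frame(chrom = "chrA", start = s, end = s + sample.int(100, n, TRUE))
    d <- sample(0:60, 1)
    got <- merge_regions(df, d)
    expect_equal(got, oracle_merge_chrom(df, d))
    # idempotence and pairwise separation > d
    expect_equal(merge_regions(got, d), got)
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] - got$end[-nrow(got)] > d))
  }
})

test_that("the consensus grid enumerates q x d cells with per-cell merges", {
  pkA <- data.frame(chrom = "chrA", start = c(0, 300, 1000),
                    end = c(100, 400, 1200),
                    neg_log10_q = c(5, 2, 1.2))
  pkB <- data.frame(chrom = "chrA", start = c(50, 2000), end = c(150, 2100),
                    neg_log10_q = c(3, 0.9))
  grid <- build_consensus_grid(list(A = pkA, B = pkB))
  expect_s3_class(grid, "consensus_grid")
  expect_length(grid$cells, 25L)

  empty <- build_consensus_grid(list(A = pkA[0, ], B = pkB[0, ]))
  expect_length(empty$cells, 25L)
  expect_true(all(vapply(empty$cells, function(c) nrow(c$regions) == 0L, TRUE)))

  one <- build_consensus_grid(list(A = pkA), q_list = 1.0, d_list = 0L)
  expect_length(one$cells, 1L)
  expect_equal(one$cells[[1]]$regions, merge_regions(pkA, 0))

  expect_error(build_consensus_grid(list(), q_list = 0.1, d_list = 0),
               "at least one")
  expect_error(build_consensus_grid(list(A = pkA), q_list = numeric()),
               "non-empty")
})

test_that("grid summaries report counts and width stats", {
  pk <- data.frame(chrom = "chrA", start = 0, end = 100, neg_log10_q = 5)
  grid <- build_consensus_grid(list(A = pk), q_list = c(0.05, 1e-9),
                               d_list = 0L)
  s <- grid_summary(grid)
  expect_equal(s$n_regions, c(1L, 0L))
  expect_equal(s$width_median[1], 100)
  expect_true(is.na(s$width_median[2]))
  expect_equal(s$total_bp, c(100, 0))

  set.seed(29)
  n <- 12
  s2 <- sample.int(5000, n)
  pk2 <- data.frame(chrom = "chrA", start = s2, end = s2 + sample.int(300, n),
                    neg_log10_q = runif(n, 0, 8))
  g2 <- build_consensus_grid(list(A = pk2), q_list = 0.5, d_list = 10L)
  st <- grid_summary(g2)
  w <- g2$cells[[1]]$regions$end - g2$cells[[1]]$regions$start
  expect_equal(st$width_mean, mean(w))
  expect_equal(st$width_max, max(w))
})

test_that("covered bp is monotone in q and region count monotone in d", {
  set.seed(37)
  mk_peaks <- function(n) {
    s <- sort(sample.int(100000, n))
    data.frame(chrom = "chrA", start = s, end = s + sample.int(500, n, TRUE),
               neg_log10_q = rexp(n, 0.5))
  }
  grid <- build_consensus_grid(list(A = mk_peaks(80), B = mk_peaks(60)))
  s <- grid_summary(grid)
  for (d in grid$merge_distances) {
    sub <- s[s$d == d, ]
    sub <- sub[order(-sub$q), ]  # loose -> strict
    expect_true(all(diff(sub$total_bp) <= 0))
  }
  for (q in grid$q_thresholds) {
    sub <- s[s$q == q, ]
    sub <- sub[order(sub$d), ]
    expect_true(all(diff(sub$n_regions) <= 0))
    expect_true(all(diff(sub$total_bp) >= 0))
  }
})
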