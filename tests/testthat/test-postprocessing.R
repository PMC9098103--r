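test_that("autocorrection centres the modal level at zero", {
  tab <- segment_table(seg_df("S1", "chr1",
                              start = c(1, 1001, 2001, 3001),
                              end = c(1000, 2000, 3000, 4000),
                              num_mark = c(1000, 1000, 1000, 100),
                              seg_mean = c(0.30, 0.31, 0.29, -0.70)))
  out <- autocorrect_baseline(tab)
  off <- attr(out, "offsets")[["S1"]]
  expect_lt(abs(off - 0.30), 0.02)
  expect_equal(out$seg_mean, c(0.30, 0.31, 0.29, -0.70) - off)
  # independent numeric check of the mark-weighted KDE mode
  w <- c(1000, 1000, 1000, 100); w <- w / sum(w)
  x <- c(0.30, 0.31, 0.29, -0.70)
  obj <- function(g) sum(w * dnorm(g, x, 0.05))
  grid <- seq(-1, 1, by = 1e-4)
  expect_lt(abs(grid[which.max(vapply(grid, obj, numeric(1)))] - 0.30), 0.02)
})

test_that("an already-centred table is unchanged within grid tolerance", {
  tab <- segment_table(seg_df("S1", "chr1",
                              start = c(1, 501, 1001), end = c(500, 1000, 1500),
                              num_mark = c(800, 900, 50),
                              seg_mean = c(0.005, -0.005, 0.8)))
  out <- autocorrect_baseline(tab)
  expect_lt(max(abs(out$seg_mean - tab$seg_mean)), 5e-3)
})

test_that("autocorrection is idempotent and shift-equivariant", {
  set.seed(23)
  for (i in 1:8) {
    tab <- random_segment_table(n_samples = 2, n_chroms = 2, max_segs = 4)
    once <- autocorrect_baseline(tab)
    twice <- autocorrect_baseline(once)
    expect_equal(twice$seg_mean, once$seg_mean, tolerance = 1e-3)

    c_shift <- runif(1, -0.5, 0.5)
    shifted <- as.data.frame(tab)
    shifted$seg_mean <- shifted$seg_mean + c_shift
    out_shifted <- autocorrect_baseline(segment_table(shifted))
    expect_equal(out_shifted$seg_mean, once$seg_mean, tolerance = 1e-9)
  }
})

test_that("a single-segment sample is centred to zero with a warning", {
  tab <- segment_table(seg_df("S1", "chr1", 1, 1000, 10, 0.45))
  expect_warning(out <- autocorrect_baseline(tab), "single segment")
  expect_equal(out$seg_mean, 0)
})

test_that("threshold state calling honours the inclusive cut boundaries", {
  tab <- segment_table(seg_df("S1", "chr1",
                              start = c(1, 1001, 2001, 3001),
                              end = c(1000, 2000, 3000, 4000),
                              num_mark = 10,
                              seg_mean = c(-0.2, -0.21, 0.19, 0.2)))
  out <- call_states(tab, state_call_params("threshold"))
  expect_equal(out$state, c("loss", "loss", "neutral", "gain"))
})

test_that("formula state calling rounds 2^seg_mean * 2 half-up", {
  tab <- segment_table(seg_df("S1", "chr1",
                              start = c(1, 1001, 2001, 3001),
                              end = c(1000, 2000, 3000, 4000),
                              num_mark = 10,
                              seg_mean = c(-1, 0, 1, log2(1.25))))  # 2^x*2 = 1,2,4,2.5
  out <- call_states(tab, state_call_params("formula"))
  expect_equal(out$state, c("1", "2", "4", "3"))  # 2.5 rounds half-up to 3
})

test_that("neutrality is consistent across threshold and formula modes", {
  tab <- segment_table(seg_df("S1", "chr1", 1, 1000, 10, 0))
  expect_equal(call_states(tab, state_call_params("threshold"))$state, "neutral")
  expect_equal(call_states(tab, state_call_params("formula"))$state, "2")
})

test_that("invalid state-call parameters are rejected", {
  expect_error(state_call_params(loss_cut = 0.3, gain_cut = 0.2), "loss_cut")
})

make_calls <- function(n_samples, chrom, start, end, state,
                       backbone_end = 100000) {
  lapply(seq_len(n_samples), function(i) {
    s <- sprintf("S%02d", i)
    rows <- seg_df(s, chrom, 1, backbone_end, 50, 0, "neutral")
    if (!is.na(start[i])) {
      rows <- rbind(
        seg_df(s, chrom, 1, start[i] - 1, 20, 0, "neutral"),
        seg_df(s, chrom, start[i], end[i], 20, -1, state),
        seg_df(s, chrom, end[i] + 1, backbone_end, 20, 0, "neutral"))
    }
    segment_table(rows)
  })
}

test_that("identical calls in all samples give one full-support region", {
  calls <- make_calls(10, "chr3", rep(5001, 10), rep(6000, 10), "loss")
  res <- consensus_regions(calls, density = 0.1, rho = 0.5)
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 5001)
  expect_equal(res$end, 6000)
  expect_equal(res$support_frac, 1.0)
  expect_true(res$recurrent)
})

test_that("the density threshold controls region retention", {
  starts <- c(5001, rep(NA, 9))
  calls <- make_calls(10, "chr3", starts, c(6000, rep(NA, 9)), "loss")
  keep <- consensus_regions(calls, density = 0.1, rho = 0.5, est_recur = FALSE)
  expect_equal(nrow(keep), 1)
  expect_equal(keep$support_frac, 0.1)
  none <- consensus_regions(calls, density = 0.2, rho = 0.5, est_recur = FALSE)
  expect_equal(nrow(none), 0)
})

test_that("calls below the reciprocal-overlap threshold stay in separate clusters", {
  # intervals 1-1000 and 601-1600: overlap 400 = 40% of each
  t1 <- segment_table(rbind(seg_df("S1", "chr1", 1, 1000, 10, -1, "loss"),
                            seg_df("S1", "chr1", 1001, 5000, 10, 0, "neutral")))
  t2 <- segment_table(rbind(seg_df("S2", "chr1", 1, 600, 10, 0, "neutral"),
                            seg_df("S2", "chr1", 601, 1600, 10, -1, "loss"),
                            seg_df("S2", "chr1", 1601, 5000, 10, 0, "neutral")))
  res <- consensus_regions(list(t1, t2), density = 0.4, rho = 0.5,
                           est_recur = FALSE)
  expect_equal(nrow(res), 2)  # two clusters, one region each
  expect_equal(sort(res$start), c(1, 601))
  merged <- consensus_regions(list(t1, t2), density = 0.4, rho = 0.3,
                              est_recur = FALSE)
  expect_equal(nrow(merged), 1)  # lower rho links them
})

test_that("gains never support loss regions", {
  t1 <- segment_table(rbind(seg_df("S1", "chr1", 1, 1000, 10, -1, "loss"),
                            seg_df("S1", "chr1", 1001, 5000, 10, 0, "neutral")))
  t2 <- segment_table(rbind(seg_df("S2", "chr1", 1, 1000, 10, 1, "gain"),
                            seg_df("S2", "chr1", 1001, 5000, 10, 0, "neutral")))
  res <- consensus_regions(list(t1, t2), density = 0.5, rho = 0.5,
                           est_recur = FALSE)
  # each state pool has support 1/2 < would-be merged support
  expect_true(all(res$n_support == 1))
  expect_setequal(res$state, c("loss", "gain"))
})

test_that("raising density or rho never enlarges consensus output", {
  set.seed(41)
  tables <- lapply(1:6, function(i) {
    s <- sprintf("S%02d", i)
    a <- sample(2000, 1); b <- a + sample(500:3000, 1)
    segment_table(rbind(
      seg_df(s, "chr1", 1, max(1, a - 1), 10, 0, "neutral"),
      seg_df(s, "chr1", a, b, 10, -1, "loss"),
      seg_df(s, "chr1", b + 1, 20000, 10, 0, "neutral")))
  })
  total_span <- function(res) if (nrow(res) == 0) 0 else sum(res$end - res$start + 1)
  spans <- vapply(c(0.1, 0.3, 0.5, 0.8),
                  function(d) total_span(consensus_regions(tables, density = d,
                                                           rho = 0.5,
                                                           est_recur = FALSE)),
                  numeric(1))
  expect_true(all(diff(spans) <= 0))
  n_regions <- vapply(c(0.2, 0.5, 0.9),
                      function(r) nrow(consensus_regions(tables, density = 0.1,
                                                         rho = r,
                                                         est_recur = FALSE)),
                      numeric(1))
  expect_true(all(diff(n_regions) >= 0))  # higher rho never merges clusters

  expect_error(consensus_regions(tables, density = 0), "density")
  expect_error(consensus_regions(tables, rho = 1.5), "rho")
})
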