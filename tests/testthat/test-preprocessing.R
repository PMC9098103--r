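make_bg_cohort <- function(b, n = 40, seed = 5) {
  # in-band signal well above background b; oob pool centred on b
  man <- tiny_manifest(n = n, n_typeI = 12)
  set.seed(seed)
  meth <- matrix(runif(n * 2, 2000, 6000) + b, n, 2)
  unmeth <- matrix(runif(n * 2, 2000, 6000) + b, n, 2)
  oob <- matrix(b, n, 2)
  intensity_cohort(man, meth, unmeth, oob, sample_names = c("A", "B"))
}

test_that("background correction subtracts the out-of-band level", {
  co0 <- make_bg_cohort(0)
  w <- capture_warnings(out0 <- background_correct(co0))
  expect_match(w, "passed through", all = TRUE)
  expect_equal(out0$meth, co0$meth)

  b <- 300
  co <- make_bg_cohort(b)
  out <- background_correct(co)
  expect_equal(out$meth, co$meth - b)
  expect_equal(out$unmeth, co$unmeth - b)
  # monotone: order within a channel/sample is preserved
  expect_equal(order(out$meth[, 1]), order(co$meth[, 1]))
  # floored at zero
  low <- co; low$meth[1, 1] <- 10
  out_low <- background_correct(low)
  expect_equal(unname(out_low$meth[1, 1]), 0)
})

test_that("dye-bias correction maps a doubled red channel back onto green", {
  n <- 150
  man <- tiny_manifest(n = n, n_typeI = 0)
  set.seed(7)
  grn <- matrix(sort(runif(n, 500, 5000)), n, 1)
  co <- intensity_cohort(man, grn, 2 * grn, sample_names = "A")
  out <- dye_bias_correct(co)
  expect_equal(out$unmeth, co$meth, tolerance = 1e-12)
  expect_equal(out$meth, co$meth)  # green untouched

  # distributionally identical channels -> identity map
  co2 <- intensity_cohort(man, grn, grn, sample_names = "A")
  expect_equal(dye_bias_correct(co2)$unmeth, grn, ignore_attr = TRUE)

  # monotone map: rank order within the red channel never changes
  set.seed(8)
  grn3 <- matrix(runif(n, 500, 5000), n, 1)
  red3 <- matrix(runif(n, 400, 8000), n, 1)
  out3 <- dye_bias_correct(intensity_cohort(man, grn3, red3, sample_names = "A"))
  expect_true(all(diff(out3$unmeth[order(red3), 1]) >= 0))
})

test_that("dye-bias correction falls back to median-ratio scaling on few type II probes", {
  man <- tiny_manifest(n = 30, n_typeI = 0)
  set.seed(3)
  grn <- matrix(runif(30, 500, 5000), 30, 1)
  co <- intensity_cohort(man, grn, 2 * grn, sample_names = "A")
  expect_warning(out <- dye_bias_correct(co), "median-ratio")
  expect_equal(out$unmeth, grn, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("detection p-values mask background-level probes", {
  n <- 400
  man <- tiny_manifest(n = n, n_typeI = 100)
  set.seed(13)
  oob <- matrix(rlnorm(n * 2, log(100), 0.5), n, 2)
  meth <- matrix(rlnorm(n * 2, log(4000), 0.3), n, 2)
  unmeth <- matrix(rlnorm(n * 2, log(4000), 0.3), n, 2)
  # replace 5% of probes by pure background draws
  drop <- sample(n, n * 0.05)
  meth[drop, ] <- rlnorm(length(drop) * 2, log(100), 0.5) / 2
  unmeth[drop, ] <- rlnorm(length(drop) * 2, log(100), 0.5) / 2
  co <- intensity_cohort(man, meth, unmeth, oob, sample_names = c("A", "B"))
  out <- mask_probes(co, 0.05)
  frac <- mean(out$mask)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  # signal probes survive
  expect_false(any(out$mask[setdiff(seq_len(n), drop), ]))

  # a probe above every oob value has p = 0; below every value, p = 1
  hi <- which.max(meth[, 1] + unmeth[, 1])
  expect_false(out$mask[hi, 1])
  co$meth[drop[1], 1] <- 0; co$unmeth[drop[1], 1] <- 0
  out2 <- mask_probes(co, 0.99)
  expect_true(out2$mask[drop[1], 1])

  expect_error(mask_probes(co, 1.5), "p_threshold")
})

test_that("masking is monotone through the stage sequence", {
  cfg <- sim_config(n_tumor = 2, n_control = 2, probes_per_chrom = 60, seed = 19)
  sim <- simulate_cohort(cfg, "kirc_3p")
  co <- sim$cohort
  co$mask[1:5, 1] <- TRUE
  s1 <- background_correct(co)
  s2 <- dye_bias_correct(s1)
  s3 <- mask_probes(s2, 0.05)
  expect_true(all(s3$mask[co$mask]))
  tr <- compute_lrr(s3, build_reference(s3, sim$sheet, "median_controls"))
  expect_true(all(tr$mask[s3$mask]))
})

test_that("reference construction follows the requested mode", {
  man <- tiny_manifest(n = 3, n_typeI = 0)
  mk <- function(tot) intensity_cohort(man, tot / 2, tot / 2,
                                       sample_names = colnames(tot))
  sheet1 <- validate_sample_sheet(data.frame(
    sample_name = c("T1", "C1"), intensity_path = ".", group = c("tumor", "control")))
  tot1 <- cbind(T1 = c(5, 6, 7), C1 = c(10, 20, 40))
  expect_equal(as.vector(build_reference(mk(tot1), sheet1, "median_controls")),
               c(10, 20, 40))

  sheet3 <- validate_sample_sheet(data.frame(
    sample_name = c("T1", "C1", "C2", "C3"), intensity_path = ".",
    group = c("tumor", rep("control", 3))))
  tot3 <- cbind(T1 = c(1, 1, 1), C1 = c(10, 10, 10), C2 = c(20, 20, 20),
                C3 = c(40, 40, 40))
  expect_equal(as.vector(build_reference(mk(tot3), sheet3, "median_controls")),
               c(20, 20, 20))
  expect_equal(as.vector(build_reference(mk(tot3), sheet3, "pooled_controls")),
               rep(mean(c(10, 20, 40)), 3))

  tumors_only <- validate_sample_sheet(data.frame(
    sample_name = paste0("T", 1:3), intensity_path = ".", group = "tumor"))
  tott <- cbind(T1 = c(2, 8, 2), T2 = c(4, 2, 4), T3 = c(6, 4, 8))
  expect_equal(as.vector(build_reference(mk(tott), tumors_only, "cohort_median")),
               apply(tott, 1, median))
  expect_error(build_reference(mk(tott), tumors_only, "median_controls"),
               "control")
})

test_that("LRR is log2 of total over reference", {
  man <- tiny_manifest(n = 5, n_typeI = 0)
  i_r <- c(100, 100, 100, 100, 100)
  tot <- cbind(S = c(100, 200, 50, 400, 25))
  co <- intensity_cohort(man, tot * 0.4, tot * 0.6, sample_names = "S")
  tr <- compute_lrr(co, i_r)
  expect_equal(unname(tr$values[, "S"]), c(0, 1, -1, 2, -2))
})

test_that("zero totals and zero references are masked, not propagated", {
  man <- tiny_manifest(n = 3, n_typeI = 0)
  co <- intensity_cohort(man, cbind(S = c(0, 50, 50)), cbind(S = c(0, 50, 50)),
                         sample_names = "S")
  tr <- compute_lrr(co, c(100, 0, 100))
  expect_true(tr$mask[1, 1])  # I_T = 0
  expect_true(tr$mask[2, 1])  # I_R = 0
  expect_false(tr$mask[3, 1])
  expect_true(all(is.finite(tr$values[!tr$mask])))
})

test_that("z-transform standardizes per sample and is affine invariant", {
  man <- tiny_manifest(n = 3, n_typeI = 0)
  tr <- make_track(man, list(S = c(-1, 0, 1)))
  z <- zscore_transform(tr)
  expect_equal(unname(z$values[, "S"]), c(-1, 0, 1))  # sample (n-1) SD

  set.seed(10)
  man2 <- tiny_manifest(n = 50, n_typeI = 0)
  x <- rnorm(50)
  z1 <- zscore_transform(make_track(man2, list(S = x)))
  z2 <- zscore_transform(make_track(man2, list(S = 3.7 * x + 2)))
  expect_equal(z1$values, z2$values)
  expect_equal(mean(z1$values[, "S"]), 0)
  expect_equal(sd(z1$values[, "S"]), 1)

  expect_error(zscore_transform(make_track(man, list(S = c(2, 2, 2)))),
               "zero within-sample SD")
})

test_that("LRR after dye correction is invariant to a global red-channel factor", {
  cfg <- sim_config(n_tumor = 2, n_control = 2, probes_per_chrom = 80,
                    noise_sd = 0.2, seed = 17)
  base <- simulate_cohort(cfg, "kirc_3p")
  ref_vals <- NULL
  set.seed(33)
  for (f in c(1, runif(4, 0.5, 2))) {
    cfg_f <- sim_config(n_tumor = 2, n_control = 2, probes_per_chrom = 80,
                        noise_sd = 0.2, dye_bias = f, seed = 17)
    sim <- simulate_cohort(cfg_f, "kirc_3p")
    co <- dye_bias_correct(sim$cohort)
    tr <- compute_lrr(co, build_reference(co, sim$sheet, "median_controls"))
    if (is.null(ref_vals)) ref_vals <- tr$values else {
      expect_equal(tr$values, ref_vals, tolerance = 1e-8)
    }
  }
})

test_that("noise-free pipeline LRR recovers log2(CN/2) exactly", {
  cfg <- sim_config(n_tumor = 2, n_control = 3, probes_per_chrom = 40,
                    noise_sd = 0, dye_bias = 1, seed = 2)
  sim <- simulate_cohort(cfg, "oligo_1p19q")
  tr <- compute_lrr(sim$cohort, build_reference(sim$cohort, sim$sheet,
                                                "median_controls"))
  deleted <- tr$manifest$arm %in% c("1p", "19q")
  expect_equal(unname(tr$values[deleted, "T01"]), rep(-1, sum(deleted)))
  expect_equal(unname(tr$values[!deleted, "T01"]), rep(0, sum(!deleted)))
  expect_equal(max(abs(tr$values[, "C01"])), 0)
})
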