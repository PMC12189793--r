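test_that("PLA reproduces a noise-free piecewise-linear signal exactly", {
  y <- c(1:10, seq(30, 3, by = -3))  # slopes +1 then -3, break after sample 10
  cpts <- cpts_at(10L, length(y))
  pla <- fit_pla(y, cpts)
  expect_equal(pla$fitted, y, tolerance = 1e-10)
  expect_equal(pla$rss, 0, tolerance = 1e-10)
})

test_that("single-segment PLA is the OLS line", {
  pla <- fit_pla(c(0, 1, 0), cpts_at(integer(), 3L))
  expect_equal(pla$fitted, rep(1 / 3, 3), tolerance = 1e-12)
  # least-squares optimality: any other line does worse
  x <- 1:3
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    expect_gte(sum((c(0, 1, 0) - (a + b * x))^2) + 1e-12, pla$rss)
  }
})

test_that("PLA total RSS equals the unpenalized segmentation objective", {
  set.seed(909)
  y <- rep(c(0, 5, 2), each = 20) + rnorm(60)
  cfg <- default_penalty(y)
  cpts <- pelt_segment(y, cfg)
  pla <- fit_pla(y, cpts)
  expect_equal(pla$rss + cfg$beta * cpts$interior_count, cpts$total_cost,
               tolerance = 1e-8)
})

test_that("z-normalization is exact over the reference TOI and a plain affine map elsewhere", {
  rec <- block_record()
  seg <- optimal_tois(cpts_at(c(4L, 12L, 22L), 30L), rec)
  pla <- fit_pla(rec$values, pelt_segment(rec$values, penalty_config(5, 3)))
  norm <- znormalize(rec, pla, seg, ref = 1L)
  ref_idx <- otoi_indices(seg, 1L)
  expect_equal(mean(norm$z[ref_idx]), 0, tolerance = 1e-10)
  expect_equal(sd(norm$z[ref_idx]), 1, tolerance = 1e-10)
  expect_equal(mean(norm$z_pla[ref_idx]), 0, tolerance = 1e-10)
  expect_equal(sd(norm$z_pla[ref_idx]), 1, tolerance = 1e-10)
  # direct substitution: y = ref_mean + 2 * ref_sd maps to z = 2
  y2 <- norm$ref_mean + 2 * norm$ref_sd
  expect_equal((y2 - norm$ref_mean) / norm$ref_sd, 2)
  # normalization is applied to all ni samples, transitions included
  expect_equal(length(norm$z), 30L)
})

test_that("a constant reference segment is rejected", {
  rec <- block_record(values = c(rep(1, 10), rnorm(20) + 5))
  seg <- suppressWarnings(optimal_tois(cpts_at(c(12L, 22L), 30L), rec))
  expect_error(znormalize(rec, NULL, seg), "degenerate reference")
})

test_that("aligned TOI differences obey the shared-reference identity", {
  set.seed(111)
  design <- small_design()
  for (i in 1:15) {
    rec <- simulate_subject(design, "control", "male", i, subject_seed = 70 + i)
    an <- analyze_record(rec)
    d <- toi_difference(an$norm, an$seg, 2L, 1L)
    ik <- otoi_indices(an$seg, 2L)
    il <- otoi_indices(an$seg, 1L)
    L <- d$alignment_len
    expect_equal(L, min(length(ik), length(il)))
    raw <- (rec$values[ik[1:L]] - rec$values[il[1:L]]) / an$norm$ref_sd
    expect_equal(d$diff, raw, tolerance = 1e-12)
  }
})

test_that("difference construction rejects degenerate TOI pairs and truncates ragged ones", {
  rec <- block_record()
  seg <- optimal_tois(cpts_at(c(4L, 12L, 22L), 30L), rec)
  norm <- znormalize(rec, NULL, seg)
  expect_error(toi_difference(norm, seg, 2L, 2L), "must differ")
  d <- toi_difference(norm, seg, 3L, 2L)   # lengths 6 and 5
  expect_equal(d$alignment_len, 5L)
  # identical raw segments difference to exactly zero under the shared reference
  rec2 <- block_record(values = rep(c(1, 5, 2, 8, 3, 1, 4, 2, 9, 3), 3))
  seg2 <- structure(list(k = 0L, it_times = c(NA, 11, 21),
                         otoi = list(c(1, 10), c(11, 20), c(21, 30)),
                         ott = list(), toi_labels = c("basal", "cold", "warm"),
                         ni = 30L),
                    class = "toi_segmentation")
  norm2 <- znormalize(rec2, NULL, seg2)
  d2 <- toi_difference(norm2, seg2, 2L, 1L, source = "z")
  expect_equal(d2$diff, rep(0, 10))
})

test_that("normalization is invariant to affine rescaling of the raw signal", {
  set.seed(222)
  rec <- simulate_subject(small_design(), "experimental", "female", 1,
                          subject_seed = 31)
  an1 <- analyze_record(rec)
  rec2 <- rec
  rec2$values <- 2.5 * rec$values + 100
  an2 <- analyze_record(rec2)
  expect_equal(an1$norm$z, an2$norm$z, tolerance = 1e-8)
})

test_that("the PLA smooths the signal: per-segment variance never exceeds the data's", {
  # least-squares projection property: on every changepoint segment the
  # fitted line's dispersion is bounded by the data's (the normalized z_pla
  # has no such bound, since it is rescaled by its own, smaller, reference sd)
  set.seed(333)
  design <- small_design()
  for (i in 1:8) {
    rec <- simulate_subject(design, "control", "female", i, subject_seed = 660 + i)
    an <- analyze_record(rec)
    pos <- an$cpts$positions
    for (s in seq_len(length(pos) - 1L)) {
      idx <- (pos[s] + 1L):pos[s + 1L]
      expect_lte(var(an$pla$fitted[idx]), var(rec$values[idx]) + 1e-12)
      expect_lt(sd(an$pla$fitted[idx]) / max(1e-12, sd(rec$values[idx])), 1 + 1e-12)
    }
  }
})
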