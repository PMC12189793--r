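test_that("changepoints are split by the marker of the sample at their position", {
  rec <- block_record()
  subs <- split_by_marker(cpts_at(c(4L, 12L, 22L), 30L), rec)
  expect_equal(subs, list(basal = 4L, cold = 12L, warm = 22L))
  # no interior changepoints -> all subsets empty
  subs0 <- split_by_marker(cpts_at(integer(), 30L), rec)
  expect_true(all(lengths(subs0) == 0L))
  # a changepoint on the first sample of the cold block belongs to cold
  subs1 <- split_by_marker(cpts_at(11L, 30L), rec)
  expect_equal(subs1$cold, 11L)
  expect_equal(length(subs1$basal), 0L)
})

test_that("intervention times are the earliest changepoint per TOI, with marker fallback", {
  rec <- block_record()
  subs <- split_by_marker(cpts_at(c(12L, 17L, 22L), 30L), rec)
  it <- suppressWarnings(intervention_times(subs, rec))
  expect_equal(it[2], 12)
  expect_equal(it[3], 22)
  expect_true(is.na(it[1]))  # basal entry unused when tau_1 is empty
  # empty warm subset falls back to the marker boundary, with a warning
  subs2 <- split_by_marker(cpts_at(c(4L, 12L), 30L), rec)
  expect_warning(it2 <- intervention_times(subs2, rec), "marker boundary")
  expect_equal(it2[3], 21)
})

test_that("the optimal-TOI algorithm reproduces the hand-traced example", {
  rec <- block_record()
  seg <- optimal_tois(cpts_at(c(4L, 12L, 22L), 30L), rec)
  expect_equal(seg$k, 2L)
  expect_equal(seg$it_times[2:3], c(12, 22))
  expect_equal(seg$otoi, list(c(1, 9), c(15, 19), c(25, 30)))
  expect_equal(seg$ott, list(c(10, 14), c(20, 24)))
})

test_that("with no detected changepoints the windows collapse to the marker boundaries", {
  rec <- block_record()
  seg <- suppressWarnings(optimal_tois(cpts_at(integer(), 30L), rec))
  expect_equal(seg$k, 0L)
  expect_equal(seg$ott, list(c(11, 11), c(21, 21)))
  expect_equal(seg$otoi, list(c(1, 10), c(12, 20), c(22, 30)))
})

test_that("inadmissible windows error by default and clamp when asked", {
  rec <- block_record()
  # 6 post-basal changepoints -> k = 6 -> middle TOI [IT2+7, IT3-7] empty
  crowded <- cpts_at(c(11L, 13L, 15L, 17L, 22L, 25L, 28L), 30L)
  expect_error(optimal_tois(crowded, rec), "inadmissible window")
  expect_warning(seg <- optimal_tois(crowded, rec, clamp = TRUE), "clamped")
  expect_lt(seg$k, 6L)
  covered <- sort(c(unlist(lapply(seg$otoi, function(r) r[1]:r[2])),
                    unlist(lapply(seg$ott, function(r) r[1]:r[2]))))
  expect_equal(covered, 1:30)
})

test_that("every transition window is symmetric about its intervention time", {
  set.seed(606)
  design <- small_design()
  for (i in 1:10) {
    rec <- simulate_subject(design, sample(c("control", "experimental"), 1),
                            "female", i, subject_seed = 900 + i)
    seg <- optimal_tois(pelt_segment(rec$values, default_penalty(rec$values)), rec)
    for (j in seq_along(seg$ott)) {
      expect_equal(seg$ott[[j]],
                   c(seg$it_times[j + 1] - seg$k, seg$it_times[j + 1] + seg$k))
    }
  }
})

test_that("optimal TOIs and transitions exactly partition the record", {
  set.seed(707)
  design <- small_design()
  for (i in 1:40) {
    rec <- simulate_subject(design,
                            if (i %% 2) "control" else "experimental",
                            if (i %% 3) "male" else "female",
                            i, subject_seed = 5000 + i)
    seg <- optimal_tois(pelt_segment(rec$values, default_penalty(rec$values)), rec)
    covered <- sort(c(unlist(lapply(seg$otoi, function(r) r[1]:r[2])),
                      unlist(lapply(seg$ott, function(r) r[1]:r[2]))))
    expect_equal(covered, seq_len(record_length(rec)))
    # sum of OTOI and OTT lengths accounts for every sample
    expect_equal(sum(vapply(seg$otoi, function(r) r[2] - r[1] + 1, numeric(1))) +
                   (length(seg$ott)) * (2 * seg$k + 1),
                 record_length(rec))
  }
})

test_that("segmentation geometry ignores the perfusion scale", {
  set.seed(808)
  rec <- simulate_subject(small_design(), "control", "male", 1,
                          subject_seed = 4242)
  seg1 <- optimal_tois(pelt_segment(rec$values, default_penalty(rec$values)), rec)
  rec2 <- rec
  rec2$values <- rec$values * 3.7
  seg2 <- optimal_tois(pelt_segment(rec2$values, default_penalty(rec2$values)), rec2)
  expect_equal(seg1$k, seg2$k)
  expect_equal(seg1$otoi, seg2$otoi)
  expect_equal(seg1$ott, seg2$ott)
})

test_that("a segmentation serializes to the documented JSON shape", {
  rec <- block_record()
  seg <- optimal_tois(cpts_at(c(4L, 12L, 22L), 30L), rec)
  parsed <- jsonlite::fromJSON(segmentation_json(seg))
  expect_equal(parsed$k, 2L)
  expect_equal(parsed$otoi[1, ], c(1L, 9L))
  expect_equal(parsed$ott[2, ], c(20L, 24L))
})
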