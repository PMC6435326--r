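test_that("instantaneous speeds convert steps to um/min", {
  tr <- straight_track(n = 10, step = 1, dt = 40)  # 1 um per 40 s
  expect_equal(instantaneous_speeds(tr), rep(1.5, 9))
  expect_equal(instantaneous_speeds(stationary_track()), rep(0, 11))
})

test_that("track construction and speed reject malformed time axes", {
  expect_error(track("t", 0:1, c(10, 10), matrix(0, 2, 3)),
               class = "gt_invalid_argument")
  expect_error(track("t", 0L, 0, matrix(0, 1, 3)),
               class = "gt_invalid_argument")
  uneven <- track("t", 0:2, c(0, 40, 120), matrix(rnorm(9), 3, 3))
  expect_error(instantaneous_speeds(uneven), class = "gt_invalid_argument")
})

test_that("speed is invariant under rigid motions of the coordinates", {
  set.seed(5)
  pos <- apply(matrix(rnorm(60), ncol = 3), 2, cumsum)
  tr <- track("a", 0:19, (0:19) * 40, pos)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  tr2 <- track("b", tr$frames, tr$times,
               sweep(pos %*% rot, 2, c(10, -4, 2), "+"))
  expect_equal(instantaneous_speeds(tr), instantaneous_speeds(tr2))
  expect_equal(as.numeric(directionality(tr, 10)),
               as.numeric(directionality(tr2, 10)))
})

test_that("condition mean speed averages tracks, not steps", {
  t1 <- straight_track(n = 5, step = 1 / 1.5)   # 1 um/min
  t2 <- straight_track(n = 50, step = 2)        # 3 um/min, many more steps
  out <- condition_mean_speed(list(t1, t2))
  expect_equal(out$mean, 2)  # one vote per track
  single <- condition_mean_speed(list(t1))
  expect_true(single$single_track)
  expect_true(is.na(single$se))
  expect_error(condition_mean_speed(list()), class = "gt_invalid_argument")
})

test_that("directionality is 1 for straight motion and 0 for closed segments", {
  expect_equal(as.numeric(directionality(straight_track(n = 30), 10)), 1)
  # out 5 steps and straight back: net displacement 0, path > 0
  pos <- cbind(c(0:5, 4:0), 0, 0)
  loop <- track("loop", 0:10, (0:10) * 40, pos)
  d <- directionality(loop, window = 11)
  expect_equal(as.numeric(d), 0)
  # stationary segment defined as 0 and flagged
  ds <- directionality(stationary_track(n = 10), window = 10)
  expect_equal(as.numeric(ds), 0)
  expect_equal(attr(ds, "n_zero_path"), 1L)
  expect_error(directionality(straight_track(n = 5), window = 10),
               class = "gt_track_too_short")
})

test_that("directionality is scale-invariant, bounded and time-reversible", {
  set.seed(8)
  # 19 frames tile exactly into two 10-frame segments sharing frame 10, so
  # reversing time maps the segment set onto itself
  for (i in 1:20) {
    pos <- apply(matrix(rnorm(3 * 19), ncol = 3), 2, cumsum)
    tr <- track("r", 0:18, (0:18) * 40, pos)
    d <- as.numeric(directionality(tr, 10))
    expect_gte(d, 0)
    expect_lte(d, 1)
    scaled <- track("s", tr$frames, tr$times, pos * 7.3)
    expect_equal(as.numeric(directionality(scaled, 10)), d)
    rev_tr <- track("v", tr$frames, tr$times, pos[19:1, ])
    expect_equal(as.numeric(directionality(rev_tr, 10)), d)
    expect_equal(instantaneous_speeds(rev_tr), rev(instantaneous_speeds(tr)))
  }
})

test_that("random-walk directionality matches an independent Monte-Carlo oracle", {
  # oracle: E[net displacement / path] for 9 isotropic unit steps, computed
  # directly from raw normal draws without any package code
  set.seed(314)
  n_mc <- 40000
  oracle <- mean(vapply(seq_len(n_mc), function(i) {
    steps <- matrix(rnorm(27), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    sqrt(sum(colSums(steps)^2)) / 9
  }, numeric(1)))

  cfg <- track_sim_config(n_tracks = 600, n_frames = 28, speed = 2,
                          persistence = 0, seed = 9)
  est <- condition_directionality(simulate_tracks(cfg), window = 10)$mean
  expect_equal(est, oracle, tolerance = 0.02)
})

test_that("higher persistence gives strictly higher directionality", {
  wins <- vapply(1:50, function(i) {
    hi <- condition_directionality(simulate_tracks(
      track_sim_config(n_tracks = 15, n_frames = 20, persistence = 0.9,
                       seed = 1000 + i)), window = 10)$mean
    lo <- condition_directionality(simulate_tracks(
      track_sim_config(n_tracks = 15, n_frames = 20, persistence = 0.3,
                       seed = 2000 + i)), window = 10)$mean
    hi > lo
  }, logical(1))
  expect_true(all(wins))
})

test_that("entry time is the gap between first edge and first inside crossing", {
  # crosses the edge plane at frame 10 and the inside plane at frame 43
  n <- 60
  x <- seq(0, 59, by = 1)
  tr <- track("c", 0:(n - 1), (0:(n - 1)) * 40, cbind(x, 0, 0))
  bd <- list(axis = "x", edge = 10, inside = 43, direction = ">=")
  et <- germband_entry_time(list(tr), bd)
  expect_equal(et$entry_min, 22)  # 33 frames x 40 s
  expect_equal(et$t_edge, 10 * 40 / 60)

  # earliest edge and inside arrivals may come from different tracks
  early_edge <- track("e", 0:5, (0:5) * 40, cbind(c(9, 11, 11, 11, 11, 11), 0, 0))
  late_inside <- track("i", 0:5, (0:5) * 40, cbind(c(5, 5, 44, 44, 44, 44), 0, 0))
  et2 <- germband_entry_time(list(early_edge, late_inside), bd)
  # brute-force over both tracks: earliest x >= 10 is t = 40 s (track e),
  # earliest x >= 43 is t = 80 s (track i)
  expect_equal(et2$t_edge, 40 / 60)
  expect_equal(et2$t_inside, 80 / 60)
  expect_equal(et2$entry_min, 40 / 60)

  never <- track("n", 0:5, (0:5) * 40, cbind(rep(1, 6), 0, 0))
  expect_error(germband_entry_time(list(never), bd), class = "gt_no_entry")
})

test_that("percent reduction reproduces the printed speed comparisons", {
  expect_identical(percent_reduction(2.72, 1.55), 43L)
  expect_identical(percent_reduction(2.46, 2.02), 18L)
  expect_identical(percent_reduction(2.46, 1.66), 33L)
  expect_identical(percent_reduction(2.5, 2.5), 0L)
  expect_error(percent_reduction(0, 1), class = "gt_invalid_argument")
})
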