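# Track velocity, axial directionality, alignment grouping and the
# alignment-vs-directionality association.

mk_track <- function(x, y, dt = 0.5) {
  data.frame(track_id = 1L, time_min = (seq_along(x) - 1) * dt,
             x_um = x, y_um = y)
}

test_that("velocity is path length over elapsed time, invariant to reversal", {
  tr <- mk_track(c(0, 10, 20, 30, 40), rep(0, 5))      # 10 um per 0.5 min
  expect_equal(track_velocity(tr), 20.0)
  expect_equal(track_velocity(mk_track(rep(3, 5), rep(7, 5))), 0.0)
  zig <- mk_track(c(0, 10, 0, 10, 0), rep(0, 5))       # back and forth
  expect_equal(track_velocity(zig), 20.0)
  rev <- mk_track(rev(zig$x_um), rev(zig$y_um))
  expect_equal(track_velocity(rev), track_velocity(zig))
  expect_error(track_velocity(mk_track(c(0, 1), c(0, 0), dt = 0)), "increasing")
})

test_that("axial orientation is sum|dy|/sum|dx| with the documented symmetries", {
  diag <- mk_track(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(axial_orientation(diag), 1.0)
  expect_equal(axial_orientation(mk_track(c(0, 5, 9), c(2, 2, 2))), 0.0)
  expect_true(is.na(axial_orientation(mk_track(c(1, 1, 1), c(0, 3, 9)))))
  set.seed(31)
  tr <- mk_track(cumsum(rnorm(20)), cumsum(rnorm(20)))
  # translation invariance
  shifted <- tr; shifted$x_um <- tr$x_um + 100; shifted$y_um <- tr$y_um - 50
  expect_equal(axial_orientation(shifted), axial_orientation(tr))
  # time rescaling invariance
  fast <- tr; fast$time_min <- tr$time_min * 3
  expect_equal(axial_orientation(fast), axial_orientation(tr))
  # x/y swap maps the ratio to its reciprocal
  swapped <- tr; swapped$x_um <- tr$y_um; swapped$y_um <- tr$x_um
  expect_equal(axial_orientation(swapped), 1 / axial_orientation(tr))
})

test_that("alignment grouping applies the 0.40/0.60 bounds, closed band inclusive", {
  expect_equal(as.character(classify_alignment(c(0.35, 0.40, 0.5, 0.60, 0.70))),
               c("non-aligned", "partially aligned", "partially aligned",
                 "partially aligned", "aligned"))
  expect_error(classify_alignment(1.2), "\\[0, 1\\]")
})

test_that("track summaries drop too-short tracks and report per-track stats", {
  tracks <- simulate_tracks(track_sim_spec(n_tracks = 20, frames = 10, seed = 3))
  st <- summarize_tracks(tracks)
  expect_equal(nrow(st), 20L)
  expect_equal(unique(st$n_steps), 9L)
  expect_true(all(st$velocity_um_min > 0))
  # a two-frame track falls below the 3-frame minimum
  two <- tracks[tracks$track_id == 1 & tracks$frame <= 1, ]
  class(two) <- class(tracks)
  expect_equal(nrow(summarize_tracks(two)), 0L)
})

test_that("unbiased persistent random walks have median axial orientation near 1", {
  tracks <- simulate_tracks(track_sim_spec(n_tracks = 3000, frames = 30,
                                           bias = 0, seed = 17))
  st <- summarize_tracks(tracks)
  expect_equal(median(st$axial_orientation), 1.0, tolerance = 0.05)
})

test_that("median axial orientation increases strictly with the generator bias", {
  med <- vapply(c(0, 0.25, 0.5, 1), function(b)
    median(summarize_tracks(simulate_tracks(track_sim_spec(
      n_tracks = 1500, frames = 40, bias = b, seed = 5)))$axial_orientation),
    numeric(1))
  expect_true(all(diff(med) > 0))
  expect_gt(med[4], 1.5)
})

test_that("axial orientation does not differ across alignment grades when migration is unbiased", {
  nonsig <- 0L
  for (r in 1:100) {
    a <- summarize_tracks(simulate_tracks(track_sim_spec(
      n_tracks = 40, frames = 30, bias = 0, seed = 2000L + 2L * r)))
    b <- summarize_tracks(simulate_tracks(track_sim_spec(
      n_tracks = 40, frames = 30, bias = 0, seed = 2001L + 2L * r)))
    p <- mann_whitney_u(a$axial_orientation, b$axial_orientation)$p
    if (p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 90L)
})

test_that("the alignment-orientation association is null without bias and positive with it", {
  expect_equal(alignment_orientation_association(1:5 / 10, 2 * (1:5) / 10 + 1)$r,
               1.0)
  # null: independent alignment and unbiased migration
  nonsig <- 0L
  for (r in 1:60) {
    with_seed <- 3000L + r
    set.seed(with_seed)
    algn <- runif(8, 0.2, 0.8)
    med <- vapply(1:8, function(ch)
      median(summarize_tracks(simulate_tracks(track_sim_spec(
        n_tracks = 25, frames = 25, bias = 0,
        seed = with_seed * 10L + ch)))$axial_orientation), numeric(1))
    if (alignment_orientation_association(algn, med)$p > 0.05)
      nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 45L)   # |r| small, p > 0.05 in most replicates
  # positive control: bias coupled to alignment
  algn <- seq(0.15, 0.85, length.out = 12)
  med <- vapply(seq_along(algn), function(ch)
    median(summarize_tracks(simulate_tracks(track_sim_spec(
      n_tracks = 120, frames = 50, bias = algn[ch],
      seed = 500L + ch)))$axial_orientation), numeric(1))
  assoc <- alignment_orientation_association(algn, med)
  expect_gt(assoc$r, 0.5)
  expect_lt(assoc$p, 0.05)
})
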