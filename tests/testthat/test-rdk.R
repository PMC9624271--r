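p_default <- stimulus_params()

test_that("stimulus geometry and timing are self-consistent", {
  expect_equal(implied_dot_count(p_default), 275L)
  # 6 frames at 60 Hz span 100 ms; 4 frames span ~67 ms
  expect_equal(p_default$tm_cycle_frames / p_default$refresh_hz, 0.1)
  expect_equal(round(p_default$wm_lifetime_frames / p_default$refresh_hz * 1000), 67)
  expect_equal(p_default$dot_step_dva,
               p_default$speed_dva_per_s / p_default$refresh_hz)
  expect_error(stimulus_params(dot_step_dva = 0.2), "must equal")
  expect_error(stimulus_params(inner_diameter_dva = 20), "smaller")
})

test_that("border alpha is 0 at the borders, 1 on the plateau, and unimodal", {
  expect_equal(border_alpha(4.375, p_default), 1)
  expect_equal(border_alpha(1.25, p_default), 0)
  expect_equal(border_alpha(7.5, p_default), 0)
  expect_equal(border_alpha(0.5, p_default), 0)
  expect_equal(border_alpha(9, p_default), 0)
  r <- seq(1.25, 7.5, length.out = 400)
  a <- border_alpha(r, p_default)
  d <- diff(a)
  turn <- which(d < 0)[1]
  expect_true(all(d[seq_len(turn - 1)] >= 0))
  expect_true(all(d[turn:length(d)] <= 0))
})

test_that("transparent motion at full coherence is a rigid drift", {
  mov <- simulate_rdk("tm", direction_deg = 90, coherence = 1,
                      n_frames = 6, seed = 4)
  expect_true(all(mov$identity == "signal"))
  w <- tidyr::pivot_wider(mov[, c("frame", "dot", "x", "y")],
                          names_from = "frame", values_from = c("x", "y"))
  dx <- w$x_2 - w$x_1
  dy <- w$y_2 - w$y_1
  # direction 90 deg = rightward: +x displacement of one dot step (no wraps
  # occur in one step for dots inside the aperture)
  inside <- sqrt(w$x_1^2 + w$y_1^2) < 7.4
  expect_true(all(abs(dx[inside] - 0.1) < 1e-12))
  expect_true(all(abs(dy[inside]) < 1e-12))
})

test_that("signal counts follow half-up rounding of n_dots x coherence", {
  mov <- simulate_rdk("tm", 0, coherence = 0.5, n_frames = 6, seed = 1)
  per_frame <- tapply(mov$identity == "signal", mov$frame, sum)
  expect_true(all(per_frame == 138))  # round(275 * 0.5) half-up
  movb <- simulate_rdk("bm", 0, coherence = 0.25, n_frames = 10, seed = 1)
  per_frame_b <- tapply(movb$identity == "signal", movb$frame, sum)
  expect_true(all(per_frame_b == round(275 * 0.25)))
})

test_that("dot count is constant across frames for all three simulators", {
  for (type in c("tm", "bm", "wm")) {
    mov <- simulate_rdk(type, 45, coherence = 0.5, n_frames = 9, seed = 2)
    expect_equal(unname(table(mov$frame)), rep(275L, 9),
                 ignore_attr = TRUE)
  }
})

test_that("Brownian motion at full coherence reproduces transparent motion", {
  tm <- simulate_rdk("tm", 30, coherence = 1, n_frames = 12, seed = 9)
  bm <- simulate_rdk("bm", 30, coherence = 1, n_frames = 12, seed = 9)
  expect_equal(bm$x, tm$x, tolerance = 1e-12)
  expect_equal(bm$y, tm$y, tolerance = 1e-12)
  expect_equal(bm$identity, tm$identity)
})

test_that("Brownian-motion dot lifetimes stay within 100-200 ms at 0% coherence", {
  mov <- simulate_rdk("bm", 0, coherence = 0, n_frames = 60, seed = 21)
  p <- p_default
  lifetimes <- c()
  for (d in unique(mov$dot)) {
    tr <- mov[mov$dot == d, ]
    dx <- diff(tr$x)
    dy <- diff(tr$y)
    step <- sqrt(dx^2 + dy^2)
    radius <- sqrt(tr$x^2 + tr$y^2)[-1]
    # anomalous displacement outside the aperture = wrap; inside = erasure
    erase <- which(abs(step - p$dot_step_dva) > 1e-9 & radius <= 7.5)
    if (length(erase) >= 2) lifetimes <- c(lifetimes, diff(erase))
  }
  expect_gt(length(lifetimes), 500)
  expect_true(all(lifetimes >= 6))
  expect_true(all(lifetimes <= 12))
})

test_that("white-noise motion interleaves sets with 4-frame identity epochs", {
  mov <- simulate_rdk("wm", 0, coherence = 0.5, n_frames = 12, seed = 5)
  by_frame <- tapply(mov$set, mov$frame, unique)
  expect_equal(as.integer(by_frame), rep(1:3, 4))  # one set per frame

  id_at <- function(f) mov$identity[mov$frame == f]
  # identities persist across a set's two presentations (frames 1 and 4),
  # then are reshuffled (frame 7)
  expect_identical(id_at(1), id_at(4))
  expect_identical(id_at(7), id_at(10))
  expect_false(identical(id_at(4), id_at(7)))

  # one dot step is conveyed between a set's consecutive appearances
  a <- mov[mov$frame == 1, ]
  b <- mov[mov$frame == 4, ]
  step <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  no_wrap <- sqrt(b$x^2 + b$y^2) <= 7.5
  expect_true(all(abs(step[no_wrap] - 0.1) < 1e-9))
})

test_that("outer-border wrap re-enters diametrically and conserves dots", {
  # place a coherent stimulus moving up long enough that dots wrap
  mov <- simulate_rdk("tm", 0, coherence = 1, n_frames = 40, seed = 8)
  expect_equal(unname(table(mov$frame)), rep(275L, 40), ignore_attr = TRUE)
  # any dot beyond the outer radius is invisible
  r <- sqrt(mov$x^2 + mov$y^2)
  expect_true(all(mov$alpha[r >= 7.5] == 0))
  # find a wrap event and verify the diametric re-entry
  w <- tidyr::pivot_wider(mov[, c("frame", "dot", "x", "y")],
                          names_from = "frame", values_from = c("x", "y"))
  wrapped <- FALSE
  for (f in 2:40) {
    x0 <- w[[paste0("x_", f - 1)]]; y0 <- w[[paste0("y_", f - 1)]]
    x1 <- w[[paste0("x_", f)]]; y1 <- w[[paste0("y_", f)]]
    i <- which(abs(x1 - (-(x0))) < 1e-9 & abs(y1 - (-(y0 + 0.1))) < 1e-9)
    if (length(i)) { wrapped <- TRUE; break }
  }
  expect_true(wrapped)
})

test_that("dot movies export to CSV with a JSON manifest", {
  mov <- simulate_rdk("tm", 0, 1, n_frames = 2, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dot_movie(mov, csv, js, p_default)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), nrow(mov))
  man <- jsonlite::read_json(js)
  expect_equal(man$n_dots, 275L)
})
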