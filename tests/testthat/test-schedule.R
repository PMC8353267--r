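test_that("iRT calibration recovers exact and noisy lines", {
  pts <- data.frame(irt = c(0, 20, 50, 90), rt = 5 + 0.3 * c(0, 20, 50, 90))
  cal <- fit_rt_calibration(pts)
  expect_equal(cal$slope, 0.3)
  expect_equal(cal$intercept, 5)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-10)

  expect_error(fit_rt_calibration(data.frame(irt = c(5, 5), rt = c(1, 2))),
               "distinct")

  set.seed(31)
  irt <- seq(0, 100, length.out = 11)
  noisy <- data.frame(irt = irt, rt = 5 + 0.3 * irt + rnorm(11, 0, 0.1))
  cal2 <- fit_rt_calibration(noisy)
  se_slope <- 0.1 / sqrt(sum((irt - mean(irt))^2))
  expect_lt(abs(cal2$slope - 0.3), 3 * se_slope)
})

test_that("windows are centred, clipped and shared by label twins", {
  panel <- default_panel()
  cal <- fit_rt_calibration(data.frame(irt = c(0, 100), rt = c(5, 35)))
  cfg <- schedule_config(window_width = 4, gradient_length = 40)
  method <- assign_windows(panel, cal, cfg)
  expect_equal(nrow(method$entries), nrow(panel$transitions))  # conservation

  e <- method$entries
  centre <- 5 + 0.3 * e$irt
  inner <- centre - 2 > 0 & centre + 2 < 40
  expect_equal(e$window_start[inner], centre[inner] - 2)
  expect_equal(e$window_end[inner], centre[inner] + 2)
  expect_true(all(e$window_start >= 0 & e$window_end <= 40))

  # light/heavy twins share one window
  key <- paste(e$peptide_sequence, e$fragment, e$fragment_charge,
               e$precursor_charge)
  for (k in unique(key)[1:10]) {
    w <- e[key == k, c("window_start", "window_end")]
    expect_equal(nrow(unique(w)), 1)
  }

  # clipping at the gradient start: predicted 1 min, width 4 -> [0, 3]
  one <- panel$transitions[1, , drop = FALSE]
  one$irt <- 0
  low <- assign_windows(one, structure(list(slope = 0.3, intercept = 1),
                                       class = "rt_calibration"),
                        schedule_config(window_width = 4,
                                        gradient_length = 30))
  expect_equal(low$entries$window_start, 0)
  expect_equal(low$entries$window_end, 3)

  one$irt <- NA_real_
  expect_error(assign_windows(one, cal, cfg), "without iRT")
})

test_that("concurrency sweep matches fixtures and the grid oracle", {
  w <- data.frame(window_start = c(10, 12, 13, 30),
                  window_end = c(14, 16, 17, 34))
  expect_equal(max_concurrency(w), 3)
  expect_equal(max_concurrency(w[0, ]), 0L)
  all258 <- data.frame(window_start = rep(5, 258), window_end = rep(9, 258))
  expect_equal(max_concurrency(all258), 258)
  # half-open windows: touching windows do not overlap
  touch <- data.frame(window_start = c(0, 4), window_end = c(4, 8))
  expect_equal(max_concurrency(touch), 1)

  set.seed(32)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    start <- round(runif(n, 0, 26), 1)
    wd <- data.frame(window_start = start,
                     window_end = start + round(runif(n, 0.5, 6), 1))
    expect_equal(max_concurrency(wd),
                 oracle_concurrency(wd$window_start, wd$window_end))
  }
})

test_that("cycle-time feasibility follows dwell x concurrency arithmetic", {
  mk <- function(n, width = 4) {
    structure(list(entries = data.frame(window_start = rep(10, n),
                                        window_end = rep(10 + width, n))),
              class = "scheduled_method")
  }
  cfg <- schedule_config(dwell_time = 0.010, max_cycle_time = 1.7)
  m <- check_feasibility(mk(170), cfg)
  expect_equal(m$effective_cycle_time, 1.7)
  expect_true(m$feasible)

  m0 <- check_feasibility(mk(0), cfg)
  expect_equal(m0$effective_cycle_time, 0)
  expect_true(m0$feasible)

  m400 <- check_feasibility(mk(400), cfg)
  expect_equal(m400$effective_cycle_time, 4.0)
  expect_false(m400$feasible)

  # interscan overhead adds per transition
  cfg2 <- schedule_config(dwell_time = 0.010, interscan_overhead = 0.005)
  expect_equal(check_feasibility(mk(100), cfg2)$effective_cycle_time, 1.5)
})

test_that("effective cycle time is monotone in window width", {
  panel <- default_panel()
  cal <- fit_rt_calibration(data.frame(irt = c(0, 100), rt = c(2, 30)))
  cycles <- vapply(c(1, 2, 4, 8, 16), function(w) {
    assign_windows(panel, cal,
                   schedule_config(window_width = w,
                                   gradient_length = 30))$effective_cycle_time
  }, numeric(1))
  expect_true(all(diff(cycles) >= 0))
})
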