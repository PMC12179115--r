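test_that("SUV follows the unit arithmetic", {
  sch <- turku_schedule()
  flat <- tac(sch, rep(1, nrow(sch)))
  expect_equal(suv_window(flat, 500, 70)$value, 70 / 500)
  expect_equal(suv_window(tac(sch, rep(0, nrow(sch))), 500, 70)$value, 0)
})

test_that("window averaging is duration-weighted over the overlap", {
  sch <- frame_schedule(counts = c(4, 2), durations = c(10, 10),
                        units = "min")
  vals <- c(9, 9, 9, 9, 2, 4)  # two 10-min frames tile 40-60 exactly
  s <- suv_window(tac(sch, vals), 100, 50, window = c(40, 60))
  expect_equal(s$mean_conc, 3)
  expect_equal(s$value, 3 * 50 / 100)
  # partial overlap: window 35-45 takes 5 min of frame 4 and 5 of frame 5
  s2 <- suv_window(tac(sch, vals), 100, 50, window = c(35, 45))
  expect_equal(s2$mean_conc, (5 * 9 + 5 * 2) / 10)
})

test_that("SUV is linear in concentration and weight, inverse in activity", {
  sch <- turku_schedule()
  x <- tac(sch, seq_len(nrow(sch)))
  base <- suv_window(x, 400, 80)$value
  expect_equal(suv_window(tac(sch, 2 * x$values), 400, 80)$value, 2 * base)
  expect_equal(suv_window(x, 400, 160)$value, 2 * base)
  expect_equal(suv_window(x, 800, 80)$value, base / 2)
})

test_that("degenerate windows are rejected", {
  sch <- turku_schedule()
  x <- tac(sch, rep(1, nrow(sch)))
  expect_error(suv_window(x, 500, 70, window = c(70, 80)), "overlap")
  expect_error(suv_window(x, 500, 70, window = c(60, 40)), "end > start")
  expect_error(suv_window(x, -1, 70), "positive")
})
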