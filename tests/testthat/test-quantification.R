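test_that("ROI means are exact on constant images and local to their ROI", {
  img <- matrix(7.5, 40, 40)
  roi <- matrix(FALSE, 40, 40); roi[5:10, 5:10] <- TRUE
  expect_equal(measure_expression(img, roi), 7.5)
  expect_error(measure_expression(img, matrix(FALSE, 40, 40)), "empty")
  labs <- matrix(0L, 40, 40); labs[5:10, 5:10] <- 1L; labs[20:30, 20:30] <- 2L
  img[labs == 2] <- 100
  m1 <- measure_expression(img, labs, cell_id = 1)
  m2 <- measure_expression(img, labs, cell_id = 2)
  expect_equal(c(m1, m2), c(7.5, 100))
})

test_that("quiet-field cytoplasm intensity is recovered within 2%", {
  fx <- quiet_field()
  seg <- segment_cells(fx$field$image[, , 1], fx$config$pixel_size,
                       min_area = 30)
  # cell 4 has no puncta; its adaptor-channel ROI mean is cytoplasm + bg
  d <- sqrt((seg$rois$centroid_x_um - fx$cells$x_um[4])^2 +
              (seg$rois$centroid_y_um - fx$cells$y_um[4])^2)
  lab <- seg$rois$cell_id[which.min(d)]
  m <- measure_expression(fx$field$image[, , 2], seg$labels, cell_id = lab)
  truth <- fx$cells$cyt_adaptor[4] + fx$config$background_level[2]
  expect_lt(abs(m - truth) / truth, 0.02)
})

test_that("group summaries give the closed-form mean and SEM", {
  df <- data.frame(region = "R", group = "g", v = c(1, 2, 3))
  s <- summarize_group(df, "v")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-9)
  df$v <- c(4, 4, 4)
  expect_equal(summarize_group(df, "v")$sem, 0)
  expect_error(summarize_group(data.frame(region = "R", group = "g", v = 1), "v"),
               "fewer than 2")
})

test_that("undefined percentage entries are excluded with n adjusted", {
  df <- data.frame(region = "R", group = "g",
                   n_coloc = c(1, 2, 3),
                   pct = c(10, NA, 30))
  sc <- summarize_group(df, "n_coloc")
  sp <- summarize_group(df, "pct")
  expect_equal(sc$n_cells, 3)
  expect_equal(sp$n_cells, 2)
  expect_equal(sp$mean, 20)
})

test_that("control normalization returns percentages of control", {
  s <- data.frame(region = "R", group = c("control", "t1", "t2"),
                  endpoint = "e", n_cells = 10,
                  mean = c(50, 75, 50), sem = 1)
  n <- normalize_to_control(s, "control")
  expect_equal(n$relative_mean, c(100, 150, 100))
  s0 <- s; s0$mean[1] <- 0
  expect_error(normalize_to_control(s0, "control"), "zero")
  expect_error(normalize_to_control(s[-1, ], "control"), "control")
})

test_that("simulated expression effects are recovered on the relative scale", {
  cfg <- acquisition_config(field_shape = c(300L, 300L))
  des <- cohort_design(groups = c("control", "treated"), cells_per_group = 24,
                       baseline = list(expression_adaptor = 120,
                                       expression_autophagosome = 110,
                                       puncta_rate_adaptor = 0.01,
                                       puncta_rate_autophagosome = 0.01,
                                       coloc_fraction = 0),
                       multipliers = list(treated = list(expression_adaptor = 1.5)),
                       soma_radius = 8, seed = 21)
  co <- generate_cohort(des, cfg)
  meas <- measure_cohort(co, cfg)
  s <- summarize_group(meas, "expr_adaptor")
  n <- normalize_to_control(s, "control")
  rel <- n$relative_mean[n$group == "treated"]
  # sampling error: per-cell CV 0.15 over 24 cells per group
  expect_lt(abs(rel - 150), 150 * 3 * 0.15 * sqrt(2 / 24))
})
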