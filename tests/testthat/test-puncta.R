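test_that("a uniform image produces no puncta", {
  for (v in c(0, 7, 1000)) {
    img <- matrix(v, 120, 120)
    expect_equal(nrow(detect_puncta(img, 0.11)), 0)
  }
})

test_that("too coarse a pixel size is refused with the resolvable limit", {
  img <- matrix(0, 64, 64)
  expect_error(detect_puncta(img, 0.3), "0.9")
})

test_that("noise-free unit-diameter spots are recovered exactly", {
  fx <- quiet_field()
  det <- detect_puncta(fx$field$image[, , 2], fx$config$pixel_size)
  expect_equal(nrow(det), 10)
  ps <- fx$config$pixel_size
  for (i in seq_len(10)) {
    d <- sqrt((det$x_um - fx$puncta$x_um[i])^2 +
                (det$y_um - fx$puncta$y_um[i])^2)
    expect_lte(min(d), ps)
  }
  expect_true(all(det$diameter_um >= 0.7 & det$diameter_um <= 1.4))
})

test_that("detection is invariant to intensity rescaling", {
  fx <- quiet_field()
  img <- fx$field$image[, , 2]
  d1 <- detect_puncta(img, fx$config$pixel_size)
  d2 <- detect_puncta(img * 37.5, fx$config$pixel_size)
  expect_equal(d1$row, d2$row)
  expect_equal(d1$col, d2$col)
  expect_equal(d1$diameter_um, d2$diameter_um, tolerance = 1e-9)
})

test_that("raising the relative threshold never adds detections", {
  co <- small_cohort()
  img <- co$cohort$fields[[1]]$image[, , 2]
  ps <- co$config$pixel_size
  prev <- Inf
  for (thr in c(0.1, 0.2, 0.35, 0.6)) {
    n <- nrow(detect_puncta(img, ps, detection_config(relative_threshold = thr)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("puncta are assigned to the cell under their centroid", {
  fx <- quiet_field()
  seg <- segment_cells(fx$field$image[, , 1], fx$config$pixel_size,
                       min_area = 30)
  det <- detect_puncta(fx$field$image[, , 2], fx$config$pixel_size)
  det <- assign_to_cells(det, seg$labels)
  # all 10 true puncta live in cell 1; find its label by centroid
  d <- sqrt((seg$rois$centroid_x_um - fx$cells$x_um[1])^2 +
              (seg$rois$centroid_y_um - fx$cells$y_um[1])^2)
  lab1 <- seg$rois$cell_id[which.min(d)]
  expect_true(all(det$cell_id == lab1))
  # a synthetic detection over background stays unassigned
  fake <- det[1, ]; fake$row <- 2L; fake$col <- 2L
  expect_true(is.na(assign_to_cells(fake, seg$labels)$cell_id))
  expect_error(assign_to_cells(transform(det, row = 10000L), seg$labels),
               "geometry")
})

test_that("per-cell assigned counts match ground truth on a quiet field", {
  cfg <- quiet_config(field_shape = c(420L, 420L))
  cells <- layout_cells(4, cfg, soma_radius = 10)
  set.seed(42)
  pl <- list()
  for (k in 1:4) {
    n <- c(5, 3, 7, 2)[k]
    g <- expand.grid(dx = c(-5.5, 0, 5.5), dy = c(-5.5, 0, 5.5))[1:n, ]
    pl[[k]] <- data.frame(cell_id = k, channel = "adaptor",
                          x_um = cells$x_um[k] + g$dx,
                          y_um = cells$y_um[k] + g$dy,
                          diameter_um = runif(n, 0.8, 1.4),
                          amp_adaptor = 60, amp_autophagosome = 0)
  }
  p <- do.call(rbind, pl); p$punctum_id <- seq_len(nrow(p))
  fld <- generate_field(cfg, cells, p, seed = 3)
  seg <- segment_cells(fld$image[, , 1], cfg$pixel_size, min_area = 30)
  det <- assign_to_cells(detect_puncta(fld$image[, , 2], cfg$pixel_size),
                         seg$labels)
  for (k in 1:4) {
    d <- sqrt((seg$rois$centroid_x_um - cells$x_um[k])^2 +
                (seg$rois$centroid_y_um - cells$y_um[k])^2)
    lab <- seg$rois$cell_id[which.min(d)]
    expect_equal(sum(det$cell_id == lab, na.rm = TRUE), sum(p$cell_id == k))
  }
})
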