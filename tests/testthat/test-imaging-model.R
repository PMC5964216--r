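test_that("an empty noiseless scene renders all-zero marker-free channels", {
  cfg <- acquisition_config(field_shape = c(64L, 64L), background_level = 0,
                            photon_noise_scale = 0, read_noise_sigma = 0)
  cells <- data.frame(cell_id = integer(), x_um = numeric(), y_um = numeric(),
                      soma_radius_um = numeric(), cyt_cell_marker = numeric(),
                      cyt_adaptor = numeric(), cyt_autophagosome = numeric())
  p <- data.frame(punctum_id = integer(), cell_id = integer(),
                  channel = character(), x_um = numeric(), y_um = numeric(),
                  diameter_um = numeric(), amp_adaptor = numeric(),
                  amp_autophagosome = numeric())
  fld <- generate_field(cfg, cells, p, seed = 1)
  expect_true(all(fld$image[, , 2] == 0))
  expect_true(all(fld$image[, , 3] == 0))
})

test_that("rendered puncta appear as local maxima at ground-truth centres", {
  fx <- quiet_field()
  img <- fx$field$image[, , 2]
  ps <- fx$config$pixel_size
  # independent exhaustive pixel scan: interior pixels not exceeded by any
  # neighbour, with adjacent plateau pixels (integer quantization) merged
  nr <- nrow(img); nc <- ncol(img)
  hits <- NULL
  bg_floor <- 6 + max(fx$cells$cyt_adaptor) + 1   # background + cytoplasm
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1)) {
    v <- img[r, cc]
    if (v <= bg_floor) next
    nb <- img[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (v >= max(nb)) hits <- rbind(hits, c(r, cc))
  }
  # merge plateau pixels closer than 3 px into one maximum
  cl <- rep(0L, nrow(hits)); nxt <- 0L
  for (i in seq_len(nrow(hits))) {
    if (cl[i] == 0L) { nxt <- nxt + 1L; cl[i] <- nxt }
    near <- which((hits[, 1] - hits[i, 1])^2 + (hits[, 2] - hits[i, 2])^2 <= 9)
    cl[near] <- cl[i]
  }
  cy <- tapply(hits[, 1], cl, mean); cx <- tapply(hits[, 2], cl, mean)
  expect_equal(length(cy), 10)
  hx <- (cx - 0.5) * ps
  hy <- (cy - 0.5) * ps
  d <- sapply(seq_len(10), function(i)
    min(sqrt((hx - fx$puncta$x_um[i])^2 + (hy - fx$puncta$y_um[i])^2)))
  expect_true(all(d <= ps * 1.5))
})

test_that("noise differs across seeds while ground truth is unchanged", {
  cfg <- acquisition_config(field_shape = c(128L, 128L))
  cells <- layout_cells(1, cfg, soma_radius = 5)
  p <- data.frame(punctum_id = 1, cell_id = 1, channel = "both",
                  x_um = cells$x_um[1], y_um = cells$y_um[1],
                  diameter_um = 1, amp_adaptor = 80, amp_autophagosome = 80)
  f1 <- generate_field(cfg, cells, p, seed = 1)
  f2 <- generate_field(cfg, cells, p, seed = 2)
  f1b <- generate_field(cfg, cells, p, seed = 1)
  expect_false(identical(f1$image, f2$image))
  expect_identical(f1$image, f1b$image)          # bit-for-bit determinism
  expect_identical(f1$truth, f2$truth)
})

test_that("geometry violations are rejected with the offending ids", {
  cfg <- acquisition_config(field_shape = c(128L, 128L))
  cells <- layout_cells(1, cfg, soma_radius = 5)
  p <- data.frame(punctum_id = 99, cell_id = 1, channel = "adaptor",
                  x_um = cells$x_um[1] + 8, y_um = cells$y_um[1],
                  diameter_um = 1, amp_adaptor = 80, amp_autophagosome = 0)
  expect_error(generate_field(cfg, cells, p, seed = 1), "99")
  p$cell_id <- 42
  expect_error(generate_field(cfg, cells, p, seed = 1), "undeclared")
  expect_error(acquisition_config(channel_roles = c(cell_marker = 1L,
                                                    adaptor = 1L,
                                                    autophagosome = 2L)),
               "distinct")
})

test_that("noise-free rendering is homogeneous of degree one in intensity", {
  cfg <- quiet_config(field_shape = c(200L, 200L))
  cells <- layout_cells(1, cfg, soma_radius = 6)
  p <- data.frame(punctum_id = 1:2, cell_id = 1, channel = "adaptor",
                  x_um = cells$x_um[1] + c(-2, 2), y_um = cells$y_um[1],
                  diameter_um = 1, amp_adaptor = 50, amp_autophagosome = 0)
  f1 <- generate_field(cfg, cells, p, seed = 1)
  cfg2 <- cfg; cfg2$background_level <- cfg$background_level * 3
  cells2 <- cells
  for (cl in grep("^cyt_", names(cells2))) cells2[[cl]] <- cells2[[cl]] * 3
  p2 <- p; p2$amp_adaptor <- p$amp_adaptor * 3
  f3 <- generate_field(cfg2, cells2, p2, seed = 1)
  # scaling commutes with rendering up to integer quantization
  expect_true(max(abs(f3$image - 3 * f1$image)) <= 2)
})

test_that("cohort puncta counts follow the group Poisson rates", {
  cfg <- acquisition_config(field_shape = c(500L, 500L))
  des <- cohort_design(groups = "control", cells_per_group = 64,
                       baseline = list(expression_adaptor = 120,
                                       expression_autophagosome = 110,
                                       puncta_rate_adaptor = 25,
                                       puncta_rate_autophagosome = 15,
                                       coloc_fraction = 0),
                       soma_radius = 12, seed = 9)
  co <- generate_cohort(des, cfg)
  tp <- co$truth_puncta
  expect_false(any(tp$channel == "both"))        # zero colocalized fraction
  counts <- table(factor(tp$cell_id[tp$channel == "adaptor"],
                         levels = unique(co$truth_cells$cell_id)))
  expect_lt(abs(mean(counts) - 25), 3 * sqrt(25 / 64))
  # conservation: rendered-channel truth counts match the flat table exactly
  per_field <- sapply(co$fields, function(f)
    sum(f$truth$puncta$channel %in% c("adaptor", "both")))
  flat <- table(factor(tp$field_id[tp$channel %in% c("adaptor", "both")],
                       levels = seq_along(co$fields)))
  expect_equal(unname(per_field), as.vector(flat))
})

test_that("hard-core placement keeps puncta centres apart", {
  co <- small_cohort()$cohort
  for (fi in unique(co$truth_puncta$field_id)) {
    tp <- co$truth_puncta[co$truth_puncta$field_id == fi, ]
    for (cid in unique(tp$cell_id)) {
      q <- tp[tp$cell_id == cid, ]
      if (nrow(q) < 2) next
      dd <- as.matrix(dist(cbind(q$x_um, q$y_um)))
      lim <- outer(q$diameter_um, q$diameter_um, "+") / 2
      diag(dd) <- Inf
      # allow the documented graceful degradation under extreme crowding
      expect_gt(mean(dd >= lim - 1e-9), 0.97)
    }
  }
})

test_that("expression multipliers act multiplicatively on cytoplasm", {
  cfg <- quiet_config(field_shape = c(260L, 260L))
  des <- cohort_design(groups = c("control", "treated"), cells_per_group = 4,
                       baseline = list(expression_adaptor = 100,
                                       expression_autophagosome = 100,
                                       puncta_rate_adaptor = 0.01,
                                       puncta_rate_autophagosome = 0.01,
                                       coloc_fraction = 0),
                       multipliers = list(treated = list(expression_adaptor = 1.5)),
                       soma_radius = 8, expression_cv = 0, seed = 4)
  co <- generate_cohort(des, cfg)
  tc <- co$truth_cells
  r <- mean(tc$cyt_adaptor[tc$group == "treated"]) /
    mean(tc$cyt_adaptor[tc$group == "control"])
  expect_equal(r, 1.5, tolerance = 1e-12)
})

test_that("scenario designs keep the control at baseline", {
  base <- cohort_design()
  for (cat in c("failed-fusion", "impaired-induction")) {
    d <- scenario_from_category(cat, base)
    expect_true(all(unlist(d$multipliers$control) == 1))
  }
  d <- scenario_from_category("failed-fusion", base)
  m <- d$multipliers$`24h`
  expect_gt(m$rate_autophagosome, 1)   # fusion failure raises both rates,
  expect_gt(m$rate_adaptor, 1)         # both expressions, and the
  expect_gt(m$expression_adaptor, 1)   # colocalized fraction
  expect_gt(m$expression_autophagosome, 1)
  expect_gt(m$coloc_fraction, 1)
  d2 <- scenario_from_category("impaired-induction", base)
  expect_lt(d2$multipliers$`5d`$rate_autophagosome, 1)
  expect_lt(d2$multipliers$`5d`$expression_autophagosome, 1)
  expect_lt(d2$multipliers$`5d`$expression_adaptor, 1)
  expect_error(scenario_from_category("no-such-mode", base), "unknown")
})
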