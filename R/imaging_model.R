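#' Acquisition configuration for synthetic confocal-like fields
#'
#' Describes the virtual microscope: pixel size, field geometry, which channel
#' carries which biological role, the point-spread blur, per-channel ambient
#' background, and the noise/quantization model. Defaults emulate a 60x
#' confocal acquisition where a 0.5 um punctum spans about 4.5 pixels.
#'
#' @param pixel_size Pixel size in um/pixel; must be > 0.
#' @param field_shape Integer vector `c(rows, cols)` of the field in pixels.
#' @param channel_roles Named integer vector assigning each of the roles
#'   `cell_marker`, `adaptor`, `autophagosome` to a distinct channel index.
#' @param psf_sigma Gaussian point-spread standard deviation in um, applied to
#'   puncta and soma edges.
#' @param background_level Ambient background intensity per channel (length 1
#'   or one per channel).
#' @param photon_noise_scale Scale of the Poisson (shot) noise component;
#'   0 disables it. Pixel values are drawn as
#'   `rpois(value / scale) * scale`, so smaller scales mean less noise.
#' @param read_noise_sigma Standard deviation of additive Gaussian read noise
#'   in intensity units; 0 disables it.
#' @param bit_depth Output bit depth; pixels are rounded and clamped to
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(pixel_size = 0.11,
                               field_shape = c(500L, 500L),
                               channel_roles = c(cell_marker = 1L, adaptor = 2L,
                                                 autophagosome = 3L),
                               psf_sigma = 0.1,
                               background_level = c(4, 6, 6),
                               photon_noise_scale = 1,
                               read_noise_sigma = 1.5,
                               bit_depth = 12L) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single value > 0")
  if (length(field_shape) != 2L || any(field_shape < 8))
    stop("field_shape must be c(rows, cols) with both >= 8")
  roles <- c("cell_marker", "adaptor", "autophagosome")
  if (!all(roles %in% names(channel_roles)))
    stop("channel_roles must assign all of: ", paste(roles, collapse = ", "))
  idx <- as.integer(channel_roles[roles])
  if (anyDuplicated(idx) || any(idx < 1L))
    stop("channel_roles must map the three roles to distinct channel indices")
  if (psf_sigma < 0 || photon_noise_scale < 0 || read_noise_sigma < 0)
    stop("psf_sigma and noise parameters must be >= 0")
  n_ch <- max(idx)
  bg <- rep_len(background_level, n_ch)
  structure(list(
    pixel_size = pixel_size,
    field_shape = as.integer(field_shape),
    channel_roles = stats::setNames(idx, roles),
    n_channels = n_ch,
    psf_sigma = psf_sigma,
    background_level = bg,
    photon_noise_scale = photon_noise_scale,
    read_noise_sigma = read_noise_sigma,
    bit_depth = as.integer(bit_depth)
  ), class = "acquisition_config")
}

#' Lay out non-overlapping somata on a grid
#'
#' Places up to `n` cells of a common soma radius on a regular grid inside the
#' field, leaving a margin so that blurred soma edges stay inside the image.
#' Somata never overlap by construction, which keeps downstream ROI
#' assignment unambiguous.
#'
#' @param n Number of cells requested.
#' @param config An [acquisition_config()].
#' @param soma_radius Soma radius in um.
#' @param gap Minimum clearance between soma rims in um.
#' @param cytoplasm Named numeric vector of per-role cytoplasmic intensities
#'   (names among `cell_marker`, `adaptor`, `autophagosome`).
#' @return A data frame of cell specifications (`cell_id`, `x_um`, `y_um`,
#'   `soma_radius_um`, one `cyt_<role>` column per role). Errors if fewer than
#'   `n` positions fit.
#' @export
layout_cells <- function(n, config, soma_radius = 12,
                         gap = 2,
                         cytoplasm = c(cell_marker = 100, adaptor = 120,
                                       autophagosome = 110)) {
  ps <- config$pixel_size
  fld_um <- config$field_shape * ps            # (rows -> y extent, cols -> x)
  margin <- soma_radius + 4 * config$psf_sigma + 2 * ps
  spacing <- 2 * soma_radius + gap
  ny <- floor((fld_um[1] - 2 * margin) / spacing) + 1
  nx <- floor((fld_um[2] - 2 * margin) / spacing) + 1
  if (ny < 1 || nx < 1 || ny * nx < n)
    stop("field of ", fld_um[1], " x ", fld_um[2], " um fits at most ",
         max(0, ny * nx), " somata of radius ", soma_radius, " um; ", n,
         " requested")
  g <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))[seq_len(n), , drop = FALSE]
  out <- data.frame(
    cell_id = seq_len(n),
    x_um = margin + (g$ix - 1) * spacing,
    y_um = margin + (g$iy - 1) * spacing,
    soma_radius_um = soma_radius
  )
  for (role in names(config$channel_roles))
    out[[paste0("cyt_", role)]] <- unname(cytoplasm[role])
  out
}

# number of grid positions available per field for a given soma radius
cells_per_field <- function(config, soma_radius, gap = 2) {
  ps <- config$pixel_size
  fld_um <- config$field_shape * ps
  margin <- soma_radius + 4 * config$psf_sigma + 2 * ps
  spacing <- 2 * soma_radius + gap
  ny <- floor((fld_um[1] - 2 * margin) / spacing) + 1
  nx <- floor((fld_um[2] - 2 * margin) / spacing) + 1
  max(0L, as.integer(ny) * as.integer(nx))
}

#' Render a synthetic multi-channel field
#'
#' Renders cells and puncta into a multi-channel image. Each soma is a disk of
#' cytoplasmic intensity whose edge carries the Gaussian point-spread blur;
#' each punctum is an isotropic Gaussian spot whose full width at half maximum
#' equals its stated diameter, with the point-spread blur folded in
#' analytically (the blur of a Gaussian spot is again Gaussian, with summed
#' variances). Poisson-scaled noise and Gaussian read noise are then applied
#' and the image is quantized to the configured bit depth. Identical inputs
#' and seed reproduce the output bit for bit.
#'
#' @param config An [acquisition_config()].
#' @param cells Cell specification data frame as from [layout_cells()].
#' @param puncta Ground-truth puncta data frame with columns `punctum_id`,
#'   `cell_id`, `channel` (one of `adaptor`, `autophagosome`, `both`),
#'   `x_um`, `y_um`, `diameter_um`, `amp_adaptor`, `amp_autophagosome`.
#'   `channel = "both"` encodes one physical colocalized punctum rendered in
#'   both channels. May have zero rows.
#' @param seed Integer seed for the noise stream.
#' @return A list of class `synthetic_field` with elements `image` (a
#'   rows x cols x channels array), `truth` (list with `cells` and `puncta`,
#'   returned unmodified), and `provenance`.
#' @export
generate_field <- function(config, cells, puncta, seed = 1L) {
  stopifnot(inherits(config, "acquisition_config"))
  ps <- config$pixel_size
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  if (nrow(puncta) > 0) {
    bad <- !(puncta$cell_id %in% cells$cell_id)
    if (any(bad))
      stop("puncta reference undeclared cells: punctum_id ",
           paste(puncta$punctum_id[bad], collapse = ", "))
    i <- match(puncta$cell_id, cells$cell_id)
    d2 <- (puncta$x_um - cells$x_um[i])^2 + (puncta$y_um - cells$y_um[i])^2
    out <- d2 > cells$soma_radius_um[i]^2
    if (any(out))
      stop("punctum centre outside its soma: punctum_id ",
           paste(puncta$punctum_id[out], collapse = ", "))
  }
  if (nrow(cells) > 0) {
    fits <- cells$x_um - cells$soma_radius_um >= 0 &
      cells$y_um - cells$soma_radius_um >= 0 &
      cells$x_um + cells$soma_radius_um <= nc * ps &
      cells$y_um + cells$soma_radius_um <= nr * ps
    if (!all(fits))
      stop("somata extend outside the field: cell_id ",
           paste(cells$cell_id[!fits], collapse = ", "))
  }

  psf_px <- config$psf_sigma / ps
  img <- array(0, dim = c(nr, nc, config$n_channels))
  for (ch in seq_len(config$n_channels)) img[, , ch] <- config$background_level[ch]

  # somata: radial profile cyt * Phi((R - r)/psf), the Gaussian-blurred edge
  # of a disk in the large-radius limit (crisp disk when psf = 0)
  for (k in seq_len(nrow(cells))) {
    cr <- cells$y_um[k] / ps + 0.5; cc <- cells$x_um[k] / ps + 0.5
    R_px <- cells$soma_radius_um[k] / ps
    halo <- ceiling(R_px + 4 * psf_px + 1)
    rows <- max(1, floor(cr - halo)):min(nr, ceiling(cr + halo))
    cols <- max(1, floor(cc - halo)):min(nc, ceiling(cc + halo))
    rr <- sqrt(outer((rows - cr)^2, (cols - cc)^2, "+"))
    prof <- if (psf_px > 0) stats::pnorm((R_px - rr) / psf_px) else (rr <= R_px) * 1
    for (role in names(config$channel_roles)) {
      ch <- config$channel_roles[[role]]
      cyt <- cells[[paste0("cyt_", role)]][k]
      if (cyt != 0) img[rows, cols, ch] <- img[rows, cols, ch] + cyt * prof
    }
  }

  # puncta: Gaussian spots, FWHM = diameter, psf folded analytically
  ch_a <- config$channel_roles[["adaptor"]]
  ch_l <- config$channel_roles[["autophagosome"]]
  if (nrow(puncta) > 0) {
    for (k in seq_len(nrow(puncta))) {
      s0 <- puncta$diameter_um[k] / (2 * sqrt(2 * log(2))) / ps
      se <- sqrt(s0^2 + psf_px^2)
      cr <- puncta$y_um[k] / ps + 0.5; cc <- puncta$x_um[k] / ps + 0.5
      halo <- ceiling(4.5 * se + 1)
      rows <- max(1, floor(cr - halo)):min(nr, ceiling(cr + halo))
      cols <- max(1, floor(cc - halo)):min(nc, ceiling(cc + halo))
      g <- exp(-outer((rows - cr)^2, (cols - cc)^2, "+") / (2 * se^2)) *
        (s0^2 / se^2)
      chan <- puncta$channel[k]
      if (chan %in% c("adaptor", "both"))
        img[rows, cols, ch_a] <- img[rows, cols, ch_a] + puncta$amp_adaptor[k] * g
      if (chan %in% c("autophagosome", "both"))
        img[rows, cols, ch_l] <- img[rows, cols, ch_l] + puncta$amp_autophagosome[k] * g
    }
  }

  set.seed(seed)
  s <- config$photon_noise_scale
  if (s > 0) {
    lam <- pmax(img, 0) / s
    img[] <- stats::rpois(length(lam), lam) * s
  }
  if (config$read_noise_sigma > 0)
    img[] <- img + stats::rnorm(length(img), 0, config$read_noise_sigma)
  img[] <- pmin(pmax(round(img), 0), 2^config$bit_depth - 1)

  structure(list(
    image = img,
    truth = list(cells = cells, puncta = puncta),
    provenance = list(seed = seed,
                      seed_rule = "field seed = (base*48271 + 99991*index) mod (2^31-1)",
                      pixel_size = ps)
  ), class = "synthetic_field")
}

#' Cohort design for synthetic group comparisons
#'
#' Defines the study conditions for a simulated cohort: ordered group labels
#' with the control first, cells per group, baseline expression / puncta rates
#' / colocalized fraction, and per-group multiplicative effects on each
#' baseline element. The colocalized fraction is the fraction of adaptor
#' puncta that are also autophagosome-positive; autophagosome-only puncta are
#' added so that the total autophagosome rate meets its target.
#'
#' Baseline defaults put roughly 30 adaptor and 20 autophagosome puncta per
#' cell with 40% of adaptor puncta colocalized, so that the control percent
#' colocalized is about 40% on the adaptor side and 60% on the autophagosome
#' side, the order observed in brainstem neurons.
#'
#' @param groups Ordered character vector of group labels, control first.
#' @param cells_per_group Number of cells per group (>= 1).
#' @param baseline Named list with `expression_adaptor`,
#'   `expression_autophagosome` (cytoplasmic intensities),
#'   `puncta_rate_adaptor`, `puncta_rate_autophagosome` (mean puncta/cell),
#'   and `coloc_fraction` (in `[0, 1]`).
#' @param multipliers Named list (one entry per non-control group is enough)
#'   of lists with elements among `expression_adaptor`,
#'   `expression_autophagosome`, `rate_adaptor`, `rate_autophagosome`,
#'   `coloc_fraction`; missing elements default to 1. Control multipliers are
#'   fixed at 1.
#' @param soma_radius Soma radius in um.
#' @param soma_gap Minimum clearance between soma rims in um.
#' @param diameter_dist Punctum diameter distribution: a scaled Beta law,
#'   `list(shape1, shape2, min, max)` on a bounded support in um.
#' @param amp_mean,amp_sdlog Mean and log-sd of the log-normal punctum
#'   amplitude law (intensity units above local background).
#' @param expression_cv Log-sd of per-cell log-normal variation in
#'   cytoplasmic expression.
#' @param marker_intensity Cytoplasmic intensity of the cell-marker channel.
#' @param region Region label attached to all cells (metadata only).
#' @param seed Integer base seed; each field derives its own stream from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("control", "24h", "5d", "end_stage"),
                          cells_per_group = 100L,
                          baseline = list(expression_adaptor = 120,
                                          expression_autophagosome = 110,
                                          puncta_rate_adaptor = 30,
                                          puncta_rate_autophagosome = 20,
                                          coloc_fraction = 0.4),
                          multipliers = list(),
                          soma_radius = 12,
                          soma_gap = 2,
                          diameter_dist = list(shape1 = 2.5, shape2 = 3.5,
                                               min = 0.5, max = 2.0),
                          amp_mean = 150, amp_sdlog = 0.25,
                          expression_cv = 0.15,
                          marker_intensity = 100,
                          region = "R1",
                          seed = 1L) {
  if (length(groups) < 1 || anyDuplicated(groups))
    stop("groups must be distinct labels with the control first")
  if (cells_per_group < 1) stop("cells_per_group must be >= 1")
  if (baseline$coloc_fraction < 0 || baseline$coloc_fraction > 1)
    stop("baseline coloc_fraction must be in [0, 1]")
  if (diameter_dist$min < 0.3 - 1e-9 || diameter_dist$max > 2.5 + 1e-9 ||
      diameter_dist$min >= diameter_dist$max)
    stop("diameter_dist support must lie within [0.3, 2.5] um")
  full <- lapply(stats::setNames(groups, groups), function(g) {
    m <- multipliers[[g]] %||% list()
    out <- list(expression_adaptor = 1, expression_autophagosome = 1,
                rate_adaptor = 1, rate_autophagosome = 1, coloc_fraction = 1)
    out[names(m)] <- m
    out
  })
  if (any(unlist(full[[groups[1]]]) != 1))
    stop("control group multipliers must all equal 1")
  if (any(unlist(full) <= 0)) stop("multipliers must be > 0")
  structure(list(groups = groups, cells_per_group = as.integer(cells_per_group),
                 baseline = baseline, multipliers = full,
                 soma_radius = soma_radius, soma_gap = soma_gap,
                 diameter_dist = diameter_dist,
                 amp_mean = amp_mean, amp_sdlog = amp_sdlog,
                 expression_cv = expression_cv,
                 marker_intensity = marker_intensity,
                 region = region, seed = as.integer(seed)),
            class = "cohort_design")
}

# draw punctum diameters from the design's scaled Beta law
draw_diameters <- function(n, dd) {
  dd$min + (dd$max - dd$min) * stats::rbeta(n, dd$shape1, dd$shape2)
}

#' Simulate a cohort of synthetic fields
#'
#' Realizes a [cohort_design()] into rendered fields plus flat ground-truth
#' tables. Per cell, the adaptor punctum count is Poisson with the group's
#' effective adaptor rate; colocalized puncta are a binomial thinning of the
#' adaptor puncta at the effective colocalized fraction (rendered in both
#' channels as `channel = "both"`), and autophagosome-only puncta are Poisson
#' with rate `max(rate_autophagosome - rate_adaptor * coloc_fraction, 0)` so
#' the total autophagosome rate meets its target. Deterministic under a fixed
#' design seed; each field uses its own derived RNG stream.
#'
#' @param design A [cohort_design()].
#' @param config An [acquisition_config()].
#' @return A list with `fields` (list of `synthetic_field`s, each annotated
#'   with `field_id`, `group`, `region`), `truth_cells` and `truth_puncta`
#'   (flat data frames keyed by `field_id`), and `design`.
#' @export
generate_cohort <- function(design, config) {
  stopifnot(inherits(design, "cohort_design"), inherits(config, "acquisition_config"))
  npf <- cells_per_field(config, design$soma_radius, gap = design$soma_gap %||% 2)
  if (npf < 1)
    stop("field_shape too small for soma_radius ", design$soma_radius, " um")
  fields <- list(); truth_cells <- list(); truth_puncta <- list()
  field_idx <- 0L
  roles <- names(config$channel_roles)
  for (g in design$groups) {
    mult <- design$multipliers[[g]]
    b <- design$baseline
    rate_a <- b$puncta_rate_adaptor * mult$rate_adaptor
    rate_l <- b$puncta_rate_autophagosome * mult$rate_autophagosome
    f_eff <- min(1, max(0, b$coloc_fraction * mult$coloc_fraction))
    expr_a <- b$expression_adaptor * mult$expression_adaptor
    expr_l <- b$expression_autophagosome * mult$expression_autophagosome
    remaining <- design$cells_per_group
    cell_offset <- 0L
    while (remaining > 0) {
      field_idx <- field_idx + 1L
      n_here <- min(npf, remaining)
      scene_seed <- derive_seed(design$seed, 2L * field_idx - 1L)
      noise_seed <- derive_seed(design$seed, 2L * field_idx)
      set.seed(scene_seed)
      cells <- layout_cells(n_here, config, soma_radius = design$soma_radius,
                            gap = design$soma_gap %||% 2,
                            cytoplasm = stats::setNames(rep(0, 3), roles))
      cells$cyt_cell_marker <- design$marker_intensity *
        stats::rlnorm(n_here, -design$expression_cv^2 / 2, design$expression_cv)
      cells$cyt_adaptor <- expr_a *
        stats::rlnorm(n_here, -design$expression_cv^2 / 2, design$expression_cv)
      cells$cyt_autophagosome <- expr_l *
        stats::rlnorm(n_here, -design$expression_cv^2 / 2, design$expression_cv)

      pl <- vector("list", n_here)
      for (k in seq_len(n_here)) {
        A <- stats::rpois(1, rate_a)
        C <- stats::rbinom(1, A, f_eff)
        B <- stats::rpois(1, max(rate_l - rate_a * f_eff, 0))
        n_p <- A + B
        if (n_p == 0) next
        chan <- c(rep("both", C), rep("adaptor", A - C), rep("autophagosome", B))
        d <- draw_diameters(n_p, design$diameter_dist)
        # hard-core placement: puncta are solid vesicles, so centres keep at
        # least the sum of their radii apart (rejection sampling with
        # graceful degradation under extreme crowding)
        px <- numeric(n_p); py <- numeric(n_p)
        for (q in seq_len(n_p)) {
          rmax <- max(cells$soma_radius_um[k] - d[q] / 2, 0.1)
          for (try in 1:40) {
            rad <- rmax * sqrt(stats::runif(1))
            th <- stats::runif(1, 0, 2 * pi)
            xq <- cells$x_um[k] + rad * cos(th)
            yq <- cells$y_um[k] + rad * sin(th)
            if (q == 1) break
            sep2 <- (px[1:(q - 1)] - xq)^2 + (py[1:(q - 1)] - yq)^2
            lim <- 0.5 * (d[1:(q - 1)] + d[q])
            if (all(sep2 >= lim^2)) break
          }
          px[q] <- xq; py[q] <- yq
        }
        pl[[k]] <- data.frame(
          cell_id = cells$cell_id[k], channel = chan,
          x_um = px,
          y_um = py,
          diameter_um = d,
          amp_adaptor = stats::rlnorm(n_p, log(design$amp_mean) -
                                        design$amp_sdlog^2 / 2, design$amp_sdlog),
          amp_autophagosome = stats::rlnorm(n_p, log(design$amp_mean) -
                                              design$amp_sdlog^2 / 2, design$amp_sdlog)
        )
      }
      puncta <- do.call(rbind, pl)
      if (is.null(puncta))
        puncta <- data.frame(cell_id = integer(), channel = character(),
                             x_um = numeric(), y_um = numeric(),
                             diameter_um = numeric(), amp_adaptor = numeric(),
                             amp_autophagosome = numeric())
      puncta$punctum_id <- seq_len(nrow(puncta))

      fld <- generate_field(config, cells, puncta, seed = noise_seed)
      fld$field_id <- field_idx
      fld$group <- g
      fld$region <- design$region
      fields[[field_idx]] <- fld

      tc <- cells
      tc$cell_in_field <- tc$cell_id                 # id within this field
      tc$cell_id <- tc$cell_id + cell_offset         # group-unique cell ids
      tc <- cbind(field_id = field_idx, group = g, region = design$region, tc)
      truth_cells[[field_idx]] <- tc
      if (nrow(puncta) > 0) {
        tp <- puncta
        tp$cell_in_field <- tp$cell_id
        tp$cell_id <- tp$cell_id + cell_offset
        truth_puncta[[field_idx]] <- cbind(field_id = field_idx, group = g,
                                           region = design$region, tp)
      }
      cell_offset <- cell_offset + n_here
      remaining <- remaining - n_here
    }
  }
  list(fields = fields,
       truth_cells = do.call(rbind, truth_cells),
       truth_puncta = if (length(truth_puncta)) do.call(rbind, truth_puncta) else NULL,
       design = design)
}

# Dysfunction scenario multipliers. Each row realizes one decision-table
# category as multiplicative effects on the generator baselines; the derived
# endpoints then satisfy the category's expected direction pattern (the
# percent-colocalized ratios are coupled to the rates, so the
# "induced-flux-unimpaired" row necessarily depresses the autophagosome-side
# percentage; see the methods vignette).
scenario_table <- function() {
  m <- rbind(
    `induced-flux-unimpaired`          = c(1.50, 0.65, 1.6, 1.0, 1.00),
    `impaired-induction`               = c(0.65, 0.70, 0.5, 1.0, 0.50),
    `impaired-interaction`             = c(0.65, 1.50, 1.0, 1.7, 0.45),
    `failed-fusion`                    = c(1.50, 1.50, 1.7, 1.7, 1.50),
    `optn-failure-exhaustion`          = c(1.00, 0.60, 1.0, 0.45, 1.50),
    `autophagosome-failure-exhaustion` = c(0.65, 1.50, 0.5, 1.5, 0.50)
  )
  colnames(m) <- c("expression_autophagosome", "expression_adaptor",
                   "rate_autophagosome", "rate_adaptor", "coloc_fraction")
  m
}

#' Derive a cohort design realizing a dysfunction category
#'
#' Maps one of the six decision-table dysfunction categories to multiplier
#' settings on a base design: every non-control group receives the category's
#' multiplicative effects on expression, puncta rates, and colocalized
#' fraction, while the control stays at baseline. Simulating the returned
#' design and running the full pipeline at adequate effect size and cell
#' count yields direction calls matching that category's template.
#'
#' @param category One of `induced-flux-unimpaired`, `impaired-induction`,
#'   `impaired-interaction`, `failed-fusion`, `optn-failure-exhaustion`,
#'   `autophagosome-failure-exhaustion`.
#' @param base A [cohort_design()] supplying groups, baselines and seed.
#' @param strength Effect-size exponent applied to every multiplier (1 =
#'   the built-in large effects; < 1 attenuates them).
#' @return A `cohort_design` with the category's multipliers installed for
#'   all non-control groups.
#' @export
scenario_from_category <- function(category, base = cohort_design(), strength = 1) {
  tab <- scenario_table()
  if (!category %in% rownames(tab))
    stop("unknown dysfunction category: ", category,
         " (expected one of: ", paste(rownames(tab), collapse = ", "), ")")
  eff <- tab[category, ]^strength
  mult <- list()
  for (g in base$groups[-1]) {
    mult[[g]] <- as.list(eff)
  }
  base$multipliers <- lapply(stats::setNames(base$groups, base$groups), function(g) {
    m <- mult[[g]] %||% list()
    out <- list(expression_adaptor = 1, expression_autophagosome = 1,
                rate_adaptor = 1, rate_autophagosome = 1, coloc_fraction = 1)
    out[names(m)] <- m
    out
  })
  base
}
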