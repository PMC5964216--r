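# Shared small synthetic scenes, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# noise-free acquisition for exactness checks
quiet_config <- function(pixel_size = 0.11, field_shape = c(300L, 300L),
                         psf_sigma = 0.1) {
  acquisition_config(pixel_size = pixel_size, field_shape = field_shape,
                     psf_sigma = psf_sigma, background_level = c(4, 6, 6),
                     photon_noise_scale = 0, read_noise_sigma = 0)
}

# one quiet field: 4 somata of 10 um, 10 well-separated adaptor puncta in cell 1
quiet_field <- function() {
  if (!is.null(.fixtures$quiet)) return(.fixtures$quiet)
  cfg <- quiet_config(field_shape = c(420L, 420L))
  cells <- layout_cells(4, cfg, soma_radius = 10)
  set.seed(101)
  # spots on a small grid inside cell 1, spaced >= 3 um; sub-pixel offsets
  # avoid symmetric placement exactly between pixel centres
  g <- expand.grid(dx = c(-6, -2, 2, 6), dy = c(-6, -2, 2))[1:10, ]
  p <- data.frame(punctum_id = 1:10, cell_id = 1, channel = "adaptor",
                  x_um = cells$x_um[1] + g$dx + 0.037,
                  y_um = cells$y_um[1] + g$dy + 0.021,
                  diameter_um = 1.0, amp_adaptor = 60, amp_autophagosome = 0)
  .fixtures$quiet <- list(config = cfg, cells = cells, puncta = p,
                          field = generate_field(cfg, cells, p, seed = 7))
  .fixtures$quiet
}

# small noisy cohort at default conditions (8 cells, 12 um somata)
small_cohort <- function() {
  if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
  cfg <- acquisition_config(field_shape = c(260L, 500L))
  des <- cohort_design(groups = "control", cells_per_group = 8,
                       soma_radius = 12, seed = 5)
  .fixtures$cohort <- list(config = cfg, design = des,
                           cohort = generate_cohort(des, cfg))
  .fixtures$cohort
}
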