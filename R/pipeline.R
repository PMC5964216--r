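#' Write a synthetic field to disk
#'
#' One multi-page TIFF per field (one page per channel, 16-bit), a sidecar
#' ground-truth CSV, and a JSON provenance record (seed, pixel size, seed
#' derivation rule).
#'
#' @param field A `synthetic_field`.
#' @param dir Output directory (created if needed).
#' @param basename File stem; defaults to `field_<id>`.
#' @param bit_depth Bit depth used for TIFF scaling (defaults to 16).
#' @return Invisibly, the paths written.
#' @export
write_field <- function(field, dir, basename = NULL, bit_depth = 16L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  basename <- basename %||% sprintf("field_%03d", field$field_id %||% 0L)
  tif <- file.path(dir, paste0(basename, ".tif"))
  img <- field$image / (2^bit_depth - 1)
  img[img > 1] <- 1
  EBImage::writeImage(EBImage::Image(img), tif, type = "tiff",
                      bits.per.sample = 16L)
  truth_csv <- file.path(dir, paste0(basename, "_truth.csv"))
  tp <- field$truth$puncta
  truth <- data.frame(field = basename,
                      cell_id = tp$cell_id, punctum_id = tp$punctum_id,
                      channel = tp$channel, x_um = tp$x_um, y_um = tp$y_um,
                      diameter_um = tp$diameter_um)
  utils::write.csv(truth, truth_csv, row.names = FALSE)
  prov <- file.path(dir, paste0(basename, "_provenance.json"))
  jsonlite::write_json(field$provenance, prov, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, truth_csv, prov))
}

#' Read a multi-page TIFF field
#'
#' @param path TIFF path (one page per channel).
#' @param bit_depth Bit depth for rescaling intensities back to counts.
#' @return A rows x cols x channels numeric array.
#' @export
read_field_tiff <- function(path, bit_depth = 16L) {
  img <- EBImage::readImage(path)
  arr <- as.array(EBImage::imageData(img))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  arr * (2^bit_depth - 1)
}

#' Assemble a pipeline run configuration
#'
#' Exactly one input source: a [cohort_design()] for simulation, or a
#' directory of multi-page TIFFs plus a metadata table (columns `file`,
#' `region`, `group`, `pixel_size_um`).
#'
#' @param design Optional [cohort_design()] (simulation mode).
#' @param input_dir,metadata Optional image-directory mode.
#' @param config An [acquisition_config()] (channel roles, pixel size).
#' @param detection A [detection_config()].
#' @param matching A [match_config()].
#' @param alpha Significance level for the statistics.
#' @param control_label Control group label.
#' @param min_area Minimum ROI area (um^2).
#' @param out_dir Output directory for tables and the manifest.
#' @param seed Integer seed governing all randomness in simulation mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = NULL, input_dir = NULL, metadata = NULL,
                       config = acquisition_config(),
                       detection = detection_config(),
                       matching = match_config(),
                       alpha = 0.05, control_label = "control",
                       min_area = 20, out_dir = tempfile("punctaflux_run_"),
                       seed = 1L) {
  if (is.null(design) == is.null(input_dir))
    stop("exactly one input source required: design, or input_dir + metadata")
  structure(list(design = design, input_dir = input_dir, metadata = metadata,
                 config = config, detection = detection, matching = matching,
                 alpha = alpha, control_label = control_label,
                 min_area = min_area, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration without computing anything
#'
#' Reports missing files, metadata rows referencing absent images, channel
#' role gaps, and absent pixel size or control group. Never mutates state.
#'
#' @param rc A [run_config()].
#' @return Data frame of findings (`severity`, `message`); empty when the
#'   configuration is complete.
#' @export
validate_inputs <- function(rc) {
  findings <- list()
  add <- function(sev, msg) findings[[length(findings) + 1L]] <<-
    data.frame(severity = sev, message = msg)
  roles <- c("cell_marker", "adaptor", "autophagosome")
  missing_roles <- setdiff(roles, names(rc$config$channel_roles))
  if (length(missing_roles))
    add("error", paste("channel roles not assigned:",
                       paste(missing_roles, collapse = ", ")))
  if (is.null(rc$config$pixel_size) || !is.finite(rc$config$pixel_size) ||
      rc$config$pixel_size <= 0)
    add("error", "pixel size missing or invalid")
  if (!is.null(rc$design)) {
    if (!rc$control_label %in% rc$design$groups)
      add("error", paste0("control group '", rc$control_label,
                          "' absent from the design groups"))
  } else {
    md <- rc$metadata
    if (is.character(md) && length(md) == 1) {
      if (!file.exists(md)) {
        add("error", paste("metadata file not found:", md))
        md <- NULL
      } else md <- utils::read.csv(md, stringsAsFactors = FALSE)
    }
    if (is.null(md)) {
      add("error", "metadata table required in image-directory mode")
    } else {
      need <- c("file", "region", "group")
      miss <- setdiff(need, names(md))
      if (length(miss))
        add("error", paste("metadata lacks columns:", paste(miss, collapse = ", ")))
      else {
        for (f in md$file) {
          p <- file.path(rc$input_dir, f)
          if (!file.exists(p)) add("error", paste("image file not found:", f))
        }
        if (!rc$control_label %in% md$group)
          add("error", paste0("control group '", rc$control_label,
                              "' absent from metadata"))
        if (!"pixel_size_um" %in% names(md) &&
            (is.null(rc$config$pixel_size) || rc$config$pixel_size <= 0))
          add("error", "no pixel size in metadata or configuration")
      }
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), message = character())
}

# deterministic CSV writer (fixed significant digits, no row names)
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full assessment pipeline
#'
#' Orchestrates simulate (or load) -> segment -> detect -> colocalize ->
#' quantify -> test -> classify, writes every stage table as CSV plus a JSON
#' run manifest, and returns the results. All randomness derives from the
#' run seed, and re-running an identical configuration reproduces
#' byte-identical CSV outputs.
#'
#' @param rc A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list: `measurements`, `summaries`, `calls`,
#'   `patterns`, `verdict` (the region x stage matrix), and `manifest`.
#' @export
run_pipeline <- function(rc, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  v <- validate_inputs(rc)
  if (any(v$severity == "error"))
    stop("invalid run configuration:\n  ",
         paste(v$message[v$severity == "error"], collapse = "\n  "))
  if (!dir.exists(rc$out_dir)) dir.create(rc$out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  log <- function(...) {
    msg <- paste0(...)
    say(msg)
    log_lines <<- c(log_lines, msg)
  }

  # stage 1: inputs
  if (!is.null(rc$design)) {
    design <- rc$design
    design$seed <- rc$seed
    log("simulate: ", length(design$groups), " groups x ",
        design$cells_per_group, " cells (seed ", rc$seed, ")")
    cohort <- generate_cohort(design, rc$config)
    fields <- cohort$fields
  } else {
    md <- rc$metadata
    if (is.character(md)) md <- utils::read.csv(md, stringsAsFactors = FALSE)
    fields <- lapply(seq_len(nrow(md)), function(i) {
      arr <- read_field_tiff(file.path(rc$input_dir, md$file[i]))
      list(image = arr, field_id = i, group = md$group[i], region = md$region[i])
    })
    log("load: ", length(fields), " fields from ", rc$input_dir)
  }

  # stage 2: per-field measurement
  meas_l <- list(); punc_l <- list()
  for (i in seq_along(fields)) {
    mf <- measure_field(fields[[i]], rc$config, rc$detection, rc$matching,
                        min_area = rc$min_area)
    meas_l[[i]] <- mf$cells
    punc_l[[i]] <- mf$puncta
  }
  meas <- do.call(rbind, meas_l)
  puncta <- do.call(rbind, punc_l)
  log("measure: ", nrow(meas), " cells, ", nrow(puncta),
      " detected puncta across ", length(fields), " fields")
  meas_path <- write_table(meas, file.path(rc$out_dir, "cell_measurements.csv"))
  punc_path <- write_table(puncta, file.path(rc$out_dir, "puncta.csv"))

  # stage 3: summaries relative to control
  eps <- endpoint_table()
  summ <- do.call(rbind, lapply(eps$column, function(cl)
    summarize_group(meas, cl)))
  summ <- normalize_to_control(summ, rc$control_label)
  summ_path <- write_table(summ, file.path(rc$out_dir, "group_summaries.csv"))

  # stage 4: statistics and change calls per region
  regions <- unique(meas$region)
  calls <- list(); stats_rows <- list()
  for (r in regions) {
    bat <- endpoint_battery(meas[meas$region == r, ], rc$control_label, rc$alpha)
    calls[[r]] <- bat$calls
    stats_rows[[r]] <- bat$calls
  }
  calls <- do.call(rbind, calls)
  stats_path <- write_table(calls, file.path(rc$out_dir, "endpoint_stats.csv"))
  log("stats: ", nrow(calls), " group x endpoint comparisons")

  # stage 5: classification per region x stage
  templates <- builtin_templates()
  results <- list(); patterns <- list()
  for (r in regions) {
    cr <- calls[calls$region == r, ]
    for (g in setdiff(unique(cr$group), rc$control_label)) {
      pat <- direction_pattern(cr, g)
      cls <- classify(pat, templates)
      key <- paste(r, g, sep = ":")
      patterns[[key]] <- pat
      results[[key]] <- list(region = r, stage = g, classification = cls)
    }
  }
  verdict <- summarize_matrix(results)
  verdict_path <- write_table(verdict$matched,
                              file.path(rc$out_dir, "verdict_matched.csv"))
  marks_path <- write_table(verdict$marks,
                            file.path(rc$out_dir, "verdict_matrix.csv"))
  writeLines(verdict$text, file.path(rc$out_dir, "verdict_matrix.txt"))
  log("classify: ", length(results), " region x stage verdicts")

  outputs <- c(meas_path, punc_path, summ_path, stats_path, verdict_path,
               marks_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("punctaflux")),
    seed = rc$seed,
    control_label = rc$control_label,
    alpha = rc$alpha,
    detection = unclass(rc$detection),
    matching = unclass(rc$matching),
    acquisition = unclass(rc$config)[c("pixel_size", "field_shape", "psf_sigma",
                                       "background_level", "photon_noise_scale",
                                       "read_noise_sigma", "bit_depth")],
    stage_counts = list(fields = length(fields), cells = nrow(meas),
                        puncta = nrow(puncta),
                        comparisons = nrow(calls), verdicts = length(results)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(rc$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(measurements = meas, summaries = summ, calls = calls,
                 patterns = patterns, verdict = verdict, manifest = manifest))
}
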