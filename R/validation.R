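#' Standard end-to-end validation conditions
#'
#' The fixed problem size used for end-to-end scenario-recovery validation:
#' a 51 x 51 um field at 0.165 um/pixel holding 25 somata of 4.5 um radius,
#' with 9 adaptor and 6 autophagosome puncta per cell at a 40% colocalized
#' fraction, 100 cells per group across the four stages. These conditions
#' are deliberately smaller than the package defaults so a full six-category
#' recovery study runs in minutes; the detection configuration drops to
#' three scales accordingly.
#'
#' @param cells_per_group Cells per group (default 100).
#' @param seed Base seed for the design.
#' @return A list with `config` (an [acquisition_config()]), `design` (a
#'   [cohort_design()]), and `detection` (a [detection_config()]).
#' @export
scenario_conditions <- function(cells_per_group = 100L, seed = 1L) {
  config <- acquisition_config(pixel_size = 0.165,
                               field_shape = c(308L, 308L))
  design <- cohort_design(
    cells_per_group = cells_per_group,
    baseline = list(expression_adaptor = 120, expression_autophagosome = 110,
                    puncta_rate_adaptor = 9, puncta_rate_autophagosome = 6,
                    coloc_fraction = 0.4),
    soma_radius = 4.5, soma_gap = 1,
    seed = seed)
  list(config = config, design = design,
       detection = detection_config(n_scales = 3L))
}

#' Run one end-to-end scenario-recovery replicate
#'
#' Simulates a cohort realizing one dysfunction category under the standard
#' validation conditions, runs the full pipeline (segmentation, detection,
#' colocalization, statistics, classification), and reports whether the
#' intended category is matched in each treated stage.
#'
#' @param category A dysfunction category (see [scenario_from_category()]).
#' @param seed Integer seed for this replicate.
#' @param cells_per_group Cells per group.
#' @param out_dir Output directory (a temporary directory by default).
#' @return A list with `matched_stages` (character vector of treated stages
#'   where the intended category matched), `n_stages` (number of treated
#'   stages), `full_blocks` (mean number of full blocks for the intended
#'   category across treated stages), and the pipeline `result`.
#' @export
run_scenario <- function(category, seed, cells_per_group = 100L,
                         out_dir = tempfile("scenario_")) {
  sc <- scenario_conditions(cells_per_group = cells_per_group, seed = seed)
  des <- scenario_from_category(category, sc$design)
  rc <- run_config(design = des, config = sc$config, detection = sc$detection,
                   out_dir = out_dir, seed = seed)
  res <- run_pipeline(rc, quiet = TRUE)
  m <- res$verdict$matched
  mine <- m[m$category == category, ]
  marks <- res$verdict$marks
  stage_cols <- setdiff(names(marks), c("category", "block"))
  fullb <- mean(vapply(stage_cols, function(cl)
    sum(marks[[cl]][marks$category == category] == "X"), numeric(1)))
  list(matched_stages = mine$stage[mine$matched],
       n_stages = nrow(mine),
       full_blocks = fullb,
       result = res)
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Pairs detected and true puncta by ascending centroid distance with each
#' object used at most once, at a fixed matching radius.
#'
#' @param detected,truth Data frames with `x_um`, `y_um`.
#' @param radius Matching radius in um (default 0.25).
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
match_to_truth <- function(detected, truth, radius = 0.25) {
  nd <- nrow(detected); nt <- nrow(truth)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    dm <- sqrt(outer(detected$x_um, truth$x_um, "-")^2 +
                 outer(detected$y_um, truth$y_um, "-")^2)
    ud <- logical(nd); ut <- logical(nt)
    for (o in order(dm)) {
      if (dm[o] > radius) break
      di <- (o - 1L) %% nd + 1L; ti <- (o - 1L) %/% nd + 1L
      if (!ud[di] && !ut[ti]) { tp <- tp + 1L; ud[di] <- ut[ti] <- TRUE }
    }
  }
  fp <- nd - tp; fn <- nt - tp
  prec <- if (nd > 0) tp / nd else 0
  rec <- if (nt > 0) tp / nt else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

#' Detection-recovery study on simulated fields
#'
#' Simulates fields of two 12-um somata at the default imaging and noise
#' conditions (about 60 adaptor and 40 autophagosome puncta per field),
#' detects puncta in both channels, and scores them against ground truth at
#' a 0.25 um matching radius.
#'
#' @param n_fields Number of fields.
#' @param seed Base seed.
#' @return A list with `pooled` (tp/fp/fn and pooled precision, recall, f1
#'   across all fields and channels) and `per_field` (data frame).
#' @export
detection_recovery <- function(n_fields = 20L, seed = 1L) {
  config <- acquisition_config(field_shape = c(260L, 500L))
  design <- cohort_design(groups = "control",
                          cells_per_group = 2L * n_fields,
                          soma_radius = 12, seed = seed)
  co <- generate_cohort(design, config)
  rows <- list(); TP <- FP <- FN <- 0L
  for (fi in seq_along(co$fields)) {
    for (chan in c("adaptor", "autophagosome")) {
      ch <- config$channel_roles[[chan]]
      det <- detect_puncta(co$fields[[fi]]$image[, , ch], config$pixel_size)
      tru <- co$truth_puncta[co$truth_puncta$field_id == fi &
                               co$truth_puncta$channel %in% c(chan, "both"), ]
      m <- match_to_truth(det, tru)
      TP <- TP + m$tp; FP <- FP + m$fp; FN <- FN + m$fn
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = fi, channel = chan, n_true = nrow(tru),
        n_detected = nrow(det), tp = m$tp,
        precision = m$precision, recall = m$recall, f1 = m$f1)
    }
  }
  prec <- TP / max(1, TP + FP); rec <- TP / max(1, TP + FN)
  list(pooled = list(tp = TP, fp = FP, fn = FN, precision = prec,
                     recall = rec, f1 = 2 * prec * rec / (prec + rec)),
       per_field = do.call(rbind, rows))
}

#' Colocalization-recovery study
#'
#' Simulates cohorts at several true colocalized fractions and recovers each
#' through the full measurement chain (segmentation, detection, one-to-one
#' matching), reporting the mean percent of adaptor puncta colocalized.
#'
#' @param fractions True colocalized fractions to simulate.
#' @param cells_per_condition Cells per condition (>= 100 recommended).
#' @param seed Base seed.
#' @return Data frame: `true_fraction`, `n_cells`, `mean_pct_adaptor_coloc`,
#'   `mean_pct_autophagosome_coloc`, `abs_error_points` (on the adaptor
#'   side, in percentage points).
#' @export
coloc_recovery <- function(fractions = c(0, 0.2, 0.4, 0.8),
                           cells_per_condition = 100L, seed = 1L) {
  config <- acquisition_config(field_shape = c(260L, 500L))
  out <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    design <- cohort_design(groups = "control",
                            cells_per_group = cells_per_condition,
                            baseline = list(expression_adaptor = 120,
                                            expression_autophagosome = 110,
                                            puncta_rate_adaptor = 30,
                                            puncta_rate_autophagosome = 20,
                                            coloc_fraction = f),
                            soma_radius = 12,
                            seed = seed + i)
    co <- generate_cohort(design, config)
    meas <- measure_cohort(co, config)
    pa <- meas$pct_adaptor_coloc[!is.na(meas$pct_adaptor_coloc)]
    pl <- meas$pct_autophagosome_coloc[!is.na(meas$pct_autophagosome_coloc)]
    out[[i]] <- data.frame(true_fraction = f, n_cells = nrow(meas),
                           mean_pct_adaptor_coloc = mean(pa),
                           mean_pct_autophagosome_coloc = mean(pl),
                           abs_error_points = abs(mean(pa) - 100 * f))
  }
  do.call(rbind, out)
}

# one synthetic per-cell endpoint sample: log-normal base, optional additive
# location shift (in units of the base standard deviation) for some groups
sample_endpoint_groups <- function(n, k = 4L, shift_groups = integer(0),
                                   shift_sd = 0) {
  base_sd <- sqrt((exp(0.25) - 1) * exp(0.25))      # sd of lognormal(0, 0.5)
  lapply(seq_len(k), function(g) {
    x <- stats::rlnorm(n, 0, 0.5)
    if (g %in% shift_groups) x <- x + shift_sd * base_sd
    x
  })
}

#' False-call calibration of the gated Dunn procedure under the null
#'
#' Simulates replicates of four groups drawn from one (skewed) distribution
#' and runs the full call procedure: Kruskal-Wallis gate at alpha, Dunn's
#' versus control with Bonferroni adjustment, signed calls. Reports the
#' fraction of replicates with at least one false `up`/`down` call.
#'
#' @param n_reps Number of replicates.
#' @param n_per_group Cells per group.
#' @param alpha Significance level.
#' @param seed Seed.
#' @return A list with `false_call_rate` and `n_reps`.
#' @export
null_false_call_rate <- function(n_reps = 1000L, n_per_group = 100L,
                                 alpha = 0.05, seed = 1L) {
  set.seed(seed)
  any_call <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    gr <- sample_endpoint_groups(n_per_group)
    kw <- kruskal_wallis(gr)
    if (is.finite(kw$p_value) && kw$p_value < alpha) {
      dn <- dunn_vs_control(gr, 1L)
      any_call[r] <- any(dn$p_adjusted < alpha)
    }
  }
  list(false_call_rate = mean(any_call), n_reps = n_reps)
}

#' Power of the gated Dunn procedure for a one-SD location shift
#'
#' One treated group receives a pure location shift of `shift_sd` pooled
#' standard deviations; reports the fraction of replicates in which that
#' group receives the correct `up` call from the full gated procedure.
#'
#' @param n_reps Number of replicates.
#' @param n_per_group Cells per group.
#' @param shift_sd Shift in pooled-SD units (default 1).
#' @param alpha Significance level.
#' @param seed Seed.
#' @return A list with `power` and `n_reps`.
#' @export
shift_call_power <- function(n_reps = 300L, n_per_group = 100L,
                             shift_sd = 1, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  correct <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    gr <- sample_endpoint_groups(n_per_group, shift_groups = 2L,
                                 shift_sd = shift_sd)
    kw <- kruskal_wallis(gr)
    if (is.finite(kw$p_value) && kw$p_value < alpha) {
      dn <- dunn_vs_control(gr, 1L)
      correct[r] <- dn$p_adjusted[1] < alpha && dn$sign[1] > 0
    }
  }
  list(power = mean(correct), n_reps = n_reps)
}
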