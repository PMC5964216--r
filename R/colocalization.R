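#' Matching configuration for object-based colocalization
#'
#' @param max_distance Maximum centroid distance in um for declaring an
#'   adaptor and an autophagosome punctum the same physical site. The default
#'   of 0.5 um is half the minimum punctum diameter.
#' @return An object of class `match_config`.
#' @export
match_config <- function(max_distance = 0.5) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  structure(list(max_distance = max_distance, policy = "one-to-one greedy"),
            class = "match_config")
}

#' Match adaptor and autophagosome puncta one-to-one
#'
#' Greedy object-based matching: all cross-channel pairs with centroid
#' distance at most `max_distance` are ranked by ascending distance (ties by
#' adaptor id, then autophagosome id) and accepted greedily so that each
#' punctum is used at most once. The result is independent of input row
#' order.
#'
#' @param adaptor,autophagosome Punctum data frames (as from
#'   [detect_puncta()]) with `punctum_id`, `x_um`, `y_um` columns, typically
#'   restricted to one cell.
#' @param config A [match_config()].
#' @return Data frame of matched pairs: `adaptor_id`, `autophagosome_id`,
#'   `distance_um`. Empty inputs give an empty result.
#' @export
match_puncta <- function(adaptor, autophagosome, config = match_config()) {
  empty <- data.frame(adaptor_id = integer(), autophagosome_id = integer(),
                      distance_um = numeric())
  na <- nrow(adaptor); nl <- nrow(autophagosome)
  if (na == 0 || nl == 0) return(empty)
  dx <- outer(adaptor$x_um, autophagosome$x_um, "-")
  dy <- outer(adaptor$y_um, autophagosome$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  ok <- which(d <= config$max_distance, arr.ind = TRUE)
  if (nrow(ok) == 0) return(empty)
  cand <- data.frame(a = adaptor$punctum_id[ok[, 1]],
                     l = autophagosome$punctum_id[ok[, 2]],
                     distance_um = d[ok])
  cand <- cand[order(cand$distance_um, cand$a, cand$l), ]
  used_a <- character(0); used_l <- character(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(as.character(cand$a[i]) %in% used_a) &&
        !(as.character(cand$l[i]) %in% used_l)) {
      take[i] <- TRUE
      used_a <- c(used_a, as.character(cand$a[i]))
      used_l <- c(used_l, as.character(cand$l[i]))
    }
  }
  out <- cand[take, , drop = FALSE]
  data.frame(adaptor_id = out$a, autophagosome_id = out$l,
             distance_um = out$distance_um, row.names = NULL)
}

#' Per-cell colocalization profile
#'
#' Counts and the two percent-colocalized endpoints for one cell:
#' `100 * n_coloc / n_adaptor` and `100 * n_coloc / n_autophagosome`. A
#' percentage with a zero denominator is undefined: its value is `NA`, its
#' `defined` flag is `FALSE`, and it is excluded (not zero-filled) from group
#' averages downstream.
#'
#' @param cell_id Cell identifier.
#' @param adaptor,autophagosome The cell's punctum data frames.
#' @param pairs Matched pairs from [match_puncta()] on these lists.
#' @return One-row data frame: `cell_id`, `n_adaptor`, `n_autophagosome`,
#'   `n_coloc`, `pct_adaptor_coloc`, `pct_autophagosome_coloc`,
#'   `pct_adaptor_defined`, `pct_autophagosome_defined`.
#' @export
coloc_profile <- function(cell_id, adaptor, autophagosome, pairs) {
  if (nrow(pairs) > 0 &&
      (!all(pairs$adaptor_id %in% adaptor$punctum_id) ||
       !all(pairs$autophagosome_id %in% autophagosome$punctum_id)))
    stop("pairs reference puncta absent from the supplied lists")
  n_a <- nrow(adaptor); n_l <- nrow(autophagosome); n_c <- nrow(pairs)
  stopifnot(n_c <= min(n_a, n_l))
  data.frame(
    cell_id = cell_id, n_adaptor = n_a, n_autophagosome = n_l, n_coloc = n_c,
    pct_adaptor_coloc = if (n_a > 0) 100 * n_c / n_a else NA_real_,
    pct_autophagosome_coloc = if (n_l > 0) 100 * n_c / n_l else NA_real_,
    pct_adaptor_defined = n_a > 0,
    pct_autophagosome_defined = n_l > 0
  )
}
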