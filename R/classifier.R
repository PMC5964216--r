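#' Built-in dysfunction category templates
#'
#' The six autophagy dysfunction categories as direction templates over the
#' three evidence blocks (expression, puncta counts, percent colocalized) and
#' their endpoints (autophagosome marker LC3, cargo adaptor OPTN, and the
#' colocalized count). Each template slot is a set of admissible calls among
#' `up`, `down`, `no_change`, or the wildcard `any` where the underlying
#' theory makes no prediction ("unknown"). Templates ship as a
#' human-readable CSV (one record per decision-table cell) rather than code
#' so that the transcription itself is reviewable.
#'
#' Note that the expression block alone cannot separate
#' `impaired-interaction` from `autophagosome-failure-exhaustion`: the two
#' categories carry identical expression rows, so both can be full on that
#' block simultaneously.
#'
#' @param path Optional path to an alternative template file with columns
#'   `category`, `block`, `endpoint`, `expected` (`|`-separated set or
#'   `any`).
#' @return A nested list: `templates[[category]][[block]][[endpoint]]` is a
#'   character vector of admissible calls, or `"any"`.
#' @export
builtin_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dysfunction_templates.csv",
                        package = "punctaflux", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "block", "endpoint", "expected") %in% names(tab)))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    set <- strsplit(tab$expected[i], "|", fixed = TRUE)[[1]]
    bad <- setdiff(set, c("up", "down", "no_change", "any"))
    if (length(bad)) stop("invalid expected call(s): ", paste(bad, collapse = ", "))
    out[[tab$category[i]]][[tab$block[i]]][[tab$endpoint[i]]] <- set
  }
  out
}

# slots of a complete direction pattern
pattern_slots <- function() {
  list(expression = c("autophagosome", "adaptor"),
       puncta = c("autophagosome", "adaptor", "coloc"),
       pct_coloc = c("autophagosome", "adaptor"))
}

#' Assemble a direction pattern from change calls
#'
#' Builds the seven-slot direction pattern (expression LC3/OPTN, puncta
#' LC3/OPTN/colocalized, percent-colocalized LC3/OPTN) for one region, stage
#' (group), from the change-call table of [endpoint_battery()].
#'
#' @param calls Change-call data frame with `endpoint`, `group`, `call`.
#' @param group The stage (group label) to extract.
#' @return A nested list `pattern[[block]][[endpoint]]` with calls in
#'   `up`/`down`/`no_change`.
#' @export
direction_pattern <- function(calls, group) {
  cc <- calls[calls$group == group, ]
  lookup <- stats::setNames(cc$call, cc$endpoint)
  pat <- list(
    expression = list(autophagosome = lookup[["expression_autophagosome"]],
                      adaptor = lookup[["expression_adaptor"]]),
    puncta = list(autophagosome = lookup[["puncta_autophagosome"]],
                  adaptor = lookup[["puncta_adaptor"]],
                  coloc = lookup[["puncta_coloc"]]),
    pct_coloc = list(autophagosome = lookup[["pct_coloc_autophagosome"]],
                     adaptor = lookup[["pct_coloc_adaptor"]])
  )
  validate_pattern(pat)
  pat
}

validate_pattern <- function(pattern) {
  slots <- pattern_slots()
  for (b in names(slots)) for (e in slots[[b]]) {
    v <- pattern[[b]][[e]]
    if (is.null(v) || is.na(v) || !v %in% c("up", "down", "no_change"))
      stop("direction pattern slot missing or invalid: ", b, "/", e)
  }
  invisible(TRUE)
}

opposite_call <- function(call) {
  switch(call, up = "down", down = "up", no_change = NA_character_)
}

#' Classify a direction pattern against the dysfunction templates
#'
#' For each category and evidence block the status is `full` when every
#' endpoint's call lies in the template's expected set (wildcards always
#' satisfied), `inconsistent` when some endpoint's call is the direction
#' opposite to every member of its expected set (only possible against a
#' single-direction expectation), and `partial` otherwise. A category is
#' matched when no block is inconsistent and at least one *evidentiary*
#' block is full - a block whose template expects an actual direction
#' somewhere; a block that only expects "no change" cannot by itself
#' positively identify a category. Several categories can match the same
#' pattern, since some decision-table rows coincide.
#'
#' @param pattern A direction pattern from [direction_pattern()].
#' @param templates Templates from [builtin_templates()].
#' @return A list of class `classification_result` with `blocks` (data frame
#'   `category`, `block`, `status`) and `matched` (character vector of
#'   matched categories, in template order).
#' @export
classify <- function(pattern, templates = builtin_templates()) {
  validate_pattern(pattern)
  slots <- pattern_slots()
  rows <- list()
  matched <- character(0)
  for (cat in names(templates)) {
    statuses <- character(0)
    evidentiary <- logical(0)
    for (b in names(slots)) {
      full <- TRUE; inconsistent <- FALSE; directional <- FALSE
      for (e in slots[[b]]) {
        expected <- templates[[cat]][[b]][[e]]
        call <- pattern[[b]][[e]]
        if ("any" %in% expected) next
        if (any(expected %in% c("up", "down"))) directional <- TRUE
        if (!call %in% expected) {
          full <- FALSE
          opp <- vapply(expected, opposite_call, character(1))
          if (!anyNA(opp) && all(opp == call)) inconsistent <- TRUE
        }
      }
      statuses[b] <- if (inconsistent) "inconsistent" else if (full) "full" else "partial"
      evidentiary[b] <- directional
      rows[[length(rows) + 1L]] <- data.frame(category = cat, block = b,
                                              status = statuses[b])
    }
    if (!any(statuses == "inconsistent") &&
        any(statuses == "full" & evidentiary))
      matched <- c(matched, cat)
  }
  structure(list(blocks = do.call(rbind, rows), matched = matched),
            class = "classification_result")
}

#' Region-by-stage verdict matrix
#'
#' Collates classification results into the summary matrix: one row per
#' category and evidence block, one column per region/stage, with `full`
#' rendered as `"X"`, `partial` as `"/"`, and `inconsistent` as blank. A
#' companion `matched` table lists the matched categories per cell.
#'
#' @param results Named list or data-frame-like input: each element a list
#'   with `region`, `stage`, and a `classification_result`.
#' @return A list with `marks` (data frame, rows = category x block, one
#'   column per `region:stage`), `matched` (data frame `region`, `stage`,
#'   `category`, `matched`), and `text` (a rendered text table). Errors on a
#'   duplicated region/stage.
#' @export
summarize_matrix <- function(results) {
  if (length(results) == 0)
    return(list(marks = data.frame(category = character(), block = character()),
                matched = data.frame(region = character(), stage = character(),
                                     category = character()),
                text = ""))
  keys <- vapply(results, function(r) paste(r$region, r$stage, sep = ":"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate region/stage: ", keys[duplicated(keys)][1])
  base <- results[[1]]$classification$blocks[, c("category", "block")]
  marks <- base
  matched <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    st <- r$classification$blocks$status
    marks[[keys[i]]] <- c(full = "X", partial = "/", inconsistent = "")[st]
    matched[[i]] <- data.frame(region = r$region, stage = r$stage,
                               category = r$classification$blocks$category[
                                 !duplicated(r$classification$blocks$category)],
                               stringsAsFactors = FALSE)
    matched[[i]]$matched <- matched[[i]]$category %in% r$classification$matched
  }
  txt <- utils::capture.output(print(marks, row.names = FALSE))
  list(marks = marks, matched = do.call(rbind, matched),
       text = paste(txt, collapse = "\n"))
}
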