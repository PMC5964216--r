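# Independent brute-force oracle for the decision-table classifier,
# shared by the unit and acceptance suites.

# independent brute-force walker over the transcribed decision table
oracle_csv <- function() {
  read.csv(system.file("extdata", "dysfunction_templates.csv",
                       package = "punctaflux"), stringsAsFactors = FALSE)
}

oracle_classify <- function(pattern, tab) {
  opp <- c(up = "down", down = "up")
  cats <- unique(tab$category)
  blocks <- unique(tab$block)
  status <- list(); matched <- character(0)
  for (cat in cats) {
    st <- character(0); ev <- logical(0)
    for (b in blocks) {
      rows <- tab[tab$category == cat & tab$block == b, ]
      full <- TRUE; inc <- FALSE; direc <- FALSE
      for (r in seq_len(nrow(rows))) {
        set <- strsplit(rows$expected[r], "|", fixed = TRUE)[[1]]
        if ("any" %in% set) next
        if (any(set %in% c("up", "down"))) direc <- TRUE
        call <- pattern[[b]][[rows$endpoint[r]]]
        if (!(call %in% set)) {
          full <- FALSE
          opposites <- unname(opp[set])
          if (!anyNA(opposites) && all(opposites == call)) inc <- TRUE
        }
      }
      st[b] <- if (inc) "inconsistent" else if (full) "full" else "partial"
      ev[b] <- direc
    }
    status[[cat]] <- st
    if (!any(st == "inconsistent") && any(st == "full" & ev))
      matched <- c(matched, cat)
  }
  list(status = status, matched = matched)
}

mk_pattern <- function(calls) {
  # calls: character(7) in slot order eL, eO, pL, pO, pC, cL, cO
  list(expression = list(autophagosome = calls[1], adaptor = calls[2]),
       puncta = list(autophagosome = calls[3], adaptor = calls[4],
                     coloc = calls[5]),
       pct_coloc = list(autophagosome = calls[6], adaptor = calls[7]))
}

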