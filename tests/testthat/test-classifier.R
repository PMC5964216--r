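test_that("template transcription is complete and matches spot checks", {
  tpl <- builtin_templates()
  expect_length(tpl, 6)
  for (cat in names(tpl)) {
    expect_setequal(names(tpl[[cat]]), c("expression", "puncta", "pct_coloc"))
    expect_length(tpl[[cat]]$puncta, 3)
    expect_length(tpl[[cat]]$expression, 2)
    expect_length(tpl[[cat]]$pct_coloc, 2)
  }
  expect_equal(tpl$`impaired-interaction`$expression$autophagosome, "down")
  expect_equal(tpl$`impaired-interaction`$expression$adaptor, "up")
  expect_equal(tpl$`induced-flux-unimpaired`$puncta$autophagosome, "up")
  expect_setequal(tpl$`induced-flux-unimpaired`$puncta$adaptor,
                  c("down", "no_change"))
  expect_equal(tpl$`induced-flux-unimpaired`$puncta$coloc, "no_change")
  expect_equal(tpl$`optn-failure-exhaustion`$expression$autophagosome, "any")
  expect_equal(tpl$`optn-failure-exhaustion`$expression$adaptor, "down")
})

test_that("canonical full patterns classify as intended", {
  tpl <- builtin_templates()
  # all seven calls up: the fusion-failure signature
  res <- classify(mk_pattern(rep("up", 7)), tpl)
  expect_true("failed-fusion" %in% res$matched)
  bl <- res$blocks[res$blocks$category == "failed-fusion", ]
  expect_true(all(bl$status == "full"))
  # identical expression rows cannot separate two categories
  res2 <- classify(mk_pattern(c("down", "up", rep("no_change", 5))), tpl)
  bl2 <- res2$blocks
  expect_equal(bl2$status[bl2$category == "impaired-interaction" &
                            bl2$block == "expression"], "full")
  expect_equal(bl2$status[bl2$category == "autophagosome-failure-exhaustion" &
                            bl2$block == "expression"], "full")
  # a flat pattern matches nothing
  res3 <- classify(mk_pattern(rep("no_change", 7)), tpl)
  expect_length(res3$matched, 0)
  expect_error(classify(list(expression = list(autophagosome = "up")), tpl),
               "slot")
})

test_that("the rule engine agrees with the brute-force oracle on sampled patterns", {
  # the exhaustive 3^7 sweep runs in the acceptance suite; here a seeded sample
  tpl <- builtin_templates()
  tab <- oracle_csv()
  lv <- c("up", "down", "no_change")
  grid <- expand.grid(rep(list(lv), 7), stringsAsFactors = FALSE)
  set.seed(1)
  grid <- grid[sample(nrow(grid), 250), ]
  for (i in seq_len(nrow(grid))) {
    pat <- mk_pattern(unlist(grid[i, ], use.names = FALSE))
    got <- classify(pat, tpl)
    want <- oracle_classify(pat, tab)
    expect_identical(sort(got$matched), sort(want$matched))
    for (cat in names(want$status)) {
      g <- got$blocks[got$blocks$category == cat, ]
      expect_identical(stats::setNames(g$status, g$block), want$status[[cat]])
    }
  }
})

test_that("the verdict matrix renders statuses and rejects duplicates", {
  tpl <- builtin_templates()
  r1 <- list(region = "10N", stage = "24h",
             classification = classify(mk_pattern(rep("up", 7)), tpl))
  r2 <- list(region = "10N", stage = "5d",
             classification = classify(mk_pattern(rep("no_change", 7)), tpl))
  v <- summarize_matrix(list(r1, r2))
  expect_true("10N:24h" %in% names(v$marks))
  ff <- v$marks[v$marks$category == "failed-fusion", "10N:24h"]
  expect_equal(ff, rep("X", 3))
  m <- v$matched
  expect_true(m$matched[m$stage == "24h" & m$category == "failed-fusion"])
  expect_false(any(m$matched[m$stage == "5d"]))
  empty <- summarize_matrix(list())
  expect_equal(nrow(empty$matched), 0)
  expect_error(summarize_matrix(list(r1, r1)), "duplicate")
})
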