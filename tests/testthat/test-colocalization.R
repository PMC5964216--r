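mk_puncta <- function(x, y, ids = seq_along(x)) {
  data.frame(punctum_id = ids, x_um = x, y_um = y)
}

test_that("identical centroid lists match completely at zero distance", {
  a <- mk_puncta(c(1, 2, 3), c(1, 1, 1))
  pr <- match_puncta(a, a)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$distance_um, rep(0, 3))
})

test_that("no pairs form beyond the distance gate", {
  a <- mk_puncta(c(0, 5), c(0, 0))
  b <- mk_puncta(c(2, 8), c(0, 0))
  expect_equal(nrow(match_puncta(a, b)), 0)
  expect_equal(nrow(match_puncta(a, b[0, ])), 0)
})

test_that("greedy matching equals an exhaustive check of the rule", {
  # independent oracle: enumerate every admissible pair, sort by
  # (distance, adaptor id, autophagosome id), accept greedily
  greedy_oracle <- function(a, l, dmax) {
    rows <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(l))) {
      d <- sqrt((a$x_um[i] - l$x_um[j])^2 + (a$y_um[i] - l$y_um[j])^2)
      if (d <= dmax) rows <- rbind(rows, data.frame(a = a$punctum_id[i],
                                                    l = l$punctum_id[j], d = d))
    }
    if (is.null(rows)) return(rows)
    rows <- rows[order(rows$d, rows$a, rows$l), ]
    ua <- c(); ul <- c(); out <- NULL
    for (r in seq_len(nrow(rows))) {
      if (!(rows$a[r] %in% ua) && !(rows$l[r] %in% ul)) {
        out <- rbind(out, rows[r, ]); ua <- c(ua, rows$a[r]); ul <- c(ul, rows$l[r])
      }
    }
    out
  }
  set.seed(88)
  for (rep in 1:5) {
    a <- mk_puncta(runif(20, 0, 6), runif(20, 0, 6))
    l <- mk_puncta(runif(20, 0, 6), runif(20, 0, 6))
    got <- match_puncta(a, l)
    exp <- greedy_oracle(a, l, 0.5)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$adaptor_id, exp$a)
      expect_equal(got$autophagosome_id, exp$l)
    }
    # symmetry of the pair count and order independence
    swapped <- match_puncta(l, a)
    expect_equal(nrow(swapped), nrow(got))
    shuf <- match_puncta(a[sample(nrow(a)), ], l[sample(nrow(l)), ])
    expect_equal(nrow(shuf), nrow(got))
    expect_setequal(paste(shuf$adaptor_id, shuf$autophagosome_id),
                    paste(got$adaptor_id, got$autophagosome_id))
  }
})

test_that("widening the distance gate never loses pairs", {
  set.seed(3)
  a <- mk_puncta(runif(30, 0, 8), runif(30, 0, 8))
  l <- mk_puncta(runif(30, 0, 8), runif(30, 0, 8))
  prev <- -1
  for (d in c(0.2, 0.5, 1, 2)) {
    n <- nrow(match_puncta(a, l, match_config(max_distance = d)))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("colocalization percentages follow the stated formulas", {
  a <- mk_puncta(1:4, rep(0, 4))
  l <- mk_puncta(seq(0.9, 9.9, by = 1)[1:10], rep(0.1, 10))
  pairs <- match_puncta(a, l)[1:2, ]
  prof <- coloc_profile(7, a, l, pairs)
  expect_equal(prof$n_coloc, 2)
  expect_equal(prof$pct_adaptor_coloc, 50)
  expect_equal(prof$pct_autophagosome_coloc, 20)
  expect_true(prof$pct_adaptor_defined && prof$pct_autophagosome_defined)
})

test_that("zero denominators yield undefined percentages, not zeros", {
  empty <- mk_puncta(numeric(0), numeric(0), integer(0))
  l <- mk_puncta(1:3, rep(0, 3))
  prof <- coloc_profile(1, empty, l, match_puncta(empty, l))
  expect_equal(prof$n_coloc, 0)
  expect_true(is.na(prof$pct_adaptor_coloc))
  expect_false(prof$pct_adaptor_defined)
  expect_error(coloc_profile(1, empty, l,
                             data.frame(adaptor_id = 9, autophagosome_id = 1,
                                        distance_um = 0)),
               "absent")
})
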