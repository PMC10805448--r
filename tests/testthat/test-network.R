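sl_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(region_i = r[[1]], region_j = r[[2]],
               streamline_count = r[[3]], mean_fa = r[[4]])
  }))
}

test_that("the FA > 0.2 edge rule is applied strictly", {
  nets <- build_networks(sl_df(list(1L, 2L, 10L, 0.25),
                               list(1L, 3L, 10L, 0.15)))
  expect_equal(nets$FA_wei[1, 2], 0.25)
  expect_equal(nets$FA_wei[2, 1], 0.25)
  expect_equal(nets$FA_bin[1, 2], 1)
  expect_equal(nets$FA_wei[1, 3], 0)
  expect_equal(sum(nets$FA_wei > 0), 2L)  # one undirected edge

  # FA exactly at the threshold is excluded (strict inequality)
  at_thr <- build_networks(sl_df(list(1L, 2L, 10L, 0.20)))
  expect_equal(sum(unclass(at_thr$FA_wei)), 0)
  just_above <- build_networks(sl_df(list(1L, 2L, 10L, 0.2000001)))
  expect_equal(sum(unclass(just_above$FA_bin)), 2)
})

test_that("min_count filters low-evidence edges", {
  sl <- sl_df(list(1L, 2L, 1L, 0.5), list(3L, 4L, 7L, 0.5))
  nets <- build_networks(sl, min_count = 5L)
  expect_equal(nets$FA_wei[1, 2], 0)
  expect_equal(nets$FA_wei[3, 4], 0.5)
})

test_that("an empty streamline list yields valid all-zero networks", {
  empty <- sl_df()[0, ]
  empty <- data.frame(region_i = integer(), region_j = integer(),
                      streamline_count = integer(), mean_fa = numeric())
  nets <- build_networks(empty)
  expect_true(all(unclass(nets$FA_wei) == 0))
  expect_length(validate_matrix(nets$FA_bin), 0L)
  # downstream metrics handle the degenerate graph without error
  gm <- global_metrics(nets$FA_wei)
  expect_equal(gm$Eg, 0)
  expect_equal(gm$Cp, 0)
  expect_equal(gm$Eloc, 0)
  expect_true(is.na(gm$Lp))
  expect_equal(gm$n_unreachable_pairs, 90 * 89)
})

test_that("construction is invariant to record order and consistent", {
  set.seed(42)
  n_rec <- 200L
  pairs <- t(combn(90L, 2L))
  sel <- pairs[sample(nrow(pairs), n_rec), ]
  sl <- data.frame(region_i = sel[, 1], region_j = sel[, 2],
                   streamline_count = sample(1:50, n_rec, TRUE),
                   mean_fa = runif(n_rec, 0.05, 0.9))
  shuffled <- sl[sample(n_rec), ]
  a <- build_networks(sl)
  b <- build_networks(shuffled)
  expect_equal(unclass(a$FA_wei), unclass(b$FA_wei))
  # binary pattern is exactly the indicator of the weighted pattern
  expect_equal(unclass(a$FA_bin), (unclass(a$FA_wei) > 0) * 1,
               ignore_attr = TRUE)
  # raising the threshold never adds edges
  strict <- build_networks(sl, fa_threshold = 0.5)
  expect_true(all(unclass(a$FA_wei)[unclass(strict$FA_wei) > 0] > 0))
  expect_lte(sum(unclass(strict$FA_bin)), sum(unclass(a$FA_bin)))
})

test_that("malformed streamline inputs are rejected", {
  expect_error(build_networks(sl_df(list(1L, 91L, 5L, 0.5))), "1..90")
  expect_error(build_networks(sl_df(list(2L, 2L, 5L, 0.5))), "self-pairs")
  expect_error(build_networks(sl_df(list(5L, 3L, 5L, 0.5))), "region_i <")
  expect_error(build_networks(sl_df(list(1L, 2L, 5L, 0.5),
                                    list(1L, 2L, 9L, 0.6))), "duplicate")
  expect_error(build_networks(sl_df(list(1L, 2L, 5L, 1.4))), "\\[0, 1\\]")
})

test_that("validate_matrix reports violations without mutating", {
  ok <- matrix(0, 90, 90)
  ok[1, 2] <- ok[2, 1] <- 0.5
  expect_length(validate_matrix(ok, kind = "FA_wei"), 0L)

  asym <- ok; asym[1, 2] <- 0.6
  expect_match(validate_matrix(asym, kind = "FA_wei"), "asymmetric",
               all = FALSE)

  diag_bad <- ok; diag_bad[3, 3] <- 1
  expect_match(validate_matrix(diag_bad, kind = "FA_wei"), "diagonal",
               all = FALSE)

  range_bad <- ok; range_bad[4, 5] <- range_bad[5, 4] <- 1.3
  expect_match(validate_matrix(range_bad, kind = "FA_wei"), "\\(0.2, 1\\]",
               all = FALSE)

  nonbinary <- ok
  expect_match(validate_matrix(nonbinary, kind = "FA_bin"), "0 or 1",
               all = FALSE)
  expect_error(validate_matrix(matrix(0, 10, 10)), "90x90")
})

test_that("the connectivity_matrix constructor enforces invariants", {
  w <- matrix(0, 90, 90); w[1, 2] <- w[2, 1] <- 0.5
  m <- connectivity_matrix(w, "FA_wei", "s1")
  expect_s3_class(m, "connectivity_matrix")
  expect_identical(attr(m, "kind"), "FA_wei")
  bad <- w; bad[1, 2] <- 0.1
  expect_error(connectivity_matrix(bad, "FA_wei"), "invalid")
  expect_error(connectivity_matrix(matrix(0, 3, 3), "FA_wei"), "90x90")
})
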