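test_that("deposition percentages follow the granular+spinous+basal sum", {
  m <- rbind(toy = c(granular = 10, spinous = 30, basal = 10))
  expect_equal(deposition_percentages(m)["toy", ],
               c(granular = 20, spinous = 60, basal = 20))
  eq <- rbind(a = c(granular = 7, spinous = 7, basal = 7))
  expect_equal(unname(deposition_percentages(eq)[1, ]), rep(100 / 3, 3))
  # cornified excluded by default, includable on request
  full <- rbind(a = c(cornified = 10, granular = 10, spinous = 10,
                      basal = 10))
  expect_equal(unname(deposition_percentages(full, TRUE)[1, ]), rep(25, 4))
  expect_error(deposition_percentages(
    rbind(a = c(granular = 0, spinous = 10, basal = 10))),
    "non-positive mean for model 'a', layer 'granular'")
  expect_error(deposition_percentages(
    rbind(a = c(spinous = 10, basal = 10))), "missing layer")
})

test_that("deposition percentages always sum to 100 per model", {
  withr::with_seed(21, {
    for (i in 1:200) {
      m <- matrix(stats::runif(12, 0.1, 60), 4,
                  dimnames = list(letters[1:4],
                                  c("granular", "spinous", "basal")))
      expect_equal(unname(rowSums(deposition_percentages(m))), rep(100, 4))
    }
  })
})

test_that("rank scoring reproduces the reference epidermis column ranks", {
  epi <- cbind(epidermis = reference_epidermis_means)
  expect_equal(rank_scores(epi, "pig", "epidermis"),
               c(human = 2L, keraskin = 1L, rabbit = 3L))
  expect_equal(rank_scores(epi, "human", "epidermis"),
               c(keraskin = 3L, pig = 1L, rabbit = 2L))
  expect_equal(rank_scores(epi, "keraskin", "epidermis"),
               c(human = 2L, pig = 1L, rabbit = 3L))
  expect_equal(rank_scores(epi, "rabbit", "epidermis"),
               c(human = 1L, keraskin = 3L, pig = 2L))
})

test_that("rank scoring matches a brute-force sorting oracle", {
  withr::with_seed(31, {
    strata <- c("epidermis", "cornified", "granular", "spinous", "basal")
    for (i in 1:1000) {
      m <- matrix(stats::runif(20, 1, 100), 4,
                  dimnames = list(c("human", "keraskin", "pig", "rabbit"),
                                  strata))
      p <- sample(rownames(m), 1)
      s <- sample(strata, 1)
      got <- rank_scores(m, p, s)
      expect_identical(got, stats::setNames(as.integer(
        brute_force_ranks(m, p, s)), names(got)))
      # always a permutation of 1..3
      expect_setequal(got, 1:3)
    }
  })
})

test_that("rank scores are invariant to positive affine rescaling", {
  withr::with_seed(17, {
    for (i in 1:50) {
      m <- matrix(stats::runif(4, 5, 80), 4, 1,
                  dimnames = list(c("human", "keraskin", "pig", "rabbit"),
                                  "epidermis"))
      a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, -5, 5)
      for (p in rownames(m)) {
        expect_identical(rank_scores(m, p, "epidermis"),
                         rank_scores(a * m + b, p, "epidermis"))
      }
    }
  })
})

test_that("ties break by fixed model order with a warning", {
  m <- matrix(c(10, 15, 5, 20), 4, 1,
              dimnames = list(c("human", "keraskin", "pig", "rabbit"),
                              "epidermis"))
  # keraskin and pig both 5 um from human
  expect_warning(r <- rank_scores(m, "human", "epidermis"), "tied")
  expect_setequal(r, 1:3)
  expect_equal(unname(r[c("keraskin", "pig")]), 1:2)  # row order wins
})

test_that("totals reproduce the reference table for all perspectives", {
  tot <- total_scores(reference_score_table)
  for (p in names(reference_totals)) {
    expect_equal(tot[[p]], reference_totals[[p]], ignore_attr = TRUE)
    expect_named(tot[[p]], names(reference_totals[[p]]))
  }
  # the three comparator totals always sum to 30 over 5 strata
  expect_true(all(vapply(tot, sum, 0) == 30))
  expect_error(total_scores(list(x = reference_score_table$human[-1, ])),
               "missing stratum")
})

test_that("the full reference score grid derives from the default library", {
  means <- profile_mean_matrix(default_profile_library())
  sc <- similarity_scores(means)
  for (p in names(reference_score_table)) {
    expect_equal(sc$scores[[p]],
                 reference_score_table[[p]], ignore_attr = TRUE)
    expect_equal(sc$totals[[p]], reference_totals[[p]],
                 ignore_attr = TRUE)
  }
})

test_that("score-matrix invariants hold on random mean matrices", {
  withr::with_seed(41, {
    strata <- c("epidermis", "cornified", "granular", "spinous", "basal")
    for (i in 1:50) {
      m <- matrix(stats::runif(20, 1, 100), 4,
                  dimnames = list(c("human", "keraskin", "pig", "rabbit"),
                                  strata))
      sc <- similarity_scores(m)
      for (p in rownames(m)) {
        expect_true(all(apply(sc$scores[[p]], 1, sort) == 1:3))
        expect_equal(sum(sc$totals[[p]]), 30L)
        expect_true(all(sc$totals[[p]] >= 5 & sc$totals[[p]] <= 15))
      }
    }
  })
})

test_that("heatmap grids keep fixed order and exclude self-comparison", {
  sc <- similarity_scores(profile_mean_matrix(default_profile_library()))
  hm <- heatmap_matrix(sc)
  models <- c("human", "keraskin", "pig", "rabbit")
  expect_equal(rownames(hm$totals), models)
  expect_equal(colnames(hm$totals), models)
  expect_true(all(is.na(diag(hm$totals))))
  expect_equal(hm$totals["human", c("keraskin", "pig", "rabbit")],
               c(keraskin = 12, pig = 7, rabbit = 11))
  for (g in hm$layer_grids) {
    expect_true(all(g[!is.na(g)] %in% 1:3))
    expect_true(all(is.na(diag(g))))
  }
  expect_true(all(hm$totals[!is.na(hm$totals)] >= 5 &
                  hm$totals[!is.na(hm$totals)] <= 15))
})

test_that("marker concordance counts shared panel calls", {
  panel <- rbind(human = c(FLG = TRUE, CLDN1 = TRUE, CDH1 = TRUE),
                 keraskin = c(TRUE, TRUE, TRUE),
                 pig = c(FALSE, TRUE, TRUE),
                 rabbit = c(FALSE, FALSE, FALSE))
  cc <- marker_concordance(panel, reference = "human")
  expect_equal(cc[["pig"]], 2 / 3)
  expect_equal(cc[["keraskin"]], 1)
  expect_equal(cc[["rabbit"]], 0)
  expect_equal(cc[["human"]], 1)  # identity
  expect_error(marker_concordance(panel, reference = "pig"),
               "must express all")
  panel[2, 2] <- NA
  expect_error(marker_concordance(panel), "incomplete")
})
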