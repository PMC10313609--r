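test_that("uniform bands measure their exact pixel thickness", {
  s <- band_section()  # cornified 30 px at 1 um/px
  expect_equal(measure_layer_thickness(s, "cornified", 10, seed = 1),
               rep(30, 10))
  expect_equal(measure_epidermal_thickness(s, 10, seed = 1), rep(70, 10))
  # additivity on a 10+10+10+10 section
  s4 <- band_section(px = c(cornified = 10, granular = 10, spinous = 10,
                            basal = 10))
  expect_equal(measure_epidermal_thickness(s4, 5, seed = 2), rep(40, 5))
})

test_that("measurements equal generator ground truth column-for-column", {
  lib <- default_profile_library()
  for (m in c("human", "keraskin")) {
    s <- generate_section(lib[[m]], width_px = 90, seed = 8)
    w <- ncol(s$label_image)
    cols <- withr::with_seed(3L, sample.int(w, w))
    expect_equal(measure_epidermal_thickness(s, w, seed = 3),
                 s$ground_truth$epidermis[cols])
    for (l in c("cornified", "granular", "spinous", "basal")) {
      expect_equal(measure_layer_thickness(s, l, w, seed = 3),
                   s$ground_truth[[l]][cols])
    }
  }
})

test_that("epidermis measurement is the column-wise sum of layer runs", {
  s <- generate_section(default_profile_library()$pig, width_px = 70,
                        seed = 5)
  layers <- c("cornified", "granular", "spinous", "basal")
  per_layer <- sapply(layers, function(l) {
    measure_layer_thickness(s, l, 30, seed = 12)
  })
  epi <- measure_epidermal_thickness(s, 30, seed = 12)
  expect_equal(rowSums(per_layer), epi, ignore_attr = TRUE)
  expect_true(all(epi >= apply(per_layer, 1, max)))
})

test_that("measuring every column is permutation-invariant in the mean", {
  s <- generate_section(default_profile_library()$human, width_px = 60,
                        seed = 10)
  w <- ncol(s$label_image)
  m1 <- mean(measure_epidermal_thickness(s, w, seed = 1))
  m2 <- mean(measure_epidermal_thickness(s, w, seed = 999))
  expect_equal(m1, m2)
})

test_that("disjoint runs resolve to the bottom-most run", {
  # hand-built column with two cornified runs separated by granular
  s <- band_section(width = 4)
  codes <- layer_labels()
  s$label_image[10:12, ] <- codes[["granular"]]  # split the cornified band
  th <- measure_layer_thickness(s, "cornified", 4, seed = 1)
  expect_equal(th, rep(23, 4))  # rows 13..35 survive below the split
})

test_that("morphometry rejects bad layers and column counts", {
  s <- band_section(width = 20)
  expect_error(measure_layer_thickness(s, "lucidum", 5), "unknown layer")
  no_gran <- band_section(px = c(cornified = 10, granular = 1, spinous = 10,
                                 basal = 10))
  no_gran$label_image[no_gran$label_image == 2L] <- 3L
  expect_error(measure_layer_thickness(no_gran, "granular", 5),
               "layer not found")
  expect_error(measure_epidermal_thickness(s, 21), "between 1 and")
  expect_error(measure_epidermal_thickness(s, 0), "between 1 and")
})

test_that("summaries report mean, SEM with n-1 denominator, and n", {
  tab <- data.frame(model = "m", layer = "basal", field = 1:3,
                    thickness_um = c(2, 4, 6))
  s <- summarize_measurements(tab)
  expect_equal(s$mean_um, 4)
  expect_equal(s$sem_um, 2 / sqrt(3))
  expect_equal(s$n, 3L)
  # constant values -> SEM 0; single value -> SEM undefined, mean kept
  s0 <- summarize_measurements(data.frame(model = "m", layer = "b",
                                          field = 1:4,
                                          thickness_um = rep(7, 4)))
  expect_equal(s0$sem_um, 0)
  s1 <- summarize_measurements(data.frame(model = "m", layer = "b",
                                          field = 1, thickness_um = 5))
  expect_equal(s1$mean_um, 5)
  expect_true(is.na(s1$sem_um))
})

test_that("batch measurement produces a well-formed long table", {
  lib <- default_profile_library()
  secs <- c(lapply(1:2, function(i) generate_section(lib$human, seed = i)),
            lapply(1:2, function(i) generate_section(lib$rabbit, seed = i)))
  tab <- measure_sections(secs, n_columns = 5, seed = 3)
  expect_named(tab, c("model", "layer", "field", "thickness_um"))
  expect_equal(nrow(tab), 4 * 5 * 5)  # sections x layers x columns
  # (model, layer, field) unique; 10 fields per model-layer
  expect_false(any(duplicated(tab[c("model", "layer", "field")])))
  expect_true(all(table(tab$model, tab$layer) == 10))
  expect_true(all(tab$thickness_um >= 0))
})
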