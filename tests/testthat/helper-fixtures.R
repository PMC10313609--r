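# shared fixtures built in code

toy_profile <- function(cv = 0, amplitude = 0, mki67 = 0.1, ...) {
  skin_profile("toy",
               layer_means = c(cornified = 10, granular = 5,
                               spinous = 20, basal = 10),
               epidermis_mean = 45, cv = cv,
               undulation_amplitude = amplitude, undulation_period = 100,
               mki67_positive_fraction = mki67, ...)
}

# hand-built section: uniform horizontal bands, 1 um/px
band_section <- function(width = 50, px = c(cornified = 30, granular = 10,
                                            spinous = 20, basal = 10),
                         top = 5, dermis = 10, pixel_size = 1) {
  codes <- layer_labels()
  col <- c(rep(codes[["background"]], top),
           rep(unname(codes[c("cornified", "granular", "spinous", "basal")]),
               px),
           rep(codes[["dermis"]], dermis))
  label <- matrix(rep(col, width), ncol = width)
  gt <- data.frame(column = seq_len(width) - 1L)
  for (l in names(px)) gt[[l]] <- px[[l]] * pixel_size
  gt$epidermis <- sum(px) * pixel_size
  structure(list(label_image = label, pixel_size = pixel_size,
                 ground_truth = gt,
                 nuclei = data.frame(x = integer(), y = integer(),
                                     stain = character()),
                 model_id = "band", seed = NA_integer_),
            class = "synthetic_section")
}

# printed reference: epidermis means and the full per-layer score grid
reference_epidermis_means <- c(human = 51.64, keraskin = 90.33,
                               pig = 75.47, rabbit = 51.64 / 3)

reference_score_table <- list(
  human = rbind(epidermis = c(keraskin = 3, pig = 1, rabbit = 2),
                cornified = c(3, 1, 2), granular = c(3, 2, 1),
                spinous = c(2, 1, 3), basal = c(1, 2, 3)),
  keraskin = rbind(epidermis = c(human = 2, pig = 1, rabbit = 3),
                   cornified = c(2, 1, 3), granular = c(2, 1, 3),
                   spinous = c(2, 1, 3), basal = c(1, 2, 3)),
  pig = rbind(epidermis = c(human = 2, keraskin = 1, rabbit = 3),
              cornified = c(1, 3, 2), granular = c(2, 1, 3),
              spinous = c(2, 1, 3), basal = c(2, 1, 3)),
  rabbit = rbind(epidermis = c(human = 1, keraskin = 3, pig = 2),
                 cornified = c(1, 3, 2), granular = c(1, 3, 2),
                 spinous = c(1, 3, 2), basal = c(1, 2, 3)))

reference_totals <- list(
  human = c(keraskin = 12, pig = 7, rabbit = 11),
  keraskin = c(human = 9, pig = 6, rabbit = 15),
  pig = c(human = 9, keraskin = 7, rabbit = 14),
  rabbit = c(human = 5, keraskin = 14, pig = 11))

reference_mki67 <- c(human = 1.45, keraskin = 8.47, pig = 1.73,
                     rabbit = 2.75)

# independent brute-force oracle for rank scoring: explicit sort + lookup
brute_force_ranks <- function(means, perspective, stratum) {
  comp <- setdiff(rownames(means), perspective)
  d <- abs(means[perspective, stratum] - means[comp, stratum])
  ord <- order(d)  # stable: ties keep comparator order
  out <- integer(length(comp))
  out[ord] <- seq_along(comp)
  stats::setNames(out, comp)
}
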