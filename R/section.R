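# Synthetic section generation: label rasters with exact per-column ground
# truth, standing in for scanned H&E/IHC slides.

#' Sample per-field thickness measurements from a profile
#'
#' Draws `n_fields` independent thickness values for one layer (or the whole
#' epidermis) from a normal distribution truncated at zero, with mean equal
#' to the profile mean and standard deviation `cv * mean`. This emulates
#' thickness measured in randomly selected fields of view.
#'
#' @param profile A [skin_profile].
#' @param layer One of `"cornified"`, `"granular"`, `"spinous"`, `"basal"`,
#'   or `"epidermis"`.
#' @param n_fields Number of fields to draw (>= 1).
#' @param seed Integer seed; fixed seed gives reproducible draws.
#' @return Numeric vector of `n_fields` thicknesses in um.
#' @export
#' @examples
#' p <- default_profile_library()$human
#' sample_field_thicknesses(p, "epidermis", 5, seed = 1)
sample_field_thicknesses <- function(profile, layer, n_fields, seed = 1L) {
  stopifnot(inherits(profile, "skin_profile"))
  if (!is.numeric(n_fields) || length(n_fields) != 1L || n_fields < 1) {
    stop("n_fields must be a positive integer")
  }
  mu <- layer_mean(profile, layer)
  sd <- profile$cv * mu
  withr::with_seed(as.integer(seed), {
    x <- stats::rnorm(n_fields, mean = mu, sd = sd)
    # truncate at zero by redrawing; vanishingly rare for cv <= 0.3
    while (any(bad <- x <= 0)) {
      x[bad] <- stats::rnorm(sum(bad), mean = mu, sd = sd)
    }
    x
  })
}

layer_mean <- function(profile, layer) {
  if (identical(layer, "epidermis")) return(profile$epidermis_mean)
  if (!layer %in% EPIDERMAL_LAYERS) {
    stop("unknown layer '", layer, "' for model '", profile$model_id, "'")
  }
  profile$layer_means[[layer]]
}

#' Generate a labeled synthetic skin section
#'
#' Renders a vertical section as an integer label raster (see
#' [layer_labels()]): background above a fixed cornified top, the four
#' epidermal layers stacked downward, dermis below. Per column, each layer's
#' thickness is its profile mean plus a share of the sinusoidal rete-ridge
#' undulation (shares proportional to layer means, so the whole epidermis
#' undulates with exactly `undulation_amplitude`) plus independent Gaussian
#' noise with sd `cv * mean`, quantized to pixels and clipped at one pixel.
#' Ground truth is read back from the rendered pixel runs, so downstream
#' thickness measurements can be checked against it exactly. Nuclei are
#' placed uniformly in the basal + spinous compartments; each is DAB
#' (MKI67) positive independently with the profile's positive fraction,
#' otherwise hematoxylin only.
#'
#' @param profile A [skin_profile].
#' @param width_px Image width in pixels (default 400).
#' @param pixel_size Pixel edge length in um (default 0.5).
#' @param seed Integer seed; a fixed seed gives a bit-identical section.
#' @param nucleus_density Expected nuclei per um^2 of basal + spinous area
#'   (default 0.02, about one nucleus per 50 um^2).
#' @param top_margin_px Background rows above the cornified surface.
#' @param dermis_margin_px Minimum dermis rows below the deepest basal pixel.
#' @return A `synthetic_section`: list with `label_image` (integer matrix,
#'   rows = y, columns = x), `pixel_size`, `ground_truth` (data frame with
#'   one row per column: per-layer and epidermis thickness in um), `nuclei`
#'   (data frame `x`, `y` 0-based pixel coordinates, `stain` in
#'   `{"hematoxylin","DAB"}`), `model_id`, `seed`.
#' @export
#' @examples
#' s <- generate_section(default_profile_library()$keraskin, seed = 1)
#' s
generate_section <- function(profile, width_px = 400L, pixel_size = 0.5,
                             seed = 1L, nucleus_density = 0.02,
                             top_margin_px = 10L, dermis_margin_px = 40L) {
  stopifnot(inherits(profile, "skin_profile"))
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px < 1) {
    stop("width_px must be a positive integer")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  width_px <- as.integer(width_px)

  m <- profile$layer_means
  share <- m / sum(m)                       # undulation share per layer
  x_um <- (seq_len(width_px) - 1L) * pixel_size
  sine <- sin(2 * pi * x_um / profile$undulation_period)

  withr::with_seed(as.integer(seed), {
    # per-column, per-layer thickness in pixels (rows = layers)
    px <- vapply(EPIDERMAL_LAYERS, function(l) {
      t_um <- m[[l]] + profile$undulation_amplitude * share[[l]] * sine +
        stats::rnorm(width_px, 0, profile$cv * m[[l]])
      pmax(1L, as.integer(round(t_um / pixel_size)))
    }, integer(width_px))
    px <- matrix(px, nrow = width_px)        # width x 4, robust to width 1
    total <- rowSums(px)
    height <- as.integer(top_margin_px + max(total) + dermis_margin_px)

    codes <- layer_labels()
    label <- vapply(seq_len(width_px), function(j) {
      c(rep.int(codes[["background"]], top_margin_px),
        rep.int(unname(codes[EPIDERMAL_LAYERS]), px[j, ]),
        rep.int(codes[["dermis"]], height - top_margin_px - total[j]))
    }, integer(height))

    # nuclei: uniform over basal + spinous pixels
    epi_area_um2 <- sum(px[, match(c("spinous", "basal"), EPIDERMAL_LAYERS)]) *
      pixel_size^2
    n_nuc <- stats::rpois(1L, nucleus_density * epi_area_um2)
    cells <- which(label == codes[["spinous"]] | label == codes[["basal"]])
    if (n_nuc > 0L && length(cells) > 0L) {
      pick <- cells[sample.int(length(cells), n_nuc, replace = TRUE)]
      nuclei <- data.frame(
        x = ((pick - 1L) %/% height),        # 0-based column
        y = ((pick - 1L) %% height),         # 0-based row
        stain = ifelse(
          stats::runif(n_nuc) < profile$mki67_positive_fraction,
          "DAB", "hematoxylin"),
        stringsAsFactors = FALSE)
    } else {
      nuclei <- data.frame(x = integer(), y = integer(),
                           stain = character(), stringsAsFactors = FALSE)
    }

    gt <- data.frame(column = seq_len(width_px) - 1L)
    for (l in EPIDERMAL_LAYERS) {
      gt[[l]] <- px[, match(l, EPIDERMAL_LAYERS)] * pixel_size
    }
    gt$epidermis <- total * pixel_size

    structure(
      list(label_image = label, pixel_size = pixel_size, ground_truth = gt,
           nuclei = nuclei, model_id = profile$model_id,
           seed = as.integer(seed)),
      class = "synthetic_section")
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  d <- dim(x$label_image)
  cat("<synthetic_section> model ", x$model_id, ", ",
      d[2], " x ", d[1], " px at ", x$pixel_size, " um/px\n", sep = "")
  cat(sprintf("  mean epidermis thickness %.2f um (ground truth), %d nuclei (%d DAB+)\n",
              mean(x$ground_truth$epidermis), nrow(x$nuclei),
              sum(x$nuclei$stain == "DAB")))
  invisible(x)
}

#' Write / read a section as plain rasters and CSV sidecars
#'
#' The label image is written as an 8-bit single-channel PNG (pixel value =
#' label code), the per-column ground truth and the nucleus table as CSV
#' (`x`, `y` 0-based, row 0 at top).
#'
#' @param section A `synthetic_section`.
#' @param dir Output directory; files are `<prefix>.png`,
#'   `<prefix>_ground_truth.csv`, `<prefix>_nuclei.csv`.
#' @param prefix File name prefix (defaults to the model id and seed).
#' @return `write_section()` returns the prefix path invisibly;
#'   `read_section()` returns a `synthetic_section` (without a seed).
#' @export
write_section <- function(section, dir,
                          prefix = paste0(section$model_id, "_",
                                          section$seed)) {
  stopifnot(inherits(section, "synthetic_section"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, prefix)
  png::writePNG(section$label_image / 255, paste0(base, ".png"))
  meta <- section$ground_truth
  utils::write.csv(meta, paste0(base, "_ground_truth.csv"), row.names = FALSE)
  utils::write.csv(section$nuclei, paste0(base, "_nuclei.csv"),
                   row.names = FALSE)
  writeLines(as.character(section$pixel_size),
             paste0(base, "_pixel_size_um.txt"))
  invisible(base)
}

#' @rdname write_section
#' @param path Prefix path as returned by `write_section()` (without
#'   extension).
#' @export
read_section <- function(path) {
  img <- png::readPNG(paste0(path, ".png"))
  label <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  gt <- utils::read.csv(paste0(path, "_ground_truth.csv"))
  nuclei <- utils::read.csv(paste0(path, "_nuclei.csv"),
                            colClasses = c("integer", "integer", "character"))
  pixel_size <- as.numeric(readLines(paste0(path, "_pixel_size_um.txt")))
  structure(
    list(label_image = label, pixel_size = pixel_size, ground_truth = gt,
         nuclei = nuclei, model_id = sub("_[0-9]+$", "", basename(path)),
         seed = NA_integer_),
    class = "synthetic_section")
}
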