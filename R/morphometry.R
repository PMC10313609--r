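# QuPath-style thickness morphometry on labeled sections. A "field of view"
# is operationalized as one sampled image column; thickness is the vertical
# pixel run of a layer label scanned bottom-to-top, times the pixel size.

#' Measure per-layer thickness in randomly sampled columns
#'
#' Samples `n_columns` distinct columns uniformly at random and returns, for
#' each, the thickness of the contiguous vertical run of the requested layer
#' label (bottom-most run if a column carries several disjoint runs, matching
#' a consistent bottom-to-top reading) multiplied by the pixel size. Columns
#' lacking the layer contribute 0 (cannot occur in generated sections, which
#' clip every layer at one pixel; can occur in imported masks).
#'
#' @param section A `synthetic_section` (or any list with `label_image` and
#'   `pixel_size` following the [layer_labels()] convention).
#' @param layer One of `"cornified"`, `"granular"`, `"spinous"`, `"basal"`.
#' @param n_columns Number of distinct columns to sample
#'   (1 <= n_columns <= width).
#' @param seed Integer seed for the column sample.
#' @return Numeric vector of `n_columns` thicknesses in um.
#' @export
#' @examples
#' s <- generate_section(default_profile_library()$human, seed = 1)
#' measure_layer_thickness(s, "basal", n_columns = 20, seed = 2)
measure_layer_thickness <- function(section, layer, n_columns = 20L,
                                    seed = 1L) {
  codes <- layer_labels()
  if (!layer %in% EPIDERMAL_LAYERS) {
    stop("unknown layer '", layer, "'")
  }
  cols <- sample_columns(section, n_columns, seed)
  code <- codes[[layer]]
  if (!any(section$label_image == code)) {
    stop("layer not found: '", layer, "' is absent from the image")
  }
  vapply(cols, function(j) {
    run_length_bottom(section$label_image[, j] == code)
  }, numeric(1)) * section$pixel_size
}

#' Measure total epidermal thickness in randomly sampled columns
#'
#' As [measure_layer_thickness()], but the measured run spans all four
#' epidermal labels as one extent: from the bottom of the basal layer to the
#' top of the cornified layer.
#'
#' @inheritParams measure_layer_thickness
#' @return Numeric vector of `n_columns` thicknesses in um.
#' @export
measure_epidermal_thickness <- function(section, n_columns = 20L, seed = 1L) {
  codes <- layer_labels()
  cols <- sample_columns(section, n_columns, seed)
  epi <- unname(codes[EPIDERMAL_LAYERS])
  if (!any(section$label_image %in% epi)) {
    stop("layer not found: no epidermal labels present in the image")
  }
  vapply(cols, function(j) {
    run_length_bottom(section$label_image[, j] %in% epi)
  }, numeric(1)) * section$pixel_size
}

# distinct uniform columns, without replacement
sample_columns <- function(section, n_columns, seed) {
  width <- ncol(section$label_image)
  if (!is.numeric(n_columns) || length(n_columns) != 1L || n_columns < 1 ||
      n_columns > width) {
    stop("n_columns must lie between 1 and the image width (", width, ")")
  }
  withr::with_seed(as.integer(seed),
                   sample.int(width, as.integer(n_columns)))
}

# length of the bottom-most TRUE run in a logical column vector
run_length_bottom <- function(mask) {
  if (!any(mask)) return(0)
  r <- rle(mask)
  sum_true <- which(r$values)
  r$lengths[sum_true[length(sum_true)]]
}

#' Measure a batch of sections into a long-form measurement table
#'
#' Runs the per-layer and whole-epidermis measurements on each section,
#' using the same sampled columns across layers within a section so the
#' column-wise additivity of layer thicknesses is preserved. Fields are
#' numbered consecutively per model.
#'
#' @param sections List of `synthetic_section` objects (possibly several
#'   models).
#' @param layers Character vector of layers to measure; any of
#'   `"epidermis"`, `"cornified"`, `"granular"`, `"spinous"`, `"basal"`.
#' @param n_columns Columns (fields) sampled per section.
#' @param seed Integer seed; per-section sampling seeds are derived from it.
#' @return A `data.frame` with columns `model`, `layer`, `field`,
#'   `thickness_um` (the long-form layer measurement table).
#' @export
measure_sections <- function(sections,
                             layers = c("epidermis", EPIDERMAL_LAYERS),
                             n_columns = 20L, seed = 1L) {
  stopifnot(length(sections) > 0)
  field_counter <- list()
  out <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    sub_seed <- derive_seed(seed, i)
    model <- s$model_id
    start <- field_counter[[model]] %||% 0L
    rows <- lapply(layers, function(l) {
      th <- if (identical(l, "epidermis")) {
        measure_epidermal_thickness(s, n_columns, seed = sub_seed)
      } else {
        measure_layer_thickness(s, l, n_columns, seed = sub_seed)
      }
      data.frame(model = model, layer = l,
                 field = start + seq_along(th), thickness_um = th,
                 stringsAsFactors = FALSE)
    })
    field_counter[[model]] <- start + n_columns
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% .Machine$integer.max)
}

#' Summarize a measurement table as mean, SEM and n per group
#'
#' @param table Long-form measurement table as returned by
#'   [measure_sections()] (columns `model`, `layer`, `field`,
#'   `thickness_um`).
#' @return A `data.frame` with one row per (model, layer): `mean_um`,
#'   `sem_um` (sample sd with n-1 denominator over sqrt(n); `NA` when
#'   n < 2), and `n`.
#' @export
#' @examples
#' tab <- data.frame(model = "m", layer = "basal", field = 1:3,
#'                   thickness_um = c(2, 4, 6))
#' summarize_measurements(tab)  # mean 4, SEM 2/sqrt(3)
summarize_measurements <- function(table) {
  stopifnot(all(c("model", "layer", "thickness_um") %in% names(table)))
  if (any(table$thickness_um < 0)) stop("thickness must be >= 0")
  key <- interaction(table$model, table$layer, drop = TRUE)
  groups <- split(table, key)
  res <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(model = g$model[1], layer = g$layer[1],
               mean_um = mean(g$thickness_um),
               sem_um = if (n >= 2) {
                 stats::sd(g$thickness_um) / sqrt(n)
               } else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(res$model, res$layer), ]
}

#' Mean-thickness matrix from a measurement summary
#'
#' Reshapes the output of [summarize_measurements()] into the models x
#' strata matrix consumed by the scoring functions, with rows in fixed model
#' order (alphabetical: human, keraskin, pig, rabbit for the default
#' library) — the order that also breaks scoring ties.
#'
#' @param summary Data frame with columns `model`, `layer`, `mean_um`.
#' @return Numeric matrix, rownames = models, colnames = strata.
#' @export
mean_thickness_matrix <- function(summary) {
  stopifnot(all(c("model", "layer", "mean_um") %in% names(summary)))
  models <- sort(unique(summary$model))
  strata <- intersect(c(EPIDERMAL_LAYERS, "epidermis"),
                      unique(summary$layer))
  m <- matrix(NA_real_, length(models), length(strata),
              dimnames = list(models, strata))
  for (i in seq_len(nrow(summary))) {
    if (summary$layer[i] %in% strata) {
      m[summary$model[i], summary$layer[i]] <- summary$mean_um[i]
    }
  }
  m
}
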