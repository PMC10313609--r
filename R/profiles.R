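#' @keywords internal
"_PACKAGE"

# Canonical epidermal strata, superficial to deep. Label codes for rasters:
# 0 background, 1 cornified, 2 granular, 3 spinous, 4 basal, 5 dermis.
EPIDERMAL_LAYERS <- c("cornified", "granular", "spinous", "basal")
MODEL_ORDER <- c("human", "keraskin", "pig", "rabbit")
MARKERS <- c("FLG", "CLDN1", "CDH1")

#' Integer label codes used in section rasters
#'
#' Sections are stored as single-channel integer rasters. This vector maps
#' compartment names to the pixel values used throughout the package
#' (row 0 at top, labels in anatomical order background, cornified, granular,
#' spinous, basal, dermis going down a column).
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' layer_labels()
layer_labels <- function() {
  c(background = 0L, cornified = 1L, granular = 2L, spinous = 3L,
    basal = 4L, dermis = 5L)
}

#' Construct a skin-model generative profile
#'
#' A `skin_profile` holds the generative parameters for one skin model: the
#' mean thickness of each epidermal layer, the total epidermal thickness
#' (measured independently in the source protocol, so it need not equal the
#' layer sum, although the bundled defaults are calibrated so it does), the
#' per-field coefficient of variation, the rete-ridge undulation geometry,
#' the fraction of MKI67-positive (proliferating) nuclei, and a qualitative
#' barrier-marker expression panel.
#'
#' @param model_id Character scalar naming the model (e.g. `"human"`).
#' @param layer_means Named numeric vector of mean thicknesses in um for
#'   `cornified`, `granular`, `spinous` and `basal`; all > 0.
#' @param epidermis_mean Mean total epidermal thickness in um (> 0), start of
#'   the epidermis to the end of the cornified layer.
#' @param cv Coefficient of variation of per-field thickness (>= 0).
#' @param undulation_amplitude Peak amplitude in um of the sinusoidal
#'   rete-ridge undulation of the whole epidermis (0 = flat).
#' @param undulation_period Period in um of the undulation (> 0).
#' @param mki67_positive_fraction Probability in \[0, 1\] that an epidermal
#'   nucleus is MKI67 (DAB) positive.
#' @param marker_expression Named logical vector over `FLG`, `CLDN1`, `CDH1`.
#'
#' @return An object of class `skin_profile`.
#' @export
#' @examples
#' skin_profile("toy",
#'   layer_means = c(cornified = 10, granular = 5, spinous = 20, basal = 10),
#'   epidermis_mean = 45, cv = 0.1)
skin_profile <- function(model_id, layer_means, epidermis_mean,
                         cv = 0.2, undulation_amplitude = 0,
                         undulation_period = 100,
                         mki67_positive_fraction = 0,
                         marker_expression = c(FLG = TRUE, CLDN1 = TRUE,
                                               CDH1 = TRUE)) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id))
  if (!all(EPIDERMAL_LAYERS %in% names(layer_means))) {
    stop("layer_means must name all of: ",
         paste(EPIDERMAL_LAYERS, collapse = ", "))
  }
  layer_means <- layer_means[EPIDERMAL_LAYERS]
  if (any(!is.finite(layer_means)) || any(layer_means <= 0)) {
    stop("all layer mean thicknesses must be positive")
  }
  if (!is.finite(epidermis_mean) || epidermis_mean <= 0) {
    stop("epidermis_mean must be positive")
  }
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0")
  if (!is.finite(undulation_amplitude) || undulation_amplitude < 0) {
    stop("undulation_amplitude must be >= 0")
  }
  if (!is.finite(undulation_period) || undulation_period <= 0) {
    stop("undulation_period must be positive")
  }
  if (mki67_positive_fraction < 0 || mki67_positive_fraction > 1) {
    stop("mki67_positive_fraction must lie in [0, 1]")
  }
  if (!all(MARKERS %in% names(marker_expression))) {
    stop("marker_expression must name all of: ",
         paste(MARKERS, collapse = ", "))
  }
  structure(
    list(model_id = model_id,
         layer_means = layer_means,
         epidermis_mean = epidermis_mean,
         cv = cv,
         undulation_amplitude = undulation_amplitude,
         undulation_period = undulation_period,
         mki67_positive_fraction = mki67_positive_fraction,
         marker_expression = as.logical(marker_expression[MARKERS]) |>
           stats::setNames(MARKERS)),
    class = "skin_profile")
}

#' @export
print.skin_profile <- function(x, ...) {
  cat("<skin_profile> ", x$model_id, "\n", sep = "")
  cat(sprintf("  layers (um): cornified %.2f, granular %.2f, spinous %.2f, basal %.2f\n",
              x$layer_means[["cornified"]], x$layer_means[["granular"]],
              x$layer_means[["spinous"]], x$layer_means[["basal"]]))
  cat(sprintf("  epidermis mean %.2f um, cv %.2f\n", x$epidermis_mean, x$cv))
  cat(sprintf("  undulation: amplitude %.1f um, period %.1f um\n",
              x$undulation_amplitude, x$undulation_period))
  cat(sprintf("  MKI67+ fraction %.4f\n", x$mki67_positive_fraction))
  expr <- ifelse(x$marker_expression, "+", "-")
  cat("  markers:", paste0(MARKERS, expr, collapse = " "), "\n")
  invisible(x)
}

#' Default skin-model profile library
#'
#' Returns the four bundled profiles: human skin, Keraskin (a reconstructed
#' human epidermis, flat with no rete ridges), ex vivo pig skin, and rabbit
#' skin. Total epidermal means are the reported values 51.64 um (human),
#' 90.33 um (Keraskin) and 75.47 um (pig); the rabbit epidermis is one third
#' of the human value. Per-layer means are package defaults calibrated so
#' that (i) each model's layers sum exactly to its epidermal mean, (ii) the
#' documented cross-model ratios hold (Keraskin cornified twice the human
#' value, Keraskin granular 4.4x human, rabbit spinous one fifth and basal
#' one half of human), and (iii) the rank-based similarity grid computed from
#' the means reproduces the reference scoring table in full. MKI67-positive
#' fractions are 1.45/8.47/1.73/2.75% for human/Keraskin/pig/rabbit. The
#' marker panel encodes that pig skin lacks FLG and rabbit skin lacks all
#' three human barrier markers.
#'
#' @return Named list of [skin_profile] objects, in fixed model order
#'   human, keraskin, pig, rabbit.
#' @export
#' @examples
#' lib <- default_profile_library()
#' lib$human$epidermis_mean   # 51.64
#' lib$keraskin$undulation_amplitude  # 0: flat RHE
default_profile_library <- function() {
  human_epi <- 51.64
  list(
    human = skin_profile(
      "human",
      layer_means = c(cornified = 15.00, granular = 5.00,
                      spinous = 20.00, basal = 11.64),
      epidermis_mean = human_epi, cv = 0.2,
      undulation_amplitude = 8, undulation_period = 100,
      mki67_positive_fraction = 0.0145,
      marker_expression = c(FLG = TRUE, CLDN1 = TRUE, CDH1 = TRUE)),
    keraskin = skin_profile(
      "keraskin",
      layer_means = c(cornified = 30.00, granular = 22.00,
                      spinous = 26.00, basal = 12.33),
      epidermis_mean = 90.33, cv = 0.2,
      undulation_amplitude = 0, undulation_period = 100,
      mki67_positive_fraction = 0.0847,
      marker_expression = c(FLG = TRUE, CLDN1 = TRUE, CDH1 = TRUE)),
    pig = skin_profile(
      "pig",
      layer_means = c(cornified = 16.30, granular = 16.50,
                      spinous = 25.70, basal = 16.97),
      epidermis_mean = 75.47, cv = 0.2,
      undulation_amplitude = 12, undulation_period = 100,
      mki67_positive_fraction = 0.0173,
      marker_expression = c(FLG = FALSE, CLDN1 = TRUE, CDH1 = TRUE)),
    rabbit = skin_profile(
      "rabbit",
      # spinous = human/5, basal = human/2, epidermis = human/3;
      # cornified takes up the remainder and is the thinnest of the four.
      layer_means = c(cornified = human_epi / 3 - 4.50 - 4.00 - 5.82,
                      granular = 4.50, spinous = 4.00, basal = 5.82),
      epidermis_mean = human_epi / 3, cv = 0.2,
      undulation_amplitude = 0, undulation_period = 100,
      mki67_positive_fraction = 0.0275,
      marker_expression = c(FLG = FALSE, CLDN1 = FALSE, CDH1 = FALSE))
  )
}

#' Read / write a profile library as a YAML config
#'
#' Profiles serialize to a YAML map keyed by model id, one key per field,
#' thicknesses in um. `read_profile_library()` validates every entry through
#' [skin_profile()].
#'
#' @param profiles Named list of [skin_profile] objects.
#' @param path File path of the YAML config.
#' @return `read_profile_library()` returns a named list of profiles;
#'   `write_profile_library()` returns `path` invisibly.
#' @export
write_profile_library <- function(profiles, path) {
  stopifnot(is.list(profiles), length(profiles) > 0)
  out <- lapply(profiles, function(p) {
    list(layer_means_um = as.list(p$layer_means),
         epidermis_mean_um = p$epidermis_mean,
         cv = p$cv,
         undulation_amplitude_um = p$undulation_amplitude,
         undulation_period_um = p$undulation_period,
         mki67_positive_fraction = p$mki67_positive_fraction,
         marker_expression = as.list(p$marker_expression))
  })
  names(out) <- vapply(profiles, `[[`, "", "model_id")
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_profile_library
#' @export
read_profile_library <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- lapply(names(raw), function(id) {
    p <- raw[[id]]
    skin_profile(
      id,
      layer_means = unlist(p$layer_means_um),
      epidermis_mean = p$epidermis_mean_um,
      cv = p$cv,
      undulation_amplitude = p$undulation_amplitude_um,
      undulation_period = p$undulation_period_um,
      mki67_positive_fraction = p$mki67_positive_fraction,
      marker_expression = unlist(p$marker_expression))
  })
  stats::setNames(profiles, names(raw))
}
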