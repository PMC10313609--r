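# Deposition percentages, rank-based similarity scoring between skin models,
# the score heatmap, and the qualitative marker-concordance summary.

#' Deposition percentage of the epidermal layers
#'
#' For each model, expresses the mean thickness of the granular, spinous and
#' basal layers as a percentage of their sum. The cornified layer is
#' excluded by definition (set `include_cornified = TRUE` to add it to both
#' numerators and the denominator).
#'
#' @param means Numeric matrix of mean thicknesses, rownames = models,
#'   colnames including `granular`, `spinous`, `basal` (see
#'   [mean_thickness_matrix()]).
#' @param include_cornified Include the cornified layer in the profile
#'   (default `FALSE`).
#' @return Numeric matrix of percentages (rows = models); each row sums
#'   to 100.
#' @export
#' @examples
#' m <- rbind(toy = c(granular = 10, spinous = 30, basal = 10))
#' deposition_percentages(m)  # 20 / 60 / 20
deposition_percentages <- function(means, include_cornified = FALSE) {
  layers <- c(if (include_cornified) "cornified", "granular", "spinous",
              "basal")
  missing <- setdiff(layers, colnames(means))
  if (length(missing)) {
    stop("missing layer mean(s): ", paste(missing, collapse = ", "))
  }
  sub <- means[, layers, drop = FALSE]
  bad <- which(!is.finite(sub) | sub <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive mean for model '", rownames(sub)[bad[1, 1]],
         "', layer '", colnames(sub)[bad[1, 2]], "'")
  }
  100 * sub / rowSums(sub)
}

#' Rank comparator models by absolute mean-thickness difference
#'
#' For one perspective model and one stratum, computes the absolute
#' difference between the perspective's mean thickness and each comparator's,
#' and assigns ascending ranks: the closest comparator scores 1, the next 2,
#' the furthest 3 (lower score = greater similarity). Ties are broken by
#' fixed model order (the row order of `means`, alphabetical for the default
#' library), with a warning.
#'
#' @param means Numeric matrix of mean thicknesses (rownames = models,
#'   colnames = strata); row order defines the tie-break order.
#' @param perspective Model id whose column of the scoring table is
#'   computed.
#' @param stratum Stratum to score (a column of `means`).
#' @return Named integer vector of scores over the comparator models; always
#'   a permutation of `1:(number of comparators)`.
#' @export
#' @examples
#' epi <- cbind(epidermis = c(human = 51.64, keraskin = 90.33,
#'                            pig = 75.47, rabbit = 51.64 / 3))
#' rank_scores(epi, "pig", "epidermis")   # keraskin 1, human 2, rabbit 3
rank_scores <- function(means, perspective, stratum) {
  if (!perspective %in% rownames(means)) {
    stop("unknown perspective model '", perspective, "'")
  }
  if (!stratum %in% colnames(means)) {
    stop("unknown stratum '", stratum, "'")
  }
  comparators <- setdiff(rownames(means), perspective)
  if (length(comparators) < 2L) {
    stop("need at least 2 comparator models, got ", length(comparators))
  }
  d <- abs(means[perspective, stratum] - means[comparators, stratum])
  if (anyNA(d)) stop("missing mean thickness for stratum '", stratum, "'")
  if (anyDuplicated(d)) {
    warning("tied absolute differences for '", perspective, "' / '",
            stratum, "'; broken by fixed model order")
  }
  r <- rank(d, ties.method = "first")
  stats::setNames(as.integer(r), comparators)
}

#' Full similarity score matrix across models and strata
#'
#' Applies [rank_scores()] for every perspective model over the five strata
#' (epidermis plus the four layers) and accumulates per-comparator totals.
#' Totals range from 5 (closest possible) to 15 (furthest possible), and
#' for three comparators always sum to 30 within a perspective.
#'
#' @param means Numeric matrix of mean thicknesses with all five strata
#'   (`epidermis`, `cornified`, `granular`, `spinous`, `basal`) and at
#'   least three models.
#' @param strata Strata to score (default all five).
#' @return Object of class `similarity_scores`: list with `scores`
#'   (perspective -> strata x comparators integer matrix), `totals`
#'   (perspective -> named integer vector), `strata`, `models`.
#' @export
#' @examples
#' lib <- default_profile_library()
#' means <- profile_mean_matrix(lib)
#' similarity_scores(means)
similarity_scores <- function(means,
                              strata = c("epidermis", EPIDERMAL_LAYERS)) {
  missing <- setdiff(strata, colnames(means))
  if (length(missing)) {
    stop("missing stratum mean(s): ", paste(missing, collapse = ", "))
  }
  models <- rownames(means)
  scores <- lapply(models, function(p) {
    comp <- setdiff(models, p)
    m <- vapply(strata, function(s) rank_scores(means, p, s),
                integer(length(comp)))
    t(matrix(m, nrow = length(comp), dimnames = list(comp, strata)))
  })
  names(scores) <- models
  totals <- lapply(scores, colSums)
  structure(list(scores = scores,
                 totals = lapply(totals, function(x) {
                   stats::setNames(as.integer(x), names(x))
                 }),
                 strata = strata, models = models),
            class = "similarity_scores")
}

#' Mean-thickness matrix straight from a profile library
#'
#' Convenience accessor building the models x strata matrix of configured
#' (not measured) mean thicknesses from a profile library, e.g. to score the
#' models from their calibrated means.
#'
#' @param profiles Named list of [skin_profile] objects.
#' @return Numeric matrix, rownames = model ids (library order), columns
#'   `cornified`, `granular`, `spinous`, `basal`, `epidermis`.
#' @export
profile_mean_matrix <- function(profiles) {
  m <- t(vapply(profiles, function(p) {
    c(p$layer_means, epidermis = p$epidermis_mean)
  }, numeric(5)))
  rownames(m) <- unname(vapply(profiles, `[[`, "", "model_id"))
  m
}

#' Per-comparator total similarity scores
#'
#' Sums each perspective's per-stratum scores over the five strata. Errors
#' if any stratum is missing from the matrix.
#'
#' @param x A `similarity_scores` object, or a list mapping perspective to a
#'   strata x comparators score matrix.
#' @param strata Strata that must be present (default the five used
#'   throughout).
#' @return Named list: perspective -> named integer vector of totals.
#' @export
#' @examples
#' # per-layer scores of a reference table can be totalled directly:
#' h <- rbind(epidermis = c(keraskin = 3, pig = 1, rabbit = 2),
#'            cornified = c(3, 1, 2), granular = c(3, 2, 1),
#'            spinous = c(2, 1, 3), basal = c(1, 2, 3))
#' total_scores(list(human = h))
total_scores <- function(x, strata = c("epidermis", EPIDERMAL_LAYERS)) {
  scores <- if (inherits(x, "similarity_scores")) x$scores else x
  lapply(scores, function(m) {
    missing <- setdiff(strata, rownames(m))
    if (length(missing)) {
      stop("missing stratum score(s): ", paste(missing, collapse = ", "))
    }
    colSums(m[strata, , drop = FALSE]) |>
      (\(v) stats::setNames(as.integer(v), colnames(m)))()
  })
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat("<similarity_scores> perspectives:",
      paste(x$models, collapse = ", "), "\n")
  for (p in x$models) {
    cat("\n", p, " vs:\n", sep = "")
    print(rbind(x$scores[[p]], total = x$totals[[p]]))
  }
  invisible(x)
}

#' Ordered numeric grids for the similarity heatmap
#'
#' Flattens a `similarity_scores` object into per-stratum grids and a totals
#' grid in fixed model order, with `NA` on the (excluded) self-comparison
#' diagonal. `plot()` on the result renders a raster heatmap with a monotone
#' white-to-red ramp (deeper color = higher score = lower similarity).
#'
#' @param x A `similarity_scores` object.
#' @return Object of class `similarity_heatmap`: list of `layer_grids`
#'   (stratum -> perspective x comparator matrix) and `totals` (matrix).
#' @export
heatmap_matrix <- function(x) {
  stopifnot(inherits(x, "similarity_scores"))
  models <- x$models
  grid_for <- function(get) {
    g <- matrix(NA_real_, length(models), length(models),
                dimnames = list(perspective = models, comparator = models))
    for (p in models) {
      v <- get(p)
      g[p, names(v)] <- v
    }
    g
  }
  layer_grids <- lapply(x$strata, function(s) {
    grid_for(function(p) x$scores[[p]][s, ])
  })
  names(layer_grids) <- x$strata
  structure(list(layer_grids = layer_grids,
                 totals = grid_for(function(p) x$totals[[p]])),
            class = "similarity_heatmap")
}

#' @export
plot.similarity_heatmap <- function(x, which = "totals", ...) {
  g <- if (identical(which, "totals")) x$totals else x$layer_grids[[which]]
  if (is.null(g)) stop("unknown grid '", which, "'")
  ramp <- grDevices::colorRampPalette(c("#FFF5F0", "#67000D"))(64)
  n <- ncol(g)
  # transpose + reverse rows so the matrix prints as displayed
  graphics::image(seq_len(n), seq_len(n), t(g[n:1, ]), col = ramp,
                  axes = FALSE, xlab = "comparator", ylab = "perspective",
                  main = paste("similarity scores:", which), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(g), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(g)), las = 2)
  invisible(x)
}

#' Marker-panel concordance with a reference model
#'
#' Given a qualitative expression panel (models x markers logical matrix)
#' and a reference model expressing every marker, returns the fraction of
#' markers each model shares with the reference.
#'
#' @param panel Logical matrix, rownames = models, colnames = markers
#'   (default panel: FLG, CLDN1, CDH1), or a named list of named logical
#'   vectors.
#' @param reference Reference model id (default `"human"`).
#' @return Named numeric vector of concordance fractions in \[0, 1\].
#' @export
#' @examples
#' lib <- default_profile_library()
#' panel <- t(vapply(lib, `[[`, logical(3), "marker_expression"))
#' marker_concordance(panel)  # pig 2/3, rabbit 0, keraskin 1
marker_concordance <- function(panel, reference = "human") {
  if (is.list(panel)) panel <- do.call(rbind, panel)
  if (anyNA(panel)) stop("incomplete marker panel: NA entries present")
  if (!reference %in% rownames(panel)) {
    stop("reference model '", reference, "' not in panel")
  }
  ref <- panel[reference, ]
  if (!all(ref)) {
    stop("reference model must express all panel markers")
  }
  apply(panel, 1, function(row) mean(row == ref))
}
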