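# MKI67 proliferation index from DAB/hematoxylin nucleus tables.

#' Assign nuclei to equal-width vertical zones
#'
#' Partitions a field into `n_zones` equal-width vertical bands with
#' half-open intervals `[start, end)` (the final band absorbs the right
#' edge) and assigns every nucleus to exactly one zone by its 0-based x
#' coordinate.
#'
#' @param nuclei Data frame with a 0-based integer column `x` (and
#'   typically `y`, `stain`), e.g. the `nuclei` component of a
#'   `synthetic_section`.
#' @param width_px Field width in pixels (> 0).
#' @param n_zones Number of zones (default 4).
#' @return Integer vector of zone ids in `1:n_zones`, one per nucleus.
#' @export
#' @examples
#' split_zones(data.frame(x = c(10, 99)), width_px = 100)  # zones 1, 4
split_zones <- function(nuclei, width_px, n_zones = 4L) {
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px <= 0) {
    stop("width_px must be positive")
  }
  if (n_zones < 1L) stop("n_zones must be >= 1")
  x <- nuclei$x
  if (any(x < 0 | x >= width_px)) {
    stop("nucleus x coordinates must lie in [0, width_px)")
  }
  pmin(as.integer(floor(x * n_zones / width_px)) + 1L, as.integer(n_zones))
}

#' MKI67 (DAB-positive) proliferation index
#'
#' The percentage of DAB-positive nuclei among all nuclei
#' (hematoxylin + DAB), i.e. the Ki-67 labeling index.
#'
#' @param nuclei Data frame with a `stain` column taking values
#'   `"hematoxylin"` or `"DAB"`.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' proliferation_index(data.frame(stain = rep(c("DAB", "hematoxylin"),
#'                                            c(17, 183))))  # 8.5
proliferation_index <- function(nuclei) {
  if (nrow(nuclei) == 0L) {
    stop("empty nucleus table: proliferation index is undefined")
  }
  bad <- setdiff(unique(nuclei$stain), c("hematoxylin", "DAB"))
  if (length(bad)) stop("unknown stain value(s): ", paste(bad, collapse = ", "))
  100 * sum(nuclei$stain == "DAB") / nrow(nuclei)
}

#' Per-zone and overall proliferation result for one field
#'
#' Splits the nuclei into vertical zones and reports the per-zone indices,
#' the overall index (total DAB over total nuclei — the nucleus-count
#' weighted mean of the zone indices, not their plain average), and the
#' nucleus count.
#'
#' @inheritParams split_zones
#' @return Object of class `proliferation_result`: list with
#'   `zone_indices` (percentages, `NA` for empty zones), `overall_index`,
#'   `n_nuclei`, `n_zones`.
#' @export
proliferation_result <- function(nuclei, width_px, n_zones = 4L) {
  zones <- split_zones(nuclei, width_px, n_zones)
  zone_idx <- vapply(seq_len(n_zones), function(z) {
    sub <- nuclei[zones == z, , drop = FALSE]
    if (nrow(sub) == 0L) NA_real_ else proliferation_index(sub)
  }, numeric(1))
  structure(list(zone_indices = zone_idx,
                 overall_index = proliferation_index(nuclei),
                 n_nuclei = nrow(nuclei),
                 n_zones = as.integer(n_zones)),
            class = "proliferation_result")
}

#' @export
print.proliferation_result <- function(x, ...) {
  cat("<proliferation_result> ", x$n_nuclei, " nuclei, overall index ",
      sprintf("%.2f%%", x$overall_index), "\n", sep = "")
  cat("  zones:", paste(sprintf("%.2f%%", x$zone_indices), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pool nucleus tables from simulated sections until a target count
#'
#' Generates sections from one profile with consecutive derived seeds and
#' accumulates their nucleus tables until at least `min_nuclei` nuclei are
#' collected; used for stable proliferation-index estimation.
#'
#' @param profile A [skin_profile].
#' @param min_nuclei Minimum pooled nucleus count (default 10000).
#' @param seed Integer seed; per-section seeds are derived from it.
#' @param ... Passed on to [generate_section()].
#' @return Data frame of pooled nuclei (`x`, `y`, `stain`, `section`).
#' @export
pool_nuclei <- function(profile, min_nuclei = 10000L, seed = 1L, ...) {
  pooled <- list()
  total <- 0L
  i <- 0L
  while (total < min_nuclei) {
    i <- i + 1L
    s <- generate_section(profile, seed = derive_seed(seed, i), ...)
    if (nrow(s$nuclei)) {
      pooled[[i]] <- cbind(s$nuclei, section = i)
      total <- total + nrow(s$nuclei)
    }
    if (i > 100000L) stop("failed to accumulate nuclei; check the profile")
  }
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
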