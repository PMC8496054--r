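# Nuclear-to-cytoplasmic ratio quantification from two-channel fields:
# segment nuclei from the DAPI channel, obtain the cytoplasm by subtracting
# the nuclear area from the stained cell region, measure mean intensities in
# each compartment, and stratify fields by cell density.

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing followed by Otsu thresholding and connected-component
#' labelling; components smaller than `min_area` pixels are discarded.
#'
#' @param dapi Numeric matrix (one channel).
#' @param sigma Gaussian smoothing SD in pixels.
#' @param min_area Minimum component area in pixels.
#' @return List with `mask` (logical matrix), `count` (surviving nuclei)
#'   and `flagged` (`TRUE` when the channel is flat and nothing was
#'   segmented).
#' @export
segment_nuclei <- function(dapi, sigma = 1, min_area = 30) {
  if (length(dapi) == 0) rlang::abort("empty image")
  seg <- threshold_channel(dapi, sigma)
  if (is.null(seg)) {
    return(list(
      mask = matrix(FALSE, nrow(dapi), ncol(dapi)),
      count = 0L, flagged = TRUE
    ))
  }
  labels <- EBImage::bwlabel(seg)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  mask <- matrix(labels %in% keep, nrow(dapi), ncol(dapi))
  list(mask = mask, count = length(keep), flagged = length(keep) == 0)
}

#' Segment the cytoplasm by nuclear subtraction
#'
#' Thresholds the stain channel (smoothed Otsu) to obtain the full cell
#' region and removes the nuclear area, guaranteeing disjoint compartments.
#'
#' @param stain Numeric matrix (stain channel).
#' @param nuclear_mask Logical matrix from [segment_nuclei()], same shape.
#' @param sigma Gaussian smoothing SD in pixels.
#' @return List with `mask` (logical) and `flagged` (`TRUE` when the
#'   cytoplasmic compartment came out empty).
#' @export
segment_cytoplasm <- function(stain, nuclear_mask, sigma = 1) {
  if (!identical(dim(stain), dim(nuclear_mask))) {
    rlang::abort("stain channel and nuclear mask must have the same shape")
  }
  seg <- threshold_channel(stain, sigma)
  mask <- if (is.null(seg)) {
    matrix(FALSE, nrow(stain), ncol(stain))
  } else {
    seg & !nuclear_mask
  }
  list(mask = mask, flagged = !any(mask))
}

# Smooth + Otsu threshold one channel; NULL when the channel is flat.
threshold_channel <- function(channel, sigma) {
  rng <- range(channel)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(NULL)
  }
  scaled <- (channel - rng[1]) / diff(rng)
  smoothed <- if (sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(scaled), sigma = sigma))
  } else {
    scaled
  }
  thr <- EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1))
  smoothed > thr
}

#' Measure a field on given compartment masks
#'
#' Mean stain intensity within the nuclear and cytoplasmic masks and their
#' ratio. An empty compartment yields an undefined (NA) ratio with
#' `undefined = TRUE`; the field is reported, never dropped.
#'
#' @param stain Numeric matrix (stain channel).
#' @param nuclear_mask,cytoplasm_mask Disjoint logical matrices.
#' @param field_id Field identifier.
#' @param nucleus_count Number of nuclei in the field (from segmentation or
#'   ground truth).
#' @return One-row tibble: `field_id`, `nucleus_count`,
#'   `mean_nuclear_intensity`, `mean_cytoplasmic_intensity`, `nc_ratio`,
#'   `undefined`.
#' @export
measure_field <- function(stain, nuclear_mask, cytoplasm_mask,
                          field_id = "field", nucleus_count = NA_integer_) {
  if (any(nuclear_mask & cytoplasm_mask)) {
    rlang::abort("nuclear and cytoplasmic masks must be disjoint")
  }
  mn <- if (any(nuclear_mask)) mean(stain[nuclear_mask]) else NA_real_
  mc <- if (any(cytoplasm_mask)) mean(stain[cytoplasm_mask]) else NA_real_
  ratio <- if (!is.na(mn) && !is.na(mc) && mc > 0) mn / mc else NA_real_
  tibble::tibble(
    field_id = field_id,
    nucleus_count = as.integer(nucleus_count),
    mean_nuclear_intensity = mn,
    mean_cytoplasmic_intensity = mc,
    nc_ratio = ratio,
    undefined = is.na(ratio)
  )
}

#' Segment and measure one two-channel field
#'
#' Full per-field pipeline: nuclear segmentation on the DAPI channel,
#' cytoplasm by subtraction on the stain channel, intensity measurement on
#' the original (unsmoothed) stain channel.
#'
#' @param dapi,stain Numeric matrices of equal shape.
#' @param field_id Field identifier.
#' @param sigma,min_area Segmentation parameters, see [segment_nuclei()].
#' @return One-row tibble as in [measure_field()].
#' @export
quantify_field <- function(dapi, stain, field_id = "field",
                           sigma = 1, min_area = 30) {
  nuc <- segment_nuclei(dapi, sigma = sigma, min_area = min_area)
  cyt <- segment_cytoplasm(stain, nuc$mask, sigma = sigma)
  measure_field(stain, nuc$mask, cyt$mask,
    field_id = field_id, nucleus_count = nuc$count
  )
}

#' Stratify fields by cell density
#'
#' The density threshold is the arithmetic mean nucleus count over all
#' fields with a defined ratio; fields below the threshold are low density,
#' fields at or above it are high density.
#'
#' @param measurements Tibble with `nucleus_count` and `nc_ratio` (e.g.
#'   from [quantify_field()] rows or [simulate_field_measurements()]).
#' @return The measurements with a `density` column (`"low"`/`"high"`,
#'   `NA` for fields with undefined ratio); attribute `threshold`.
#' @export
density_split <- function(measurements) {
  ok <- !is.na(measurements$nc_ratio) & !is.na(measurements$nucleus_count)
  if (sum(ok) < 2) rlang::abort("need at least 2 fields with defined counts")
  threshold <- mean(measurements$nucleus_count[ok])
  out <- measurements |>
    dplyr::mutate(density = dplyr::if_else(
      .data$nucleus_count < threshold, "low", "high"
    ))
  out$density[!ok] <- NA_character_
  if (all(out$density[ok] == "high")) {
    rlang::warn("all fields have equal counts; every field is high density")
  }
  attr(out, "threshold") <- threshold
  out
}

#' Linear regression of the n/c ratio on cell count
#'
#' @param measurements Tibble with `nucleus_count` and `nc_ratio`.
#' @return A `yaptaz_ols` fit of `nc_ratio` on `nucleus_count`.
#' @export
density_regression <- function(measurements) {
  ok <- !is.na(measurements$nc_ratio) & !is.na(measurements$nucleus_count)
  ols_fit(measurements$nucleus_count[ok], measurements$nc_ratio[ok])
}

#' Density analysis of a set of field measurements
#'
#' Splits fields at the mean cell count, compares low- vs high-density n/c
#' ratios by Mann-Whitney U and fits the ratio-on-count regression line.
#'
#' @param measurements Tibble with `field_id`, `nucleus_count`, `nc_ratio`.
#' @return Object of class `density_analysis`: list with `measurements`
#'   (including the `density` column), `threshold`, `mann_whitney`
#'   (a `yaptaz_htest`) and `regression` (a `yaptaz_ols`).
#' @export
density_analysis <- function(measurements) {
  split <- density_split(measurements)
  ok <- !is.na(split$density)
  lo <- split$nc_ratio[ok & split$density == "low"]
  hi <- split$nc_ratio[ok & split$density == "high"]
  mw <- if (length(lo) > 0 && length(hi) > 0) {
    mann_whitney(lo, hi)
  } else {
    NULL
  }
  structure(
    list(
      measurements = split,
      threshold = attr(split, "threshold"),
      mann_whitney = mw,
      regression = density_regression(split)
    ),
    class = "density_analysis"
  )
}

#' @export
print.density_analysis <- function(x, ...) {
  n <- table(x$measurements$density)
  cat(sprintf(
    "Density analysis of %d fields (threshold %.2f nuclei/field)\n",
    nrow(x$measurements), x$threshold
  ))
  cat(sprintf(
    "  low: %d fields, high: %d fields\n",
    n[["low"]] %||% 0L, n[["high"]] %||% 0L
  ))
  if (!is.null(x$mann_whitney)) {
    cat(sprintf(
      "  Mann-Whitney U = %g, p = %.3g %s\n",
      x$mann_whitney$statistic, x$mann_whitney$p_value,
      significance_stars(x$mann_whitney$p_value)
    ))
  }
  cat(sprintf(
    "  regression: nc_ratio = %.4g %+.4g * count\n",
    x$regression$intercept, x$regression$slope
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap fraction between a segmented and a reference mask
#'
#' Fraction of reference-mask pixels recovered by the segmented mask
#' (recall); used to validate segmentation against generator ground truth.
#'
#' @param segmented,reference Logical matrices of equal shape.
#' @return Numeric scalar in `[0, 1]` (`NA` for an empty reference).
#' @export
mask_recall <- function(segmented, reference) {
  if (!any(reference)) {
    return(NA_real_)
  }
  sum(segmented & reference) / sum(reference)
}
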