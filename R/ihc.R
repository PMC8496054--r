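# Semiquantitative IHC scoring on tissue-microarray cohorts: per-core
# quantity x intensity products, per-tumor duplicate-core means, score
# classes, positivity calls and the cross-tabulation of marker positivity.

# Means achievable by averaging two core products (plus single-core values).
achievable_mean_scores <- function() {
  sort(unique(c(
    outer(ACHIEVABLE_PRODUCTS, ACHIEVABLE_PRODUCTS, `+`) / 2,
    ACHIEVABLE_PRODUCTS
  )))
}

#' Per-core IHC score
#'
#' Product of the quantity code (0-4: none, <1%, 1-9%, 10-50%, >50% positive
#' cells) and the intensity code (0-3: none, low, medium, strong), giving a
#' score in 0-12 confined to the achievable products
#' `{0, 1, 2, 3, 4, 6, 8, 9, 12}`.
#'
#' @param quantity Integer vector with values in 0-4.
#' @param intensity Integer vector with values in 0-3.
#' @return Integer vector of products.
#' @export
#' @examples
#' core_score(4, 3) # 12
core_score <- function(quantity, intensity) {
  bad_q <- which(!quantity %in% 0:4)
  bad_i <- which(!intensity %in% 0:3)
  if (length(bad_q) > 0) {
    rlang::abort(paste0(
      "quantity out of range 0-4 at row(s) ",
      paste(utils::head(bad_q, 5), collapse = ", ")
    ))
  }
  if (length(bad_i) > 0) {
    rlang::abort(paste0(
      "intensity out of range 0-3 at row(s) ",
      paste(utils::head(bad_i, 5), collapse = ", ")
    ))
  }
  as.integer(quantity) * as.integer(intensity)
}

#' Per-tumor mean score from duplicate cores
#'
#' Arithmetic mean of the two core products. A single available core (a
#' degenerate but allowed input) is carried through unchanged and flagged.
#'
#' @param products Numeric vector of 1 or 2 core products.
#' @return A list with `mean_score` and `single_core` (logical flag).
#' @export
tumor_mean_score <- function(products) {
  products <- products[!is.na(products)]
  if (length(products) == 0) rlang::abort("no core scores available")
  if (length(products) > 2) rlang::abort("at most two cores per tumor")
  if (!all(products %in% ACHIEVABLE_PRODUCTS)) {
    rlang::abort("core products must be achievable quantity x intensity values")
  }
  list(mean_score = mean(products), single_core = length(products) == 1)
}

#' Classify a mean IHC score
#'
#' Low/no expression for mean scores 0-3, intermediate positivity for
#' 3.5-7.5, high positivity for 8-12. Values off the achievable half-step
#' grid (e.g. 3.2) are rejected: they cannot arise from two valid cores.
#'
#' @param mean_score Numeric vector of achievable mean scores.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
#' @examples
#' classify_score(c(3, 3.5, 8))
classify_score <- function(mean_score) {
  grid <- achievable_mean_scores()
  off <- which(!vapply(
    mean_score,
    function(v) any(abs(v - grid) < 1e-9), logical(1)
  ))
  if (length(off) > 0) {
    rlang::abort(paste0(
      "mean score not achievable from two cores: ",
      paste(unique(mean_score[off]), collapse = ", ")
    ))
  }
  cut(mean_score,
    breaks = c(-Inf, 3.25, 7.75, Inf),
    labels = c("low", "intermediate", "high")
  )
}

#' Marker positivity call
#'
#' @param mean_score Numeric vector of mean scores.
#' @param threshold Half-step threshold (default 0).
#' @param mode `"greater"` (default; any staining above the threshold
#'   counts) or `"at_least"` (threshold itself counts as positive).
#' @return Logical vector.
#' @export
positivity_call <- function(mean_score, threshold = 0,
                            mode = c("greater", "at_least")) {
  mode <- match.arg(mode)
  if (mode == "greater") mean_score > threshold else mean_score >= threshold
}

#' Score a TMA cohort per tumor
#'
#' Computes per-core products, averages the duplicate cores per
#' (tumor, marker, compartment), classifies the mean and calls positivity.
#'
#' @param cores Tibble of core observations: `tumor_id`, `core_id`,
#'   `marker`, `compartment`, `quantity`, `intensity`, optionally `grade`.
#' @param threshold,mode Passed to [positivity_call()].
#' @return Tibble: one row per (tumor, marker, compartment) with
#'   `core_score_1`, `core_score_2`, `mean_score`, `single_core`,
#'   `score_class`, `positive` (and `grade` when present).
#' @export
score_tumors <- function(cores, threshold = 0,
                         mode = c("greater", "at_least")) {
  mode <- match.arg(mode)
  required <- c("tumor_id", "core_id", "marker", "compartment",
                "quantity", "intensity")
  missing_cols <- setdiff(required, names(cores))
  if (length(missing_cols) > 0) {
    rlang::abort(paste(
      "missing columns:", paste(missing_cols, collapse = ", ")
    ))
  }
  scored <- cores |>
    dplyr::mutate(product = core_score(.data$quantity, .data$intensity))
  grade_col <- if ("grade" %in% names(cores)) {
    scored |>
      dplyr::distinct(.data$tumor_id, .data$grade)
  } else {
    NULL
  }
  out <- scored |>
    dplyr::group_by(.data$tumor_id, .data$marker, .data$compartment) |>
    dplyr::summarise(
      core_score_1 = .data$product[match(1L, .data$core_id)],
      core_score_2 = .data$product[match(2L, .data$core_id)],
      n_cores = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_cores > 2)) {
    rlang::abort("more than two cores found for a (tumor, marker, compartment)")
  }
  out <- out |>
    dplyr::mutate(
      mean_score = purrr::map2_dbl(
        .data$core_score_1, .data$core_score_2,
        ~ tumor_mean_score(c(.x, .y))$mean_score
      ),
      single_core = is.na(.data$core_score_1) | is.na(.data$core_score_2),
      score_class = classify_score(.data$mean_score),
      positive = positivity_call(.data$mean_score, threshold, mode)
    ) |>
    dplyr::select(-"n_cores")
  if (!is.null(grade_col)) {
    out <- dplyr::left_join(out, grade_col, by = "tumor_id")
  }
  out
}

#' Positivity cross-tabulation row from marginal counts
#'
#' Given the number of tumors positive for each of two markers and for both
#' jointly, derives the exactly-one-marker count (`a + b - 2 * both`) and
#' the percentages of the cohort, rounded to one decimal.
#'
#' @param n_a,n_b Positive counts for the two markers.
#' @param n_both Count positive for both.
#' @param n Cohort size.
#' @return One-row tibble with counts and percentages.
#' @export
#' @examples
#' positivity_row_from_counts(37, 83, 29, 126) # exactly-one = 62 (49.2%)
positivity_row_from_counts <- function(n_a, n_b, n_both, n) {
  if (n_both > min(n_a, n_b)) {
    rlang::abort("joint count cannot exceed either marginal")
  }
  if (max(n_a, n_b) > n) rlang::abort("counts cannot exceed cohort size")
  exactly_one <- n_a + n_b - 2 * n_both
  tibble::tibble(
    n = n,
    yap = n_a, taz = n_b, exactly_one = exactly_one, both = n_both,
    yap_pct = round(100 * n_a / n, 1),
    taz_pct = round(100 * n_b / n, 1),
    exactly_one_pct = round(100 * exactly_one / n, 1),
    both_pct = round(100 * n_both / n, 1)
  )
}

#' Positivity cross-tabulation of YAP and TAZ calls
#'
#' Builds the three-row table (nuclear, cytoplasmic, and their union:
#' positive in either compartment) against four columns: YAP-positive,
#' TAZ-positive, exactly one of the two, and both. "Exactly one" is the
#' exclusive-or count `YAP + TAZ - 2 * both`.
#'
#' @param calls Tibble with `tumor_id`, `marker` (`"YAP"`/`"TAZ"`),
#'   `compartment` (`"nuclear"`/`"cytoplasmic"`) and logical `positive` —
#'   one row per combination, e.g. from [score_tumors()].
#' @param cohort_label Label attached to the table.
#' @return Tibble of class `positivity_table`: one row per compartment row
#'   with counts and one-decimal percentages; attribute `cohort_label`.
#' @export
positivity_table <- function(calls, cohort_label = "cohort") {
  needed <- c("tumor_id", "marker", "compartment", "positive")
  if (!all(needed %in% names(calls))) {
    rlang::abort(paste(
      "calls must have columns:", paste(needed, collapse = ", ")
    ))
  }
  if (anyDuplicated(calls[, c("tumor_id", "marker", "compartment")]) > 0) {
    rlang::abort("duplicated tumor ids within a (marker, compartment)")
  }
  wide <- calls |>
    dplyr::filter(.data$marker %in% c("YAP", "TAZ")) |>
    tidyr::pivot_wider(
      id_cols = "tumor_id",
      names_from = c("marker", "compartment"),
      values_from = "positive"
    )
  needed_wide <- c(
    "YAP_nuclear", "TAZ_nuclear", "YAP_cytoplasmic", "TAZ_cytoplasmic"
  )
  if (!all(needed_wide %in% names(wide)) || anyNA(wide[needed_wide])) {
    rlang::abort("every tumor needs calls for YAP and TAZ in both compartments")
  }
  n <- nrow(wide)
  row_tab <- function(yap, taz) {
    positivity_row_from_counts(sum(yap), sum(taz), sum(yap & taz), n)
  }
  out <- dplyr::bind_rows(
    nuclear = row_tab(wide$YAP_nuclear, wide$TAZ_nuclear),
    cytoplasmic = row_tab(wide$YAP_cytoplasmic, wide$TAZ_cytoplasmic),
    union = row_tab(
      wide$YAP_nuclear | wide$YAP_cytoplasmic,
      wide$TAZ_nuclear | wide$TAZ_cytoplasmic
    ),
    .id = "row"
  )
  attr(out, "cohort_label") <- cohort_label
  class(out) <- c("positivity_table", class(out))
  out
}

#' Merge G3 and G4 grades
#'
#' Recodes tumor grade so that G3 and G4 form one category (`"G3/G4"`),
#' reflecting that G4 tumors are too rare for a separate stratum.
#'
#' @param grade Character or factor vector of grades `G1..G4`.
#' @return Ordered factor with levels `G1`, `G2`, `G3/G4`.
#' @export
merge_high_grade <- function(grade) {
  g <- as.character(grade)
  g[g %in% c("G3", "G4")] <- "G3/G4"
  factor(g, levels = c("G1", "G2", "G3/G4"), ordered = TRUE)
}

#' Correlate two per-tumor variables by Spearman rank
#'
#' Ordinal-friendly association between per-tumor scores, marker calls or
#' (merged) grade; delegates to [spearman_cor()]. Factors are converted to
#' their integer codes, so use ordered factors for ordinal variables.
#'
#' @param data Tibble with one row per tumor.
#' @param var1,var2 Column names (strings or bare names).
#' @return A `yaptaz_htest` (rho, two-sided p).
#' @export
ihc_correlate <- function(data, var1, var2) {
  v1 <- rlang::as_name(rlang::enquo(var1))
  v2 <- rlang::as_name(rlang::enquo(var2))
  to_num <- function(v) {
    if (is.factor(v) || is.character(v)) as.numeric(factor(v)) else as.numeric(v)
  }
  spearman_cor(to_num(data[[v1]]), to_num(data[[v2]]))
}

#' Reference cholangiocarcinoma cohort bookkeeping
#'
#' Grade composition of the three TMA cohorts (intrahepatic, perihilar and
#' distal CCA) used as default study conditions, plus the differential
#' expression gene counts from the knockdown profiling experiment.
#'
#' @return A list with `grading` (tibble: cohort, grade, count) and
#'   `de_genes` (tibble: direction, count).
#' @export
cca_reference_cohorts <- function() {
  list(
    grading = tibble::tribble(
      ~cohort, ~grade, ~count,
      "iCCA", "G1", 9L, "iCCA", "G2", 98L, "iCCA", "G3", 42L, "iCCA", "G4", 3L,
      "pCCA", "G1", 8L, "pCCA", "G2", 114L, "pCCA", "G3", 33L, "pCCA", "G4", 0L,
      "dCCA", "G1", 1L, "dCCA", "G2", 84L, "dCCA", "G3", 41L, "dCCA", "G4", 0L
    ),
    de_genes = tibble::tibble(
      direction = c("up", "down"),
      count = c(269L, 273L)
    )
  )
}
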