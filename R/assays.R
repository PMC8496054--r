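# Knockdown functional readouts: reference-gene-normalized relative
# expression (2^-ddCt) and fold-of-control assay normalization.

#' Relative expression by the 2^-ddCt method
#'
#' For each (gene, condition): `dCt = mean Ct(target) - mean Ct(reference)`
#' within the condition; `ddCt = dCt(condition) - dCt(control)`;
#' `rq = base^-ddCt`. Replicates are aggregated by mean Ct before
#' differencing (default) or, alternatively, per-replicate RQ values are
#' averaged. Replicate dispersion is reported as the SD of per-replicate RQ
#' in both modes.
#'
#' @param ct Tibble of Ct records: `condition`, `gene`, `replicate`, `ct`
#'   (cycles, > 0).
#' @param reference Reference gene symbol (present in every condition).
#' @param control Control condition label (default `"scrambled"`).
#' @param base Amplification efficiency base (default 2 = perfect doubling).
#' @param aggregate `"mean_ct"` (default) or `"per_replicate"`.
#' @return Tibble: `condition`, `gene`, `delta_ct`, `delta_delta_ct`, `rq`,
#'   `rq_sd`, `n_replicates`. The control condition has `rq = 1` for every
#'   gene by construction.
#' @export
ddct <- function(ct, reference = "B2M", control = "scrambled", base = 2,
                 aggregate = c("mean_ct", "per_replicate")) {
  aggregate <- match.arg(aggregate)
  needed <- c("condition", "gene", "replicate", "ct")
  if (!all(needed %in% names(ct))) {
    rlang::abort(paste("ct table needs columns:", paste(needed, collapse = ", ")))
  }
  if (any(ct$ct <= 0)) rlang::abort("Ct values must be positive")
  if (!control %in% ct$condition) {
    rlang::abort(paste0("control condition '", control, "' not found"))
  }
  ref <- ct |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  missing_ref <- setdiff(unique(ct$condition), ref$condition)
  if (length(missing_ref) > 0) {
    rlang::abort(paste0(
      "reference gene '", reference, "' missing in condition(s): ",
      paste(missing_ref, collapse = ", ")
    ))
  }
  targets <- ct |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::left_join(ref, by = "condition") |>
    dplyr::mutate(dct_rep = .data$ct - .data$ref_ct)

  per_cond <- targets |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      delta_ct = mean(.data$dct_rep),
      dct_reps = list(.data$dct_rep),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  ctrl_dct <- per_cond |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select("gene", control_dct = "delta_ct")
  missing_ctrl <- setdiff(unique(per_cond$gene), ctrl_dct$gene)
  if (length(missing_ctrl) > 0) {
    rlang::abort(paste0(
      "no control-condition measurements for gene(s): ",
      paste(missing_ctrl, collapse = ", ")
    ))
  }
  out <- per_cond |>
    dplyr::left_join(ctrl_dct, by = "gene") |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - .data$control_dct,
      rq_reps = purrr::map2(
        .data$dct_reps, .data$control_dct,
        ~ base^-(.x - .y)
      ),
      rq = dplyr::if_else(
        rep(aggregate == "mean_ct", dplyr::n()),
        base^-.data$delta_delta_ct,
        purrr::map_dbl(.data$rq_reps, mean)
      ),
      rq_sd = purrr::map_dbl(.data$rq_reps, stats::sd)
    ) |>
    dplyr::select(
      "condition", "gene", "delta_ct", "delta_delta_ct",
      "rq", "rq_sd", "n_replicates"
    ) |>
    dplyr::arrange(.data$gene, .data$condition)
  out
}

#' Fold-of-control normalization of assay readings
#'
#' Divides every reading by the mean of the control-condition readings
#' (e.g. viability or BrdU proliferation absorbance normalized against
#' scrambled-siRNA-treated cells).
#'
#' @param readings Tibble with `condition` and `value`.
#' @param control Control condition label.
#' @return The tibble with a `normalized` column; control readings average
#'   to 1 by construction.
#' @export
normalize_assay <- function(readings, control = "scrambled") {
  if (!all(c("condition", "value") %in% names(readings))) {
    rlang::abort("readings need columns 'condition' and 'value'")
  }
  ctrl <- readings$value[readings$condition == control]
  if (length(ctrl) == 0) {
    rlang::abort(paste0("control condition '", control, "' is empty"))
  }
  m <- mean(ctrl)
  if (m == 0) rlang::abort("control mean is zero; normalization undefined")
  dplyr::mutate(readings, normalized = .data$value / m)
}

#' Gene-by-condition relative-expression matrix
#'
#' Reshapes a [ddct()] result into a genes x conditions table ready for
#' heatmap display, optionally on the log2(RQ) scale. Requires a complete
#' design (every gene x condition cell present exactly once).
#'
#' @param rq Tibble from [ddct()] with `gene`, `condition`, `rq`.
#' @param log2 Return `log2(rq)` instead of `rq`.
#' @param annotations Optional tibble with `gene` plus annotation columns
#'   (e.g. single- vs combined-silencing response class) joined onto the
#'   result.
#' @return Tibble: `gene`, one column per condition, plus any annotations.
#' @export
condition_heatmap <- function(rq, log2 = FALSE, annotations = NULL) {
  dup <- rq |>
    dplyr::count(.data$gene, .data$condition) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0(
      "duplicate gene x condition cell(s): ",
      paste(paste(dup$gene, dup$condition, sep = "/"), collapse = ", ")
    ))
  }
  vals <- if (log2) dplyr::mutate(rq, rq = log2(.data$rq)) else rq
  wide <- vals |>
    dplyr::select("gene", "condition", "rq") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rq")
  if (anyNA(wide)) {
    rlang::abort("incomplete design: missing gene x condition cells")
  }
  if (!is.null(annotations)) {
    wide <- dplyr::left_join(wide, annotations, by = "gene")
  }
  wide
}
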