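# CIN25 signature workflow: CPM normalization, per-gene z-scaling, summed
# signature score, k-means clustering of the signature submatrix, median
# dichotomization and Kaplan-Meier / log-rank survival stratification.

#' Default CIN25 signature gene set
#'
#' The chromosomal-instability signature comprises 25 genes; this default
#' ships the seven members named in the accompanying analyses (AURKA, AURKB,
#' CCNB1, CCNB2, FOXM1, TOP2A, TTK) plus editable placeholders
#' (`CIN25_08`..`CIN25_25`). Supply the full published membership for real
#' analyses.
#'
#' @return Character vector of 25 gene symbols.
#' @export
cin25_genes <- function() {
  c(
    "AURKA", "AURKB", "CCNB1", "CCNB2", "FOXM1", "TOP2A", "TTK",
    sprintf("CIN25_%02d", 8:25)
  )
}

#' Counts-per-million normalization
#'
#' Scales every sample (column) to a total of one million, optionally
#' followed by a `log2(CPM + 1)` transform.
#'
#' @param counts Numeric gene x sample matrix, no negative entries.
#' @param log2 Apply `log2(CPM + 1)` after scaling.
#' @return Matrix of the same shape.
#' @export
cpm_normalize <- function(counts, log2 = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) rlang::abort("raw counts must be non-negative")
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    rlang::abort(paste0(
      "zero library size for sample(s): ",
      paste(colnames(counts)[zero] %||% zero, collapse = ", ")
    ))
  }
  cpm <- sweep(counts, 2, totals, `/`) * 1e6
  if (log2) log2(cpm + 1) else cpm
}

#' Per-gene z-scaling across samples
#'
#' Centers each gene (row) to mean 0 and scales to unit variance (n - 1
#' denominator) across the supplied samples. Zero-variance genes are left
#' at 0 with a warning.
#'
#' @param mat Numeric gene x sample matrix (typically log2 CPM).
#' @return Matrix of the same shape with scaled rows.
#' @export
scale_genes <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) rlang::abort("need at least 2 samples to scale")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    rlang::warn(paste0(
      sum(flat), " zero-variance gene(s) contribute 0 to scaled values"
    ))
    sdv[flat] <- 1
  }
  (mat - mu) / sdv
}

#' Signature score per sample
#'
#' Scales each signature gene across all supplied samples (so every gene
#' contributes equally) and sums the scaled values per sample. Scores over
#' the scaling population sum to zero by construction.
#'
#' @param mat Numeric gene x sample matrix on the scale to be scored
#'   (typically log2 CPM).
#' @param genes Signature gene symbols; intersected with `rownames(mat)`.
#'   Symbols absent from the matrix are reported via a warning and the
#'   `missing_genes` attribute.
#' @return Tibble: `sample_id`, `score`; attribute `missing_genes`.
#' @export
score_signature <- function(mat, genes = cin25_genes()) {
  mat <- as.matrix(mat)
  present <- intersect(genes, rownames(mat))
  missing <- setdiff(genes, rownames(mat))
  if (length(present) == 0) {
    rlang::abort(paste0(
      "no signature genes found in the matrix; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (length(missing) > 0) {
    rlang::warn(paste0(
      length(missing), " signature gene(s) absent from the matrix: ",
      paste(utils::head(missing, 8), collapse = ", ")
    ))
  }
  scaled <- scale_genes(mat[present, , drop = FALSE])
  out <- tibble::tibble(
    sample_id = colnames(mat) %||% as.character(seq_len(ncol(mat))),
    score = unname(colSums(scaled))
  )
  attr(out, "missing_genes") <- missing
  out
}

#' k-means clustering of samples on the scaled signature submatrix
#'
#' Lloyd's algorithm on the per-gene scaled signature submatrix (samples as
#' points), best of `restarts` random initializations by within-cluster sum
#' of squares, deterministic under the given seed.
#'
#' @param mat Numeric gene x sample matrix (typically log2 CPM).
#' @param genes Signature gene symbols; `NULL` uses all rows.
#' @param k Number of clusters.
#' @param restarts Number of random initializations.
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `cluster` (integer 1..k); attribute
#'   `within_ss`.
#' @export
kmeans_cluster <- function(mat, genes = NULL, k = 3, restarts = 25,
                           seed = 1L) {
  mat <- as.matrix(mat)
  if (!is.null(genes)) {
    present <- intersect(genes, rownames(mat))
    if (length(present) == 0) rlang::abort("no signature genes in the matrix")
    mat <- mat[present, , drop = FALSE]
  }
  if (ncol(mat) < k) rlang::abort("k cannot exceed the number of samples")
  scaled <- scale_genes(mat)
  pts <- t(scaled)
  fit <- with_seed(seed, {
    # Lloyd restarts from bad initializations may leave a cluster empty;
    # such runs lose the nstart comparison and their warning is noise.
    withCallingHandlers(
      stats::kmeans(pts,
        centers = k, nstart = restarts,
        algorithm = "Lloyd", iter.max = 100
      ),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  out <- tibble::tibble(
    sample_id = colnames(mat) %||% as.character(seq_len(ncol(mat))),
    cluster = as.integer(fit$cluster)
  )
  attr(out, "within_ss") <- fit$tot.withinss
  out
}

#' Median dichotomization of signature scores
#'
#' Scores strictly above the median go to `"high"`, scores at or below it
#' to `"low"` (ties deterministically low).
#'
#' @param scores Tibble with `sample_id` and `score` (from
#'   [score_signature()]).
#' @return The tibble with a `group` column.
#' @export
median_split <- function(scores) {
  if (nrow(scores) < 2) rlang::abort("need at least 2 samples")
  med <- stats::median(scores$score)
  out <- scores |>
    dplyr::mutate(group = dplyr::if_else(.data$score > med, "high", "low"))
  if (all(out$group == "low")) {
    rlang::warn("all scores equal; every sample assigned to the low group")
  }
  out
}

#' Kaplan-Meier product-limit curves per group
#'
#' @param data Tibble with `time` (>= 0), `event` (logical or 0/1) and
#'   `group`.
#' @return Object of class `km_curve`: a tibble of curve points (`group`,
#'   `time`, `n_risk`, `n_event`, `survival`), including the `time = 0`,
#'   `survival = 1` anchor per group.
#' @export
km_curve <- function(data) {
  if (any(data$time < 0)) rlang::abort("negative survival times")
  if (nrow(data) < 1) rlang::abort("need at least one record")
  if (!"group" %in% names(data)) data$group <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group,
    data = data
  )
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) {
    rep(unique(data$group), length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  pts <- tibble::tibble(
    group = grp, time = smry$time,
    n_risk = smry$n.risk, n_event = smry$n.event,
    survival = smry$surv
  )
  anchor <- pts |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(
      time = 0, n_risk = NA_integer_, n_event = 0L, survival = 1
    )
  out <- dplyr::bind_rows(anchor, pts) |>
    dplyr::arrange(.data$group, .data$time)
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' Observed-minus-expected chi-square over the pooled event times; two
#' groups give one degree of freedom.
#'
#' @param data Tibble with `time`, `event`, `group` (>= 2 groups, >= 1
#'   event overall).
#' @return A `yaptaz_htest` with the chi-square statistic and `df`.
#' @export
logrank_test <- function(data) {
  if (length(unique(data$group)) < 2) rlang::abort("need at least 2 groups")
  if (sum(data$event) < 1) {
    rlang::abort("log-rank is undefined without any events")
  }
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = data
  )
  df <- length(sd_fit$n) - 1
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  new_htest(
    statistic_name = "chisq", statistic = unname(sd_fit$chisq),
    p_value = p, method = "Log-rank (Mantel-Cox) test",
    exact = FALSE,
    n = stats::setNames(as.integer(sd_fit$n), paste0("n_", names(sd_fit$n))),
    extra = list(df = df)
  )
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Recovery of a planted high-score cluster
#'
#' Identifies the k-means cluster with the highest mean signature score,
#' binarizes the assignment (top cluster vs rest) and compares it to the
#' planted ground truth by adjusted Rand index.
#'
#' @param clusters Tibble from [kmeans_cluster()] (`sample_id`, `cluster`).
#' @param scores Tibble from [score_signature()] (`sample_id`, `score`).
#' @param truth Tibble with `sample_id` and logical `planted`.
#' @return List with `top_cluster`, `top_cluster_size`, `prevalence`
#'   (share of samples in the top cluster), `planted_capture` (share of
#'   planted samples inside it) and `ari`.
#' @export
cluster_recovery <- function(clusters, scores, truth) {
  merged <- clusters |>
    dplyr::inner_join(scores, by = "sample_id") |>
    dplyr::inner_join(truth, by = "sample_id")
  top <- merged |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::slice_max(.data$mean_score, n = 1)
  in_top <- merged$cluster == top$cluster
  list(
    top_cluster = top$cluster,
    top_cluster_size = sum(in_top),
    prevalence = mean(in_top),
    planted_capture = sum(in_top & merged$planted) / sum(merged$planted),
    ari = adjusted_rand_index(in_top, merged$planted)
  )
}
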