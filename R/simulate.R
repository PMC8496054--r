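# Seeded generators for every input family the analysis stages consume.
# Each generator returns its ground truth alongside the observable data so
# downstream stages carry parameter-recovery tests.

ACHIEVABLE_PRODUCTS <- c(0L, 1L, 2L, 3L, 4L, 6L, 8L, 9L, 12L)
POSITIVE_PRODUCTS <- ACHIEVABLE_PRODUCTS[-1]

#' Specification of a synthetic TMA scoring cohort
#'
#' Describes a tissue-microarray cohort: number of tumors, the grade
#' distribution, per-(marker, compartment) positivity probabilities, the
#' distribution of core scores among positive tumors, and the probability
#' that the second core of a tumor repeats the codes of the first.
#'
#' Defaults emulate an intrahepatic cholangiocarcinoma cohort of 152 tumors
#' (grades 9/98/42/3 across G1-G4) with the nuclear and cytoplasmic YAP/TAZ
#' positivity marginals observed in that subtype.
#'
#' @param n_tumors Number of tumors (>= 1).
#' @param grade_probs Named probability vector over `G1..G4`; must sum to 1.
#' @param positivity Tibble with columns `marker`, `compartment`, `prob`:
#'   per-(marker, compartment) probability that a tumor stains positive.
#' @param score_given_positive Named probability vector over the achievable
#'   positive products `{1,2,3,4,6,8,9,12}`; defaults to uniform.
#' @param core_concordance Probability in `[0, 1]` that the second core
#'   carries the same quantity/intensity codes as the first.
#' @param seed Integer seed.
#' @return A list of class `tma_cohort_spec`.
#' @export
tma_cohort_spec <- function(n_tumors = 152,
                            grade_probs = c(G1 = 9, G2 = 98, G3 = 42, G4 = 3) / 152,
                            positivity = tibble::tribble(
                              ~marker, ~compartment, ~prob,
                              "YAP", "nuclear", 0.395,
                              "TAZ", "nuclear", 0.316,
                              "YAP", "cytoplasmic", 0.283,
                              "TAZ", "cytoplasmic", 0.026
                            ),
                            score_given_positive = stats::setNames(
                              rep(1 / 8, 8), as.character(POSITIVE_PRODUCTS)
                            ),
                            core_concordance = 0.8,
                            seed = 1L) {
  if (n_tumors < 1) rlang::abort("n_tumors must be >= 1")
  check_probs(grade_probs, "grade_probs")
  if (abs(sum(grade_probs) - 1) > 1e-8) {
    rlang::abort("grade_probs must sum to 1")
  }
  check_probs(positivity$prob, "positivity$prob")
  check_probs(core_concordance, "core_concordance")
  sgp_products <- as.integer(names(score_given_positive))
  if (!all(sgp_products %in% POSITIVE_PRODUCTS)) {
    rlang::abort("score_given_positive names must be achievable positive products")
  }
  check_probs(score_given_positive, "score_given_positive")
  structure(
    list(
      n_tumors = as.integer(n_tumors), grade_probs = grade_probs,
      positivity = positivity, score_given_positive = score_given_positive,
      core_concordance = core_concordance, seed = as.integer(seed)
    ),
    class = "tma_cohort_spec"
  )
}

check_probs <- function(p, what) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort(paste0(what, " must lie in [0, 1]"))
  }
  invisible(p)
}

# Quantity/intensity factorizations of each achievable positive product.
product_factorizations <- function(product) {
  grid <- expand.grid(quantity = 1:4, intensity = 1:3)
  grid[grid$quantity * grid$intensity == product, , drop = FALSE]
}

# Vectorized draw of (quantity, intensity) codes: negative rows get 0/0,
# positive rows a product from `score_given_positive` decomposed uniformly
# into a valid code pair.
draw_codes <- function(positive, score_given_positive) {
  n <- length(positive)
  quantity <- integer(n)
  intensity <- integer(n)
  idx_pos <- which(positive)
  if (length(idx_pos) > 0) {
    prods <- as.integer(sample(names(score_given_positive), length(idx_pos),
      replace = TRUE, prob = score_given_positive
    ))
    for (p in unique(prods)) {
      fac <- product_factorizations(p)
      rows <- idx_pos[prods == p]
      pick <- sample.int(nrow(fac), length(rows), replace = TRUE)
      quantity[rows] <- fac$quantity[pick]
      intensity[rows] <- fac$intensity[pick]
    }
  }
  tibble::tibble(quantity = quantity, intensity = intensity)
}

#' Simulate a TMA scoring cohort
#'
#' Draws tumor-level positivity per (marker, compartment), grades, and two
#' cores per tumor/marker/compartment with quantity and intensity codes.
#' Positive cores receive a product drawn from `score_given_positive`,
#' decomposed uniformly into a valid (quantity, intensity) pair; negative
#' cores carry code 0/0. The second core repeats the first with probability
#' `core_concordance` and is otherwise redrawn under the same tumor-level
#' positivity.
#'
#' @param spec A [tma_cohort_spec()].
#' @return List with `cores` (tibble: `tumor_id`, `core_id`, `marker`,
#'   `compartment`, `quantity`, `intensity`, `grade`) and `truth` (tibble:
#'   `tumor_id`, `marker`, `compartment`, `positive`).
#' @export
simulate_tma_cohort <- function(spec) {
  stopifnot(inherits(spec, "tma_cohort_spec"))
  with_seed(spec$seed, {
    tumors <- tibble::tibble(
      tumor_id = sprintf("T%03d", seq_len(spec$n_tumors)),
      grade = sample(names(spec$grade_probs), spec$n_tumors,
        replace = TRUE, prob = spec$grade_probs
      )
    )
    truth <- tidyr::crossing(
      tumor_id = tumors$tumor_id,
      spec$positivity
    ) |>
      dplyr::mutate(positive = stats::runif(dplyr::n()) < .data$prob) |>
      dplyr::select("tumor_id", "marker", "compartment", "positive")

    core1 <- draw_codes(truth$positive, spec$score_given_positive)
    concordant <- stats::runif(nrow(truth)) < spec$core_concordance
    core2 <- draw_codes(truth$positive, spec$score_given_positive)
    core2[concordant, ] <- core1[concordant, ]

    cores <- dplyr::bind_rows(
      dplyr::bind_cols(truth, core_id = 1L, core1),
      dplyr::bind_cols(truth, core_id = 2L, core2)
    ) |>
      dplyr::left_join(tumors, by = "tumor_id") |>
      dplyr::arrange(.data$tumor_id, .data$marker, .data$compartment,
        .data$core_id) |>
      dplyr::select(
        "tumor_id", "core_id", "marker", "compartment",
        "quantity", "intensity", "grade"
      )

    list(cores = cores, truth = truth)
  })
}

#' Specification of a synthetic two-channel immunofluorescence field
#'
#' Cells are drawn as concentric disks: a nucleus (DAPI-positive, channel 1)
#' inside a larger cell disk whose annulus forms the cytoplasm. The stain
#' channel (channel 2) carries `nuclear_intensity` on nuclei,
#' `cytoplasmic_intensity` on annuli and `background` elsewhere, plus
#' zero-truncated Gaussian noise. Nuclei are placed without overlap by
#' rejection sampling.
#'
#' @param width,height Field size in pixels.
#' @param n_cells Number of cells to place (may be 0).
#' @param nucleus_radius,cell_radius Length-2 pixel ranges (min, max);
#'   every sampled cell radius must exceed its nucleus radius.
#' @param nuclear_intensity,cytoplasmic_intensity,background Fluorescence
#'   units; `intensities >= background >= 0`.
#' @param noise_sd Gaussian pixel noise SD (truncated at 0).
#' @param seed Integer seed.
#' @return A list of class `if_field_spec`.
#' @export
if_field_spec <- function(width = 192, height = 192, n_cells = 12,
                          nucleus_radius = c(5, 8), cell_radius = c(11, 15),
                          nuclear_intensity = 200, cytoplasmic_intensity = 100,
                          background = 10, noise_sd = 5, seed = 1L) {
  if (min(cell_radius) <= max(nucleus_radius)) {
    rlang::abort("cell_radius must exceed nucleus_radius")
  }
  if (background < 0 || nuclear_intensity < background ||
    cytoplasmic_intensity < background) {
    rlang::abort("need intensities >= background >= 0")
  }
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      n_cells = as.integer(n_cells),
      nucleus_radius = nucleus_radius, cell_radius = cell_radius,
      nuclear_intensity = nuclear_intensity,
      cytoplasmic_intensity = cytoplasmic_intensity,
      background = background, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "if_field_spec"
  )
}

#' Simulate a two-channel immunofluorescence field
#'
#' @param spec An [if_field_spec()].
#' @param field_id Identifier attached to the result.
#' @return List with `dapi` and `stain` (numeric matrices, height x width),
#'   `nuclear_mask` and `cytoplasm_mask` (disjoint logical matrices),
#'   `cells` (tibble of placed centers and radii) and `true_ratio`
#'   (`nuclear_intensity / cytoplasmic_intensity`, `NA` when no cells).
#' @export
simulate_if_field <- function(spec, field_id = "field_1") {
  stopifnot(inherits(spec, "if_field_spec"))
  with_seed(spec$seed, {
    w <- spec$width
    h <- spec$height
    cells <- place_cells(spec)
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    nuclear_mask <- matrix(FALSE, h, w)
    cell_mask <- matrix(FALSE, h, w)
    if (nrow(cells) > 0) {
      for (i in seq_len(nrow(cells))) {
        d2 <- (xs - cells$x[i])^2 + (ys - cells$y[i])^2
        nuclear_mask <- nuclear_mask | (d2 <= cells$nucleus_r[i]^2)
        cell_mask <- cell_mask | (d2 <= cells$cell_r[i]^2)
      }
    }
    cytoplasm_mask <- cell_mask & !nuclear_mask

    dapi <- matrix(0, h, w)
    dapi[nuclear_mask] <- spec$nuclear_intensity
    stain <- matrix(spec$background, h, w)
    stain[cytoplasm_mask] <- spec$cytoplasmic_intensity
    stain[nuclear_mask] <- spec$nuclear_intensity
    if (spec$noise_sd > 0) {
      dapi[] <- pmax(dapi + stats::rnorm(length(dapi), sd = spec$noise_sd), 0)
      stain[] <- pmax(stain + stats::rnorm(length(stain), sd = spec$noise_sd), 0)
    }
    list(
      field_id = field_id, dapi = dapi, stain = stain,
      nuclear_mask = nuclear_mask, cytoplasm_mask = cytoplasm_mask,
      cells = cells,
      true_ratio = if (nrow(cells) > 0) {
        spec$nuclear_intensity / spec$cytoplasmic_intensity
      } else {
        NA_real_
      }
    )
  })
}

place_cells <- function(spec) {
  placed <- tibble::tibble(
    x = numeric(), y = numeric(), nucleus_r = numeric(), cell_r = numeric()
  )
  if (spec$n_cells == 0) {
    return(placed)
  }
  max_attempts <- 200L * spec$n_cells
  attempts <- 0L
  while (nrow(placed) < spec$n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    nr <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
    cr <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
    margin <- cr + 1
    if (spec$width <= 2 * margin || spec$height <= 2 * margin) {
      rlang::abort("field too small for the requested cell radius")
    }
    x <- stats::runif(1, margin, spec$width - margin)
    y <- stats::runif(1, margin, spec$height - margin)
    # nuclei must not overlap (cytoplasm overlap is allowed)
    if (nrow(placed) == 0 ||
      all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >=
        placed$nucleus_r + nr + 2)) {
      placed <- dplyr::bind_rows(
        placed,
        tibble::tibble(x = x, y = y, nucleus_r = nr, cell_r = cr)
      )
    }
  }
  if (nrow(placed) < spec$n_cells) {
    rlang::abort(paste0(
      "could not place ", spec$n_cells, " non-overlapping nuclei in a ",
      spec$width, "x", spec$height,
      " field; the requested cell density exceeds the placement limit"
    ))
  }
  placed
}

#' Simulate per-field measurements with a planted density effect
#'
#' Measurement-level counterpart of [simulate_if_field()]: emits the
#' per-field nucleus counts and nuclear/cytoplasmic ratios directly, with
#' the ratio following `intercept + slope * count` plus Gaussian noise.
#' Used for density-stratification power studies where synthesizing and
#' segmenting full images would add nothing.
#'
#' @param n_fields Number of fields.
#' @param count_range Integer range (min, max) of nucleus counts per field.
#' @param ratio_intercept,ratio_slope Linear dependence of the n/c ratio on
#'   the nucleus count. A negative slope plants density-dependent nuclear
#'   exclusion.
#' @param noise_sd SD of Gaussian noise on the ratio (truncated at 0.05).
#' @param seed Integer seed.
#' @return Tibble: `field_id`, `nucleus_count`, `nc_ratio`.
#' @export
simulate_field_measurements <- function(n_fields = 200,
                                        count_range = c(5, 60),
                                        ratio_intercept = 3,
                                        ratio_slope = -0.03,
                                        noise_sd = 0.25, seed = 1L) {
  with_seed(seed, {
    counts <- sample(seq(count_range[1], count_range[2]), n_fields,
      replace = TRUE
    )
    ratio <- pmax(
      0.05,
      ratio_intercept + ratio_slope * counts +
        stats::rnorm(n_fields, sd = noise_sd)
    )
    tibble::tibble(
      field_id = sprintf("field_%03d", seq_len(n_fields)),
      nucleus_count = as.integer(counts),
      nc_ratio = ratio
    )
  })
}

#' Specification of a synthetic expression + survival cohort
#'
#' Emulates a bulk expression cohort of tumors and normal samples in which a
#' planted fraction of tumors carries a coordinated upregulation of a
#' signature gene set, and survival is tied to that planted state through an
#' exponential hazard.
#'
#' Defaults emulate a 104-tumor / 6-normal cholangiocarcinoma cohort in
#' which 25% of tumors form a high-CIN cluster with a 2 log2-fold
#' coordinated shift of the CIN25 genes and a planted hazard ratio of 2.5
#' against the remaining tumors (times in months, administrative censoring
#' at 60 months).
#'
#' @param n_tumors,n_normals Sample counts.
#' @param genes Character vector of gene symbols (background + signature).
#' @param signature_genes Non-empty subset of `genes` to shift.
#' @param cin_fraction Fraction of tumors planted in the high-CIN cluster;
#'   the planted count is `round(cin_fraction * n_tumors)`.
#' @param effect_log2fc Planted log2 shift of signature genes in that
#'   cluster.
#' @param noise_sd Per-sample log2 dispersion around each gene's baseline.
#' @param library_size_range Range of per-sample sequencing depth (counts).
#' @param baseline_hazard Events per time unit for non-planted tumors.
#' @param log_hazard_per_score_unit Log hazard-ratio per unit of the true
#'   per-sample score (`effect_log2fc * planted`); the default
#'   `log(2.5) / 2` gives a hazard ratio of 2.5 between planted and
#'   non-planted tumors at the default effect size.
#' @param censor_time Administrative censoring time.
#' @param seed Integer seed.
#' @return A list of class `expression_cohort_spec`.
#' @export
expression_cohort_spec <- function(n_tumors = 104, n_normals = 6,
                                   genes = c(
                                     sprintf("BG%03d", 1:200),
                                     cin25_genes()
                                   ),
                                   signature_genes = cin25_genes(),
                                   cin_fraction = 0.25,
                                   effect_log2fc = 2,
                                   noise_sd = 0.4,
                                   library_size_range = c(5e5, 1.5e6),
                                   baseline_hazard = 0.03,
                                   log_hazard_per_score_unit = log(2.5) / 2,
                                   censor_time = 60,
                                   seed = 1L) {
  if (length(signature_genes) == 0) {
    rlang::abort("signature gene set must be non-empty")
  }
  if (!all(signature_genes %in% genes)) {
    rlang::abort("signature_genes must be contained in genes")
  }
  check_probs(cin_fraction, "cin_fraction")
  if (any(library_size_range <= 0)) {
    rlang::abort("library sizes must be positive")
  }
  structure(
    list(
      n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
      genes = genes, signature_genes = signature_genes,
      cin_fraction = cin_fraction, effect_log2fc = effect_log2fc,
      noise_sd = noise_sd, library_size_range = library_size_range,
      baseline_hazard = baseline_hazard,
      log_hazard_per_score_unit = log_hazard_per_score_unit,
      censor_time = censor_time, seed = as.integer(seed)
    ),
    class = "expression_cohort_spec"
  )
}

#' Simulate an expression + survival cohort
#'
#' Per-gene baseline log2 abundances are drawn once; each sample's log2
#' expression adds Gaussian noise, and planted tumors add `effect_log2fc`
#' on the signature genes. Counts are Poisson draws of the per-sample rates
#' scaled to a uniformly drawn library size, so CPM normalization is
#' genuinely exercised. Survival times for tumors are exponential with
#' hazard `baseline_hazard * exp(log_hazard_per_score_unit * true_score)`,
#' administratively censored at `censor_time`.
#'
#' @param spec An [expression_cohort_spec()].
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (tibble: `sample_id`, `group` tumor/normal, `planted`, `true_score`)
#'   and `survival` (tibble for tumors: `sample_id`, `time`, `event`).
#' @export
simulate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_cohort_spec"))
  with_seed(spec$seed, {
    n_samples <- spec$n_tumors + spec$n_normals
    sample_id <- c(
      sprintf("tumor_%03d", seq_len(spec$n_tumors)),
      sprintf("normal_%02d", seq_len(spec$n_normals))
    )
    group <- rep(c("tumor", "normal"), c(spec$n_tumors, spec$n_normals))
    n_planted <- round(spec$cin_fraction * spec$n_tumors)
    planted <- c(
      sample(rep(c(TRUE, FALSE), c(n_planted, spec$n_tumors - n_planted))),
      rep(FALSE, spec$n_normals)
    )
    true_score <- spec$effect_log2fc * planted

    baseline <- stats::rnorm(length(spec$genes), mean = 5, sd = 1.5)
    names(baseline) <- spec$genes
    is_sig <- spec$genes %in% spec$signature_genes

    log2_expr <- matrix(
      baseline + stats::rnorm(length(spec$genes) * n_samples,
        sd = spec$noise_sd
      ),
      nrow = length(spec$genes), ncol = n_samples,
      dimnames = list(spec$genes, sample_id)
    )
    log2_expr[is_sig, planted] <- log2_expr[is_sig, planted] +
      spec$effect_log2fc

    rates <- 2^log2_expr
    lib <- stats::runif(n_samples,
      spec$library_size_range[1], spec$library_size_range[2]
    )
    lambda <- sweep(rates, 2, lib / colSums(rates), `*`)
    counts <- matrix(
      stats::rpois(length(lambda), lambda),
      nrow = nrow(lambda), dimnames = dimnames(lambda)
    )

    hz <- spec$baseline_hazard *
      exp(spec$log_hazard_per_score_unit * true_score[group == "tumor"])
    raw_t <- stats::rexp(spec$n_tumors, rate = hz)
    survival <- tibble::tibble(
      sample_id = sample_id[group == "tumor"],
      time = pmin(raw_t, spec$censor_time),
      event = raw_t <= spec$censor_time
    )

    list(
      counts = counts,
      samples = tibble::tibble(
        sample_id = sample_id, group = group,
        planted = planted, true_score = true_score
      ),
      survival = survival
    )
  })
}

#' Simulate exponential survival for labelled groups
#'
#' Convenience generator for log-rank power and type-I studies: exponential
#' event times with per-group hazard and administrative censoring.
#'
#' @param n Named integer vector of group sizes.
#' @param hazard Named numeric vector of hazards, same names as `n`.
#' @param censor_time Administrative censoring time.
#' @param seed Integer seed.
#' @return Tibble: `group`, `time`, `event`.
#' @export
simulate_survival <- function(n = c(low = 52, high = 52),
                              hazard = c(low = 0.03, high = 0.075),
                              censor_time = 60, seed = 1L) {
  stopifnot(identical(sort(names(n)), sort(names(hazard))))
  with_seed(seed, {
    purrr::map_dfr(names(n), function(g) {
      raw_t <- stats::rexp(n[[g]], rate = hazard[[g]])
      tibble::tibble(
        group = g,
        time = pmin(raw_t, censor_time),
        event = raw_t <= censor_time
      )
    })
  })
}

#' Specification of a synthetic siRNA knockdown qPCR plate
#'
#' @param target_genes Character vector of target gene symbols.
#' @param conditions Character vector of conditions; must include the
#'   control (scrambled) condition first.
#' @param knockdown_fraction Tibble with columns `gene`, `condition`,
#'   `fraction`: residual expression fraction in `(0, 1]` for each
#'   (gene, condition); cells absent from the table default to 1 (no
#'   effect). The control condition must have fraction 1 everywhere.
#' @param reference_gene Reference (normalization) gene symbol.
#' @param reference_gene_ct Baseline Ct of the reference gene (cycles).
#' @param target_ct Baseline Ct of target genes under the control condition.
#' @param replicate_n Replicates per (gene, condition); >= 2.
#' @param ct_noise_sd Gaussian Ct noise SD (cycles).
#' @param seed Integer seed.
#' @return A list of class `knockdown_plate_spec`.
#' @export
knockdown_plate_spec <- function(target_genes = c("YAP1", "WWTR1"),
                                 conditions = c(
                                   "scrambled", "siYAP", "siTAZ",
                                   "siYAP+siTAZ"
                                 ),
                                 knockdown_fraction = tibble::tribble(
                                   ~gene, ~condition, ~fraction,
                                   "YAP1", "siYAP", 0.2,
                                   "YAP1", "siYAP+siTAZ", 0.2,
                                   "WWTR1", "siTAZ", 0.2,
                                   "WWTR1", "siYAP+siTAZ", 0.2
                                 ),
                                 reference_gene = "B2M",
                                 reference_gene_ct = 18,
                                 target_ct = 25,
                                 replicate_n = 3,
                                 ct_noise_sd = 0.15,
                                 seed = 1L) {
  if (replicate_n < 2) rlang::abort("replicate_n must be >= 2")
  if (any(knockdown_fraction$fraction <= 0 | knockdown_fraction$fraction > 1)) {
    rlang::abort("residual fractions must lie in (0, 1]")
  }
  ctrl <- conditions[1]
  bad_ctrl <- knockdown_fraction$condition == ctrl &
    knockdown_fraction$fraction != 1
  if (any(bad_ctrl)) {
    rlang::abort("the control condition must have residual fraction 1")
  }
  if (!all(knockdown_fraction$condition %in% conditions)) {
    rlang::abort("knockdown_fraction refers to unknown conditions")
  }
  structure(
    list(
      target_genes = target_genes, conditions = conditions,
      knockdown_fraction = knockdown_fraction,
      reference_gene = reference_gene,
      reference_gene_ct = reference_gene_ct, target_ct = target_ct,
      replicate_n = as.integer(replicate_n), ct_noise_sd = ct_noise_sd,
      seed = as.integer(seed)
    ),
    class = "knockdown_plate_spec"
  )
}

#' Simulate a knockdown qPCR plate
#'
#' A target with residual expression fraction f under a condition shows a Ct
#' shifted by `-log2(f)` cycles above its control-condition Ct (halving the
#' template costs one cycle). The reference gene's Ct is
#' condition-independent up to noise.
#'
#' @param spec A [knockdown_plate_spec()].
#' @return Tibble of Ct records: `condition`, `gene`, `replicate`, `ct`,
#'   plus the ground-truth `true_fraction`.
#' @export
simulate_knockdown_plate <- function(spec) {
  stopifnot(inherits(spec, "knockdown_plate_spec"))
  with_seed(spec$seed, {
    design <- tidyr::crossing(
      condition = spec$conditions,
      gene = c(spec$target_genes, spec$reference_gene),
      replicate = seq_len(spec$replicate_n)
    ) |>
      dplyr::left_join(spec$knockdown_fraction,
        by = c("gene", "condition")
      ) |>
      dplyr::mutate(
        true_fraction = dplyr::if_else(
          .data$gene == spec$reference_gene, 1,
          dplyr::coalesce(.data$fraction, 1)
        ),
        base_ct = dplyr::if_else(
          .data$gene == spec$reference_gene,
          spec$reference_gene_ct, spec$target_ct
        ),
        ct = .data$base_ct - log2(.data$true_fraction) +
          stats::rnorm(dplyr::n(), sd = spec$ct_noise_sd)
      ) |>
      dplyr::select("condition", "gene", "replicate", "ct", "true_fraction")
    design
  })
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
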