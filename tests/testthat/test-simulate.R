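test_that("TMA generator honors degenerate probabilities and concordance", {
  zero <- tma_cohort_spec(
    n_tumors = 20,
    positivity = tibble::tibble(
      marker = c("YAP", "TAZ"), compartment = "nuclear", prob = 0
    ),
    seed = 3
  )
  cohort <- simulate_tma_cohort(zero)
  expect_true(all(cohort$cores$quantity == 0))
  expect_false(any(cohort$truth$positive))

  conc <- simulate_tma_cohort(tma_cohort_spec(
    n_tumors = 30, core_concordance = 1, seed = 5
  ))
  wide <- tidyr::pivot_wider(conc$cores,
    id_cols = c("tumor_id", "marker", "compartment"),
    names_from = "core_id", values_from = c("quantity", "intensity")
  )
  expect_equal(wide$quantity_1, wide$quantity_2)
  expect_equal(wide$intensity_1, wide$intensity_2)
})

test_that("TMA generator output is seeded and structurally valid", {
  spec <- tma_cohort_spec(n_tumors = 25, seed = 9)
  a <- simulate_tma_cohort(spec)
  b <- simulate_tma_cohort(spec)
  expect_identical(a, b)

  counts <- dplyr::count(a$cores, .data$tumor_id, .data$marker,
    .data$compartment)
  expect_true(all(counts$n == 2))
  expect_true(all(a$cores$quantity %in% 0:4))
  expect_true(all(a$cores$intensity %in% 0:3))
  expect_error(tma_cohort_spec(core_concordance = 1.4), "\\[0, 1\\]")
  expect_error(tma_cohort_spec(grade_probs = c(G1 = 0.5, G2 = 0.4)), "sum to 1")
})

test_that("observed positivity recovers the planted probability (binomial oracle)", {
  p <- 0.395
  n <- 152
  n_seeds <- 200
  fracs <- vapply(seq_len(n_seeds), function(s) {
    spec <- tma_cohort_spec(
      n_tumors = n,
      positivity = tibble::tibble(
        marker = "YAP", compartment = "nuclear", prob = p
      ),
      seed = s
    )
    cohort <- simulate_tma_cohort(spec)
    scored <- score_tumors(cohort$cores)
    mean(scored$positive)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n * n_seeds))
  expect_lt(abs(mean(fracs) - p), 3 * se)
})

test_that("IF field generator produces exact piecewise-constant geometry", {
  eq <- simulate_if_field(if_field_spec(
    noise_sd = 0, nuclear_intensity = 150, cytoplasmic_intensity = 150,
    seed = 2
  ))
  expect_equal(eq$true_ratio, 1)
  m <- measure_field(eq$stain, eq$nuclear_mask, eq$cytoplasm_mask)
  expect_equal(m$nc_ratio, 1)

  f <- planted_field(noise_sd = 0)
  expect_false(any(f$nuclear_mask & f$cytoplasm_mask))
  m <- measure_field(f$stain, f$nuclear_mask, f$cytoplasm_mask)
  expect_equal(m$nc_ratio, 2)

  empty <- simulate_if_field(if_field_spec(n_cells = 0, noise_sd = 0))
  expect_false(any(empty$nuclear_mask))
  expect_true(is.na(empty$true_ratio))
  m <- measure_field(empty$stain, empty$nuclear_mask, empty$cytoplasm_mask)
  expect_true(m$undefined)
})

test_that("IF field generator fails loudly when cells cannot be placed", {
  spec <- if_field_spec(width = 64, height = 64, n_cells = 60)
  expect_error(simulate_if_field(spec), "density")
  expect_error(if_field_spec(nucleus_radius = c(5, 12), cell_radius = c(11, 15)),
    "exceed")
})

test_that("expression cohort plants the stated cluster and shifts", {
  spec <- expression_cohort_spec(seed = 21)
  cohort <- simulate_expression_cohort(spec)
  expect_equal(sum(cohort$samples$planted), 26)
  expect_equal(ncol(cohort$counts), 110)
  expect_true(all(cohort$survival$time <= spec$censor_time))
  expect_identical(cohort, simulate_expression_cohort(spec))

  # planted signature genes carry the log2 shift; use a wide background
  # panel so CPM compositional attenuation is negligible
  wide <- simulate_expression_cohort(expression_cohort_spec(
    genes = c(sprintf("BG%04d", 1:3000), cin25_genes()), seed = 22
  ))
  logcpm <- cpm_normalize(wide$counts, log2 = TRUE)
  sig <- intersect(cin25_genes(), rownames(logcpm))
  planted <- wide$samples$planted
  shift <- rowMeans(logcpm[sig, planted]) - rowMeans(logcpm[sig, !planted])
  expect_equal(mean(shift), 2, tolerance = 0.15)

  expect_error(
    expression_cohort_spec(signature_genes = character(0)),
    "non-empty"
  )
})

test_that("survival generator censors administratively and respects hazards", {
  surv <- simulate_survival(
    n = c(a = 400, b = 400), hazard = c(a = 0.03, b = 0.075),
    censor_time = 60, seed = 5
  )
  expect_true(all(surv$time <= 60))
  # exponential with hazard h censored at T has event probability 1 - exp(-hT)
  p_a <- mean(surv$event[surv$group == "a"])
  expect_equal(p_a, 1 - exp(-0.03 * 60), tolerance = 0.06)
})

test_that("knockdown plate Ct shifts encode residual fractions", {
  spec <- knockdown_plate_spec(ct_noise_sd = 0, seed = 8,
    knockdown_fraction = tibble::tibble(
      gene = "YAP1", condition = "siYAP", fraction = 0.25
    ))
  plate <- simulate_knockdown_plate(spec)
  ct_ctrl <- plate$ct[plate$gene == "YAP1" & plate$condition == "scrambled"][1]
  ct_kd <- plate$ct[plate$gene == "YAP1" & plate$condition == "siYAP"][1]
  expect_equal(ct_kd - ct_ctrl, 2) # log2(1/0.25)
  ref <- plate[plate$gene == "B2M", ]
  expect_true(all(ref$ct == spec$reference_gene_ct))

  expect_error(
    knockdown_plate_spec(knockdown_fraction = tibble::tibble(
      gene = "YAP1", condition = "siYAP", fraction = 0
    )),
    "\\(0, 1\\]"
  )
  expect_error(knockdown_plate_spec(replicate_n = 1), ">= 2")
})

test_that("noisy knockdown plates round-trip through ddct within Monte-Carlo bounds", {
  rqs <- vapply(1:40, function(s) {
    spec <- knockdown_plate_spec(
      knockdown_fraction = tibble::tibble(
        gene = "YAP1", condition = "siYAP", fraction = 0.1
      ),
      replicate_n = 6, ct_noise_sd = 0.1, seed = s
    )
    rq <- ddct(simulate_knockdown_plate(spec))
    rq$rq[rq$gene == "YAP1" & rq$condition == "siYAP"]
  }, numeric(1))
  expect_gt(mean(rqs), 0.07)
  expect_lt(mean(rqs), 0.14)
})
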