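test_that("ddct implements the reference-gene normalized fold change", {
  ct <- tibble::tibble(
    condition = rep(c("scrambled", "siYAP"), each = 4),
    gene = rep(c("YAP1", "YAP1", "B2M", "B2M"), 2),
    replicate = rep(1:2, 4),
    ct = c(25, 25, 18, 18, 27, 27, 18, 18)
  )
  rq <- ddct(ct, reference = "B2M", control = "scrambled")
  expect_equal(rq$rq[rq$condition == "scrambled"], 1)
  # +2 cycles with the reference unchanged: 2^-2
  expect_equal(rq$rq[rq$condition == "siYAP"], 0.25)
  expect_equal(rq$delta_delta_ct[rq$condition == "siYAP"], 2)
})

test_that("ddct round-trips generator residual fractions exactly at zero noise", {
  spec <- knockdown_plate_spec(
    target_genes = c("YAP1", "WWTR1", "AURKA"),
    knockdown_fraction = tibble::tibble(
      gene = c("YAP1", "WWTR1", "AURKA"),
      condition = c("siYAP", "siTAZ", "siYAP+siTAZ"),
      fraction = c(0.5, 0.2, 0.3)
    ),
    ct_noise_sd = 0, seed = 1
  )
  plate <- simulate_knockdown_plate(spec)
  rq <- ddct(plate)
  expect_equal(rq$rq[rq$gene == "YAP1" & rq$condition == "siYAP"], 0.5)
  expect_equal(rq$rq[rq$gene == "WWTR1" & rq$condition == "siTAZ"], 0.2)
  expect_equal(rq$rq[rq$gene == "AURKA" & rq$condition == "siYAP+siTAZ"], 0.3)
  expect_true(all(rq$rq[rq$condition == "scrambled"] == 1))
})

test_that("relative quantification is invariant to a plate-wide Ct offset", {
  spec <- knockdown_plate_spec(seed = 23)
  plate <- simulate_knockdown_plate(spec)
  shifted <- dplyr::mutate(plate, ct = ct + 3.7)
  a <- ddct(plate)
  b <- ddct(shifted)
  expect_equal(a$rq, b$rq, tolerance = 1e-12)
})

test_that("ddct validates its design", {
  ct <- tibble::tibble(
    condition = c("scrambled", "scrambled", "siYAP"),
    gene = c("YAP1", "B2M", "YAP1"),
    replicate = 1L,
    ct = c(25, 18, 27)
  )
  expect_error(ddct(ct), "missing in condition")
  expect_error(
    ddct(dplyr::mutate(ct, ct = c(25, -1, 27))),
    "positive"
  )
  expect_error(ddct(ct, control = "mock"), "not found")
})

test_that("per-replicate aggregation mode agrees at zero noise and reports dispersion", {
  spec <- knockdown_plate_spec(ct_noise_sd = 0, seed = 2)
  plate <- simulate_knockdown_plate(spec)
  a <- ddct(plate, aggregate = "mean_ct")
  b <- ddct(plate, aggregate = "per_replicate")
  expect_equal(a$rq, b$rq, tolerance = 1e-12)
  expect_true(all(a$rq_sd == 0))

  noisy <- ddct(simulate_knockdown_plate(knockdown_plate_spec(seed = 3)))
  expect_true(all(noisy$rq_sd[noisy$condition != "scrambled"] >= 0))
})

test_that("assay normalization divides by the control mean", {
  readings <- tibble::tibble(
    condition = rep(c("scrambled", "siYAP+siTAZ"), each = 3),
    value = c(1.0, 1.2, 0.8, 0.5, 0.55, 0.45)
  )
  norm <- normalize_assay(readings)
  expect_equal(mean(norm$normalized[norm$condition == "scrambled"]), 1)
  expect_equal(
    norm$normalized[4], 0.5 / 1.0
  )
  expect_error(
    normalize_assay(tibble::tibble(condition = "siYAP", value = 1)),
    "empty"
  )
  expect_error(
    normalize_assay(tibble::tibble(condition = "scrambled", value = 0)),
    "zero"
  )
})

test_that("a planted reduction is recovered by assay normalization", {
  set.seed(17)
  means <- vapply(1:40, function(i) {
    readings <- tibble::tibble(
      condition = rep(c("scrambled", "siYAP+siTAZ"), each = 6),
      value = c(rnorm(6, 1, 0.05), rnorm(6, 0.6, 0.05))
    )
    norm <- normalize_assay(readings)
    mean(norm$normalized[norm$condition == "siYAP+siTAZ"])
  }, numeric(1))
  expect_equal(mean(means), 0.6, tolerance = 0.02)
})

test_that("condition heatmap preserves per-gene ordering and validates the design", {
  rq <- tidyr::crossing(
    gene = c("AURKA", "CCNB1", "CYR61"),
    condition = c("scrambled", "siYAP", "siTAZ", "siYAP+siTAZ")
  ) |>
    dplyr::mutate(rq = dplyr::case_when(
      condition == "scrambled" ~ 1,
      gene == "CYR61" ~ 0.4,
      condition == "siYAP+siTAZ" ~ 0.3,
      TRUE ~ 0.9
    ))
  hm <- condition_heatmap(rq)
  expect_equal(nrow(hm), 3)
  # combined < single < control for the CIN genes
  expect_true(all(hm$`siYAP+siTAZ`[hm$gene != "CYR61"] <
    hm$siYAP[hm$gene != "CYR61"]))
  expect_true(all(hm$siYAP <= hm$scrambled))

  constant <- condition_heatmap(dplyr::mutate(rq, rq = 1))
  expect_true(all(as.matrix(constant[, -1]) == 1))

  lg <- condition_heatmap(rq, log2 = TRUE)
  expect_equal(lg$scrambled, rep(0, 3))

  expect_error(condition_heatmap(dplyr::bind_rows(rq, rq[1, ])), "duplicate")
  expect_error(condition_heatmap(rq[-2, ]), "incomplete")
})

test_that("generator plate reproduces the combined-only CIN knockdown pattern", {
  cin <- c("AURKA", "CCNB1", "TOP2A")
  spec <- knockdown_plate_spec(
    target_genes = c(cin, "CYR61", "ANKRD1"),
    knockdown_fraction = dplyr::bind_rows(
      tidyr::crossing(gene = cin, condition = "siYAP+siTAZ") |>
        dplyr::mutate(fraction = 0.3),
      tidyr::crossing(
        gene = c("CYR61", "ANKRD1"),
        condition = c("siYAP", "siTAZ", "siYAP+siTAZ")
      ) |>
        dplyr::mutate(fraction = 0.4)
    ),
    ct_noise_sd = 0.05, seed = 7
  )
  rq <- ddct(simulate_knockdown_plate(spec))
  hm <- condition_heatmap(rq)
  # CIN genes respond only to combined silencing
  cin_rows <- hm$gene %in% cin
  expect_true(all(hm$`siYAP+siTAZ`[cin_rows] < 0.5))
  expect_true(all(hm$siYAP[cin_rows] > 0.8))
  expect_true(all(hm$siTAZ[cin_rows] > 0.8))
  # positive controls respond to single and combined silencing alike
  ctrl_rows <- hm$gene %in% c("CYR61", "ANKRD1")
  expect_true(all(hm$siYAP[ctrl_rows] < 0.5))
  expect_true(all(hm$siTAZ[ctrl_rows] < 0.5))
  expect_true(all(hm$`siYAP+siTAZ`[ctrl_rows] < 0.5))
})
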