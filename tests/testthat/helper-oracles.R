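# Independent oracles used across test files.

# Brute-force two-sided exact Mann-Whitney p: enumerate every assignment of
# pooled ranks to group A and count U values at least as extreme.
oracle_mw_exact_p <- function(x, y) {
  n_a <- length(x)
  n <- n_a + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n_a * (n_a + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Rank-then-Pearson Spearman oracle via base R.
oracle_spearman_r <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Noiseless planted field with known geometry for segmentation tests.
planted_field <- function(n_cells = 12, noise_sd = 0, seed = 11,
                          nuclear = 200, cytoplasmic = 100) {
  simulate_if_field(if_field_spec(
    n_cells = n_cells, noise_sd = noise_sd, seed = seed,
    nuclear_intensity = nuclear, cytoplasmic_intensity = cytoplasmic
  ))
}

# Calls tibble for positivity_table() with exact per-compartment counts.
calls_from_counts <- function(n, yap_nuc, taz_nuc, both_nuc,
                              yap_cyt = 0, taz_cyt = 0, both_cyt = 0) {
  ids <- sprintf("T%03d", seq_len(n))
  make <- function(n_a, n_b, n_both) {
    a <- c(rep(TRUE, n_a), rep(FALSE, n - n_a))
    b <- c(
      rep(TRUE, n_both), rep(FALSE, n_a - n_both),
      rep(TRUE, n_b - n_both), rep(FALSE, n - n_a - (n_b - n_both))
    )
    list(a = a, b = b)
  }
  nuc <- make(yap_nuc, taz_nuc, both_nuc)
  cyt <- make(yap_cyt, taz_cyt, both_cyt)
  dplyr::bind_rows(
    tibble::tibble(
      tumor_id = ids, marker = "YAP", compartment = "nuclear",
      positive = nuc$a
    ),
    tibble::tibble(
      tumor_id = ids, marker = "TAZ", compartment = "nuclear",
      positive = nuc$b
    ),
    tibble::tibble(
      tumor_id = ids, marker = "YAP", compartment = "cytoplasmic",
      positive = cyt$a
    ),
    tibble::tibble(
      tumor_id = ids, marker = "TAZ", compartment = "cytoplasmic",
      positive = cyt$b
    )
  )
}
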