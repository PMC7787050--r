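# Shared fixtures built in code.

# Minimal sample table: blanks plus labelled samples for one compartment.
make_sample_table <- function(compartment = "total_mucus",
                              blank_delta_c = -21, blank_delta_n = 8,
                              enriched_delta_c = 250, enriched_delta_n = 120,
                              n_blank = 3, n_lab = 3, time_h = 24,
                              frac_c = 0.35, frac_n = 0.10) {
  blanks <- tibble::tibble(
    sample_id = paste0("b", seq_len(n_blank)),
    fish_id = paste0("bf", seq_len(n_blank)),
    compartment = compartment, time_h = 0, treatment = "blank",
    delta_c_permil = blank_delta_c, delta_n_permil = blank_delta_n,
    atpct_c = NA_real_, atpct_n = NA_real_,
    frac_c = frac_c, frac_n = frac_n, dry_mass_mg = 0.5
  )
  lab <- tibble::tibble(
    sample_id = paste0("s", seq_len(n_lab)),
    fish_id = paste0("lf", seq_len(n_lab)),
    compartment = compartment, time_h = time_h, treatment = "timecourse",
    delta_c_permil = blank_delta_c + enriched_delta_c,
    delta_n_permil = blank_delta_n + enriched_delta_n,
    atpct_c = NA_real_, atpct_n = NA_real_,
    frac_c = frac_c, frac_n = frac_n, dry_mass_mg = 0.5
  )
  dplyr::bind_rows(blanks, lab)
}

make_fish_table <- function(ids, treatment = "timecourse",
                            body_weight_g = 186.1, collected_mucus_mg = 510,
                            raw_dry_mg = 51, area = 70.8) {
  tibble::tibble(
    fish_id = ids,
    body_weight_g = body_weight_g,
    extraction_area_cm2 = area,
    collected_mucus_mg = collected_mucus_mg,
    raw_dry_mg = raw_dry_mg,
    soluble_dry_mg = raw_dry_mg * 0.824,
    insoluble_dry_mg = raw_dry_mg * 0.153,
    treatment = treatment,
    time_h = 24
  )
}

# Long data frame from a named list of numeric vectors.
groups_df <- function(groups) {
  tibble::tibble(
    value = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}

# Monte-Carlo oracle for the studentized range tail probability:
# P(range(Z_1..Z_k)/ (chi_df/sqrt(df)) > q) estimated from `draws` samples.
mc_studentized_range_p <- function(q, k, df, draws = 1e6, seed = 42) {
  withr::with_seed(seed, {
    z <- as.data.frame(matrix(rnorm(draws * k), ncol = k))
    rng <- do.call(pmax, z) - do.call(pmin, z)
    u <- sqrt(rchisq(draws, df) / df)
    mean(rng / u > q)
  })
}

# Monte-Carlo oracle for the studentized maximum modulus tail probability:
# P(max_i |Z_i| / (chi_df/sqrt(df)) > q), m independent numerators.
mc_smm_p <- function(q, m, df, draws = 1e6, seed = 42) {
  withr::with_seed(seed, {
    z <- matrix(abs(rnorm(draws * m)), ncol = m)
    mx <- do.call(pmax, as.data.frame(z))
    u <- sqrt(rchisq(draws, df) / df)
    mean(mx / u > q)
  })
}
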