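# Shared fixture builders: everything is generated in code at test time.

# small panel with an STR-like frequency table and a configurable Y pool
make_panel <- function(seed, label = "pop",
                       n_loci = 13L, alleles = 8L,
                       y_pool = 400L, y_distinct = 5000L, y_skew = 1) {
  gen_population_panel(
    synthetic_panel_spec(n_loci = n_loci, alleles_per_locus = alleles,
                         y_pool_size = y_pool, y_distinct = y_distinct,
                         y_skew = y_skew, seed = seed),
    label = label)
}

# three independent reference frequency tables + CLR config
make_clr_config <- function(seed = 900L, n_loci = 13L, alleles = 8L,
                            database_size = 1900000, ...) {
  refs <- lapply(1:3, function(i)
    gen_frequency_table(
      synthetic_panel_spec(n_loci = n_loci, alleles_per_locus = alleles,
                           seed = seed + i),
      label = paste0("ref", i)))
  clr_config(refs, database_size = database_size, ...)
}

# hand-built two-locus table for exact arithmetic
toy_table <- function(label = "toy") {
  allele_freq_table(label, list(
    LA = c(a = 0.5, b = 0.3, c = 0.2),
    LB = c(x = 0.25, y = 0.75)
  ), codis_core = FALSE)
}

# a y sample with prescribed haplotype multiplicities
make_y_counts <- function(counts, label = "ycounts") {
  y_haplotype_sample(label,
                     rep(sprintf("h%03d", seq_along(counts)), counts))
}

# pair_sample built by hand from two profiles
make_pair <- function(profile_a, profile_b, y_a, y_b, truth = "unknown") {
  structure(list(profile_a = profile_a, profile_b = profile_b,
                 y_a = y_a, y_b = y_b, truth = truth,
                 source_panels = c("manual", "manual")),
            class = "pair_sample")
}
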