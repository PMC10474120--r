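# Fixture builders used across the test files. Everything is generated in
# code; no stored data.

# Noise-free conversion series for a binary system with true ratio r
# (k = (r, 1)), truncated at x_max unless x_max is NULL.
noiseless_series <- function(r, f0 = c(0.5, 0.5), n_time = 60L,
                             final_conversion = 0.9, x_max = 0.6,
                             species = c("A", "B")) {
  cfg <- synth_config(rate_set(c(r, 1), species = species), f0,
                      final_conversion = final_conversion,
                      time_grid = default_time_grid(n_time),
                      noise_sigma = 0)
  cs <- conversions(generate_kinetics(cfg))
  if (is.null(x_max)) cs else truncate_conversions(cs, x_max)
}

# Noisy replicate series for the same system, seeded.
noisy_series <- function(r, seed, noise_sigma = 0.02, f0 = c(0.5, 0.5),
                         n_time = 50L, final_conversion = 0.9,
                         x_max = 0.6) {
  cfg <- synth_config(rate_set(c(r, 1)), f0,
                      final_conversion = final_conversion,
                      time_grid = default_time_grid(n_time),
                      noise_sigma = noise_sigma, seed = seed)
  truncate_conversions(conversions(generate_kinetics(cfg)), x_max)
}

# Hand-built dataset from explicit integral matrices.
manual_dataset <- function(time, monomer, polymer,
                           species = colnames(monomer)) {
  kinetics_dataset(time = time, monomer = monomer, polymer = polymer,
                   species = species)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
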