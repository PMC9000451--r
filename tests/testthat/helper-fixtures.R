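# shared fixtures: the default study design and ground truth, noiseless
# unless a test asks otherwise

noiseless_design <- function(seed = 1L, ...) {
  assay_design(noise_sd = 0, seed = seed, ...)
}

noisy_design <- function(seed = 1L, noise_sd = 0.02, ...) {
  assay_design(noise_sd = noise_sd, seed = seed, ...)
}

default_truth <- function(...) ground_truth(...)

# a minimal hand-built plate for unit tests: one dose, replicate rates
# chosen by picking b so that Eq-1 gives the wanted percentages
plate_from_rates <- function(conc, rates_pct, A = 0.10, a = 0.90,
                             B = 0.12) {
  rows <- lapply(seq_along(rates_pct), function(i) {
    b <- B + (a - A) * (1 - rates_pct[i] / 100)
    data.frame(sample_id = "s", inhibitor_conc_mg_ml = conc,
               replicate = i, role = c("A", "a", "B", "b"),
               absorbance = c(A, a, B, b))
  })
  plate_assay(do.call(rbind, rows))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
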