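# Shared fixtures: everything is generated in code, nothing on disk.

# standard rinse design: 18 nmol single load, 12 samples, 30 min period
rinse_design <- function(n = 12, load = 18) {
  experimentDesign("rinse", load_nmol = load, n_samples = n)
}

# wavelength grid matching the instrument range at 2 nm resolution
wl_grid <- function() seq(370, 750, by = 2)

# random in-range sampling parameter triples for property loops
random_sampling_params <- function() {
  samplingParams(runif(1, 0, 0.6), runif(1, 0, 1), runif(1, 0, 0.6))
}

random_sub_params <- function() {
  subParams(runif(1, 0, 0.6), runif(1, 0, 1), runif(1, 0, 0.6),
            runif(1, 0, 0.6), runif(1, 0, 1), runif(1, 0, 0.6))
}
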