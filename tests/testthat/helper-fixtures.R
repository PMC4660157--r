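# shared fixtures: small configs and parameter sets built in code

default_params <- default_cascade_params()

# a single-Tar receptor with no methylation offset, for closed-form checks
tar_only_receptor <- function(n_cluster = 6) {
  receptor_spec(n_cluster = n_cluster, tar_fraction = 1, tsr_fraction = 0,
                K_tar = c(off = 0.02, on = 0.5), m_offset = 0, m_slope = 0.5)
}

quick_config <- function(n_cells = 4, n_steps = 50, seed = 11, beta = 1,
                         field = exponential_field(d = 1), ...) {
  simulation_config(field = field, n_cells = n_cells, n_steps = n_steps,
                    beta = beta, record_stride = 10, seed = seed, ...)
}

# eight-value ladder of total-protein multiples used across experiments
beta_ladder <- c(1/4, 1/2, 1, 2, 4, 6, 8, 10)
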