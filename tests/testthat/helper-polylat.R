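# shared test utilities

# short protocol for fast engine tests
quick_protocol <- function(n, mode, production_mcs = 2000, sample_interval = 5,
                           equilibration_mcs = 200) {
  run_protocol(n, mode, equilibration_mcs = equilibration_mcs,
               settle_mcs = equilibration_mcs, production_mcs = production_mcs,
               sample_interval = sample_interval)
}

# fabricate a minimal trajectory list for observable unit tests
fake_traj <- function(com = NULL, ree = NULL, dt = 1) {
  nf <- if (!is.null(com)) nrow(com) else nrow(ree)
  list(times = (seq_len(nf) - 1) * dt,
       com = if (is.null(com)) matrix(0, nf, 3) else com,
       end_to_end = if (is.null(ree)) matrix(0L, nf, 3) else ree)
}

# random configuration drawn from an enumerated ensemble (exact sampler)
sample_config <- function(ensemble, seed) {
  set.seed(seed)
  cfgs <- attr(ensemble, "configs")
  probs <- ensemble$weight / attr(ensemble, "Z")
  cfgs[[sample(length(cfgs), 1, prob = probs)]]
}
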