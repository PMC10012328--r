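# shared fixtures: all built in code at test time

# history with spikes at given times/thetas for one neuron
make_history <- function(times, thetas) list(t = times, theta = thetas)

# evaluation instant just after the newest spike, honouring the strict
# t_i < t rule while reproducing closed-form values that include the
# newest pairing at full weight
just_after <- function(t) t + 1e-9

# a deterministic short memory trial (theta, 0 degrees) reused across tests
quick_trial <- function(seed = 11, offset = 0, ...) {
  net <- build_network(seed = seed)
  run_trial(net, model_params(), stimulus_spec(4, offset), seed = seed + 1, ...)
}

# run one memory condition with few trials (unit-test scale)
quick_condition <- function(freq, offset, n = 5, master = 17, cid = 1,
                            params = model_params()) {
  run_memory_condition(stimulus_spec(freq, offset), params, n_trials = n,
                       master_seed = master, condition_id = cid)
}
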