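# Lazily computed, memoised study objects shared by the heavier test
# blocks (full 16-position towers are reused across several checks).
.study_cache <- new.env(parent = emptyenv())

study <- function(name, build) {
  if (!exists(name, envir = .study_cache)) {
    assign(name, build(), envir = .study_cache)
  }
  get(name, envir = .study_cache)
}

study_kernel <- function() {
  study("kernel16", function() joint_kernel(single_agent_kernel(canyon_spec())))
}

# the Fig 6/7 tower: identical CPT agents, b = 0, beta = 0.9,
# w(x) = exp(-0.5 (-log x)^0.9)
study_cpt_tower <- function() {
  study("cpt_tower", function() {
    level_k_tower(4, canyon_spec(), markov_cpt_params(),
                  config = planning_config(0.9))
  })
}

study_stag_mass <- function(tower, k1, k2 = k1) {
  rho <- tower_stationary(tower, k1, k2, study_kernel())
  coordination_metrics(rho, tower$spec)$stag_mass
}
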