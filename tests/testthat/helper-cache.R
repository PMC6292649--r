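# expensive shared fixtures, built once per test session
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# ideal-chain Brownian reference trajectory (N = 256, 6000 tau)
rouse_reference_traj <- function() {
  cached("rouse_traj", function() {
    N <- 256
    ann <- uniform_annotation(N)
    init <- make_rouse_ensemble(N, 1, 1, seed = 1)[[1]]
    brownian_run(init, ann, rouse_params(), t_total = 6000, dt = 0.01,
                 frame_interval = 1, seed = 1, cap_drift = 1, cap_reject = 1e9)
  })
}

# collapsed heteropolymer study system (N = 256): annotation, params, one
# collapse-sampled initial structure, and a 600 tau passive trajectory
collapsed_state <- function() {
  cached("collapsed", function() {
    N <- 256
    ann <- generate_annotation(N, 20, seed = 1, target_active = 0.4)
    ann <- generate_loops(ann, 20, 10, 80, seed = 2)
    par <- chrom_params(N)
    rw <- make_rouse_ensemble(N, 1, 1, seed = 3)[[1]]
    init <- langevin_sample(rw, ann, par, n_samples = 1, spacing = 1,
                            burn_in = 40, seed = 4)[[1]]
    traj <- brownian_run(init, ann, par, t_total = 600, dt = 1e-3,
                         frame_interval = 0.25, seed = 5)
    list(ann = ann, par = par, init = init, traj = traj)
  })
}

# ensemble of independently collapsed chains (N = 512), the crumpled-globule
# structural ensemble
collapse_ensemble <- function(n_samples = 30) {
  cached("ens512", function() {
    N <- 512
    ann <- generate_annotation(N, 20, seed = 1, target_active = 0.4)
    ann <- generate_loops(ann, 40, 10, 80, seed = 2)
    par <- chrom_params(N)
    ens <- collapse_conformations(ann, par, n_samples = n_samples, seed = 1)
    list(ann = ann, par = par, ensemble = ens)
  })
}
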