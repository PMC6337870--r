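# Shared fixtures, built in code. The 0.008 um^3 scenario keeps in vivo
# concentrations (counts scaled by 1/8); per-ribosome quantities are
# intensive, so burn-in / stop steps are scaled by the same factor to keep
# per-ribosome sampling equal.

scen_invivo <- function(volume_um3 = 0.064) in_vivo_scenario(volume_um3 = volume_um3)

scen_small <- function() in_vivo_scenario(volume_um3 = 0.008)

# proportional step counts for a scaled volume (full volume: 5000/1000)
steps_small <- function() list(stop = 625, burn = 125)
steps_small_relaxed <- function() list(stop = 1250, burn = 500)

fixture_tufa <- function() {
  read_fasta_cds(system.file("extdata", "tufa_like_synthetic.fasta",
                             package = "elongsim"))
}

fixture_gfp <- function() {
  read_fasta_cds(system.file("extdata", "gfp_like_synthetic.fasta",
                             package = "elongsim"))
}

# tiny single-species scenario: every codon is GCA (Ala1B), saturating pool
scen_single_species <- function(n_rib = 20, n_eftu = 200, pool = 400) {
  kin <- list(D = 2.567e-12, k_diss = 1, t_cat = 1 / 24,
              burn_in_steps = 50, stop_steps = 400)
  scenario_config(list(ribosomes = n_rib, eftu = n_eftu),
                  c(Ala1B = pool), kin, lattice_spec(0.008, 20))
}

# a perfectly linear synthetic trace (for estimator unit tests)
linear_trace <- function(n_events, dt, n_ribosomes) {
  structure(data.frame(event_index = seq_len(n_events),
                       time_s = seq_len(n_events) * dt,
                       cumulative_steps = seq_len(n_events)),
            n_ribosomes = n_ribosomes, seed = 0L, burn_in_steps = 0,
            class = c("elongation_trace", "data.frame"))
}
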