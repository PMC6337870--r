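#' Per-direction lattice jump rate
#'
#' The discretized diffusion equation gives a jump rate of `D / h^2` between
#' adjacent grid points. This is the PER-DIRECTION rate; the total jump
#' propensity of one molecule on a 3-D lattice is `6 * D / h^2`. Only this
#' convention reproduces the continuum limit (mean squared displacement
#' `6 D t`), which is verified by the tracer oracle test.
#'
#' @param D diffusion coefficient in m^2/s (>= 0).
#' @param h grid spacing in metres (> 0).
#' @return jump rate per direction in 1/s.
#' @export
jump_rate <- function(D, h) {
  stopifnot(D >= 0, h > 0)
  D / h^2
}

#' Total SSA propensity and per-channel breakdown
#'
#' Every ternary complex carries one travel channel of total rate
#' `6 * D / h^2` and one dissociation channel of rate `k_diss`, so
#' `alpha0 = N * (6 D / h^2 + k_diss)` with `N` the number of complexes.
#'
#' @param species_counts named integer vector: ternary complexes per tRNA
#'   species (a scalar total is also accepted).
#' @param D diffusion coefficient (m^2/s).
#' @param h grid spacing (m).
#' @param k_diss dissociation rate (1/s).
#' @return list with `alpha0`, `travel`, `diss` (totals, 1/s) and data frame
#'   `per_species` when a named vector was supplied.
#' @export
total_propensity <- function(species_counts, D, h, k_diss) {
  stopifnot(all(species_counts >= 0), k_diss >= 0)
  d6 <- 6 * jump_rate(D, h)
  n <- sum(species_counts)
  out <- list(alpha0 = n * (d6 + k_diss), travel = n * d6, diss = n * k_diss)
  if (!is.null(names(species_counts))) {
    out$per_species <- data.frame(
      species = names(species_counts),
      travel = as.numeric(species_counts) * d6,
      diss = as.numeric(species_counts) * k_diss,
      row.names = NULL
    )
  }
  out
}

#' Sample the Gillespie waiting time
#'
#' `tau = ln(1/r1) / alpha0` with `r1` uniform on (0, 1]; tau is
#' Exponential(alpha0)-distributed.
#'
#' @param alpha0 total propensity (> 0).
#' @param r1 optional uniform random number(s) in (0, 1]; drawn if missing.
#' @return waiting time(s) in seconds.
#' @export
sample_tau <- function(alpha0, r1 = NULL) {
  if (!is.numeric(alpha0) || alpha0 <= 0) {
    stop("stalled system: total propensity must be positive")
  }
  if (is.null(r1)) r1 <- runif(1)
  stopifnot(all(r1 > 0), all(r1 <= 1))
  log(1 / r1) / alpha0
}

#' Select a reaction channel (Gillespie direct method)
#'
#' Returns the smallest index `j` whose cumulative propensity exceeds
#' `r2 * sum(propensities)`.
#'
#' @param propensities non-negative channel propensities, not all zero.
#' @param r2 uniform random number in `[0, 1)`; drawn if missing.
#' @return integer channel index.
#' @export
select_channel <- function(propensities, r2 = NULL) {
  stopifnot(all(propensities >= 0))
  a0 <- sum(propensities)
  if (a0 <= 0) stop("all-zero propensities: no channel can fire")
  if (is.null(r2)) r2 <- runif(1)
  stopifnot(r2 >= 0, r2 < 1)
  which(cumsum(propensities) > r2 * a0)[1]
}

#' Run the diffusion-collision elongation simulation
#'
#' Gillespie direct-method simulation of ternary complexes walking on a
#' periodic cubic lattice. A complex landing on a site holding a ribosome
#' whose current codon is served by the complex's tRNA species (and whose
#' catalytic idle time has expired) triggers an elongation: the ribosome
#' advances one codon (wrapping to the first codon at the sequence end) and
#' becomes refractory for `t_cat`; the delivered tRNA returns to the free
#' pool, and the freed EFTu instantly re-binds a uniformly chosen free tRNA
#' molecule, placing the new complex at a uniformly random site. Complexes
#' also dissociate with first-order rate `k_diss`, with the same re-binding
#' rule. The run stops after `stop_steps` successful elongations.
#'
#' @param config a [scenario_config()].
#' @param sequence a [codon_sequence()] (every ribosome translates its own
#'   copy of this sequence).
#' @param seed integer seed for the simulation's Mersenne-Twister generator.
#' @param stop_steps,burn_in_steps optional overrides of the scenario's
#'   kinetics values (`burn_in_steps` is only recorded; trimming happens in
#'   the rate-analysis functions).
#' @param map codon -> tRNA species map.
#' @param max_events guard on the total number of SSA events (default 1e9);
#'   exceeding it raises a stall error naming the exhausted tRNA species.
#' @return an `elongation_trace`: data frame with columns `event_index`,
#'   `time_s`, `cumulative_steps`, with attributes `n_ribosomes`, `seed`,
#'   `burn_in_steps`, `config_digest` and `diagnostics` (event counts,
#'   direction counts, final per-species pools).
#' @export
run_simulation <- function(config, sequence, seed = 1, stop_steps = NULL,
                           burn_in_steps = NULL, map = codon_trna_map(),
                           max_events = 1e9) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(stop_steps)) stop_steps <- config$kinetics$stop_steps
  if (is.null(burn_in_steps)) burn_in_steps <- config$kinetics$burn_in_steps
  stopifnot(stop_steps >= 1)

  trna_counts <- round_half_up(config$trna)
  species <- names(trna_counts)
  seq_species <- map_codons(sequence, map)
  missing <- setdiff(unique(seq_species), species)
  if (length(missing)) {
    stop("sequence demands tRNA species absent from the scenario: ",
         paste(missing, collapse = ", "))
  }
  seq_idx <- match(seq_species, species) - 1L

  n_rib <- as.integer(round_half_up(config$machines$ribosomes))
  n_eftu <- as.integer(round_half_up(config$machines$eftu))
  total_trna <- sum(trna_counts)
  n_complex <- min(n_eftu, total_trna)
  if (n_rib < 1) stop("degenerate scenario: no ribosomes")
  if (n_complex < 1) stop("stalled system: no ternary complexes can form")

  h_m <- config$lattice$h_nm * 1e-9
  d_dir <- jump_rate(config$kinetics$D, h_m)

  res <- cpp_run_ssa(
    n_side = config$lattice$points_per_side,
    d_per_dir = d_dir,
    k_diss = config$kinetics$k_diss,
    t_cat = config$kinetics$t_cat,
    n_ribosomes = n_rib,
    n_complexes = as.integer(n_complex),
    trna_total = as.integer(trna_counts),
    seq_species = seq_idx,
    stop_steps = as.integer(stop_steps),
    max_events = as.double(max_events),
    seed = as.integer(seed)
  )
  if (res$stalled) {
    freq <- table(factor(seq_species, levels = species))
    demanded <- species[freq > 0]
    exhausted <- demanded[res$free_final[match(demanded, species)] +
                            res$bound_final[match(demanded, species)] == 0]
    stop("simulation stalled after ", format(res$n_events), " events (",
         length(res$times), "/", stop_steps, " elongations); exhausted ",
         "demanded species: ",
         if (length(exhausted)) paste(exhausted, collapse = ", ") else "none")
  }
  trace <- data.frame(event_index = seq_len(stop_steps),
                      time_s = res$times,
                      cumulative_steps = seq_len(stop_steps))
  diag <- res[c("n_events", "n_jumps", "n_diss", "dir_counts",
                "free_final", "bound_final")]
  names(diag$free_final) <- species
  names(diag$bound_final) <- species
  structure(trace,
            n_ribosomes = n_rib,
            seed = seed,
            burn_in_steps = burn_in_steps,
            config_digest = config_digest(config),
            sequence_name = attr(sequence, "name"),
            diagnostics = diag,
            class = c("elongation_trace", "data.frame"))
}

#' @export
print.elongation_trace <- function(x, ...) {
  cat("elongation_trace:", nrow(x), "events,", attr(x, "n_ribosomes"),
      "ribosomes, seed", attr(x, "seed"), "\n")
  cat("  total time:", format(max(x$time_s), digits = 4), "s\n")
  invisible(x)
}

#' Write an elongation trace and its metadata sidecar
#'
#' @param trace an `elongation_trace`.
#' @param path CSV output path; a `.json` sidecar with seed, config digest and
#'   package version is written next to it.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(seed = attr(trace, "seed"),
               config_digest = attr(trace, "config_digest"),
               n_ribosomes = attr(trace, "n_ribosomes"),
               sequence = attr(trace, "sequence_name"),
               package_version = as.character(utils::packageVersion("elongsim")))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the simulator for a fixed number of SSA events
#'
#' Diagnostic variant of [run_simulation()]: executes exactly `n_events`
#' events (or fewer if `stop_steps` elongations complete first) and returns
#' the engine diagnostics instead of raising a stall error — used to verify
#' conservation invariants over long event sequences.
#'
#' @inheritParams run_simulation
#' @param n_events number of SSA events to execute.
#' @return list with `n_events`, `n_jumps`, `n_diss`, `dir_counts`,
#'   `free_final`, `bound_final` (named per species), `n_elongations`,
#'   `trna_initial` (rounded per-species totals) and `n_complexes`.
#' @export
ssa_diagnostics <- function(config, sequence, n_events, seed = 1,
                            map = codon_trna_map()) {
  stopifnot(inherits(config, "scenario_config"), n_events >= 1)
  trna_counts <- round_half_up(config$trna)
  species <- names(trna_counts)
  seq_idx <- match(map_codons(sequence, map), species) - 1L
  if (anyNA(seq_idx)) stop("sequence demands species absent from the scenario")
  n_rib <- as.integer(round_half_up(config$machines$ribosomes))
  n_complex <- min(as.integer(round_half_up(config$machines$eftu)), sum(trna_counts))
  h_m <- config$lattice$h_nm * 1e-9
  res <- cpp_run_ssa(
    n_side = config$lattice$points_per_side,
    d_per_dir = jump_rate(config$kinetics$D, h_m),
    k_diss = config$kinetics$k_diss,
    t_cat = config$kinetics$t_cat,
    n_ribosomes = n_rib,
    n_complexes = as.integer(n_complex),
    trna_total = as.integer(trna_counts),
    seq_species = seq_idx,
    stop_steps = .Machine$integer.max,
    max_events = as.double(n_events),
    seed = as.integer(seed)
  )
  list(n_events = res$n_events, n_jumps = res$n_jumps, n_diss = res$n_diss,
       dir_counts = res$dir_counts,
       free_final = setNames(res$free_final, species),
       bound_final = setNames(res$bound_final, species),
       n_elongations = length(res$times),
       trna_initial = trna_counts, n_complexes = n_complex)
}

#' Mean squared displacement of non-reacting tracers
#'
#' Runs the lattice walk with reactions disabled and returns per-tracer
#' squared displacements (in m^2) after time `t_end`. Validates the
#' per-direction jump-rate convention against the continuum expectation
#' `MSD = 6 D t`.
#'
#' @param n_tracers number of independent tracers.
#' @param D diffusion coefficient (m^2/s).
#' @param h grid spacing (m).
#' @param t_end tracking time (s).
#' @param seed integer seed.
#' @return numeric vector of squared displacements (m^2).
#' @export
tracer_msd <- function(n_tracers, D, h, t_end, seed = 1) {
  d_dir <- jump_rate(D, h)
  r2_lattice <- cpp_tracer_msd(as.integer(n_tracers), d_dir, t_end,
                               as.integer(seed))
  r2_lattice * h^2
}

#' Ternary-complex lifetimes under jump + dissociation channels
#'
#' Simulates single complexes through the two-channel Gillespie machinery
#' (travel at `6 d` per molecule, dissociation at `k_diss`) and records the
#' time at which dissociation fires. Lifetimes are Exponential(`k_diss`).
#'
#' @param n number of lifetimes.
#' @param d_per_dir per-direction jump rate (1/s).
#' @param k_diss dissociation rate (1/s, > 0).
#' @param seed integer seed.
#' @return numeric vector of lifetimes (s).
#' @export
dissociation_lifetimes <- function(n, d_per_dir, k_diss, seed = 1) {
  stopifnot(k_diss > 0)
  cpp_dissociation_times(as.integer(n), d_per_dir, k_diss, as.integer(seed))
}
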