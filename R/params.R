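#' @useDynLib elongsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median pt runif sd setNames cor.test
#' @importFrom utils read.delim write.csv head tail
NULL

DEFAULT_GROWTH_TAGS <- c("mu1.1")

# molecule counts round half away from zero (52.2 -> 52, 130.5 -> 131)
round_half_up <- function(x) floor(x + 0.5)

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "elongsim")
  if (!nzchar(p)) stop("bundled data file not found: ", file)
  p
}

#' Load the bundled parameter tables for a tagged growth condition
#'
#' Returns the packaged in vivo copy numbers of the translation machinery
#' (actively translating ribosomes and EFTu), the per-species tRNA abundance
#' table, the kinetic constants, and the default lattice specification for a
#' 0.064 um^3 reaction volume. The only bundled tag is `"mu1.1"`, i.e.
#' concentrations at a growth rate of 1.1 per hour.
#'
#' @param growth_rate_tag character tag naming a bundled parameter set.
#' @return A list with elements `machines` (list: `ribosomes`, `eftu`),
#'   `trna` (named numeric vector of molecule counts, possibly fractional as
#'   published), `kinetics` (list: `D` in m^2/s, `k_diss` in 1/s, `t_cat` in s,
#'   `burn_in_steps`, `stop_steps`), and `lattice` (see [lattice_spec()]).
#' @export
load_default_tables <- function(growth_rate_tag = "mu1.1") {
  if (!growth_rate_tag %in% DEFAULT_GROWTH_TAGS) {
    stop("no such parameter set: '", growth_rate_tag,
         "' (bundled tags: ", paste(DEFAULT_GROWTH_TAGS, collapse = ", "), ")")
  }
  mach <- read.delim(extdata_path(paste0("machines_", growth_rate_tag, ".tsv")))
  trna <- read.delim(extdata_path(paste0("trna_", growth_rate_tag, ".tsv")))
  kin <- read.delim(extdata_path("kinetics.tsv"))
  kv <- setNames(kin$value, kin$param)
  machines <- list(
    ribosomes = mach$count[mach$species == "ribosomes"],
    eftu = mach$count[mach$species == "eftu"]
  )
  trna_vec <- setNames(trna$count, trna$species)
  stopifnot(all(trna_vec >= 0), !anyDuplicated(names(trna_vec)),
            sum(trna_vec) >= machines$eftu)
  kinetics <- list(
    D = unname(kv["D_m2_per_s"]),
    k_diss = unname(kv["k_diss_per_s"]),
    t_cat = 1 / unname(kv["max_rate_aa_per_s"]),
    burn_in_steps = unname(kv["burn_in_steps"]),
    stop_steps = unname(kv["stop_steps"])
  )
  list(machines = machines, trna = trna_vec, kinetics = kinetics,
       lattice = lattice_spec(0.064, 20))
}

#' Lattice specification for the reaction volume
#'
#' The reaction space is a cubic periodic lattice with grid spacing `h_nm`.
#' The number of points per side must be an even integer (so the cube root of
#' the volume divided by `h` is required to land within 0.5 of an even
#' integer). The default spacing of 20 nm represents the collision distance of
#' a ternary complex and a ribosome and gives 20 points per side at 0.064 um^3.
#'
#' @param volume_um3 reaction volume in cubic micrometres.
#' @param h_nm grid spacing in nanometres.
#' @param periodic logical; periodic boundary conditions.
#' @return list with `volume_um3`, `h_nm`, `points_per_side`, `periodic`.
#' @export
lattice_spec <- function(volume_um3, h_nm = 20, periodic = TRUE) {
  stopifnot(volume_um3 > 0, h_nm > 0)
  side_nm <- volume_um3^(1 / 3) * 1000
  n <- side_nm / h_nm
  n_even <- 2 * round(n / 2)
  if (n_even < 2 || abs(n - n_even) > 0.5) {
    stop("lattice side of ", format(n), " grid points is not realizable as an ",
         "even integer with h = ", h_nm, " nm")
  }
  list(volume_um3 = volume_um3, h_nm = h_nm, points_per_side = as.integer(n_even),
       periodic = periodic)
}

#' Assemble a simulation scenario
#'
#' @param machines list with `ribosomes` and `eftu` molecule counts.
#' @param trna named numeric vector of per-species tRNA counts.
#' @param kinetics list with `D`, `k_diss`, `t_cat`, `burn_in_steps`,
#'   `stop_steps`.
#' @param lattice a [lattice_spec()].
#' @param rel_conc relative concentration of the scenario (1 = in vivo at
#'   growth rate 1.1 per hour; 0.05 = the 20-fold diluted in vitro setting).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(machines, trna, kinetics, lattice, rel_conc = 1) {
  stopifnot(machines$ribosomes >= 0, machines$eftu >= 0,
            all(trna >= 0), !is.null(names(trna)),
            kinetics$D > 0, kinetics$k_diss >= 0, kinetics$t_cat > 0,
            kinetics$burn_in_steps < kinetics$stop_steps,
            rel_conc > 0)
  structure(list(machines = machines, trna = trna, kinetics = kinetics,
                 lattice = lattice, rel_conc = rel_conc),
            class = "scenario_config")
}

#' Default in vivo scenario
#'
#' Convenience constructor: bundled tables for `growth_rate_tag` in the given
#' reaction volume. Volumes other than 0.064 um^3 are obtained by
#' [rescale_volume()], so concentrations are preserved.
#'
#' @inheritParams load_default_tables
#' @param volume_um3 reaction volume in um^3.
#' @param h_nm lattice spacing in nm.
#' @export
in_vivo_scenario <- function(growth_rate_tag = "mu1.1", volume_um3 = 0.064,
                             h_nm = 20) {
  tabs <- load_default_tables(growth_rate_tag)
  base <- scenario_config(tabs$machines, tabs$trna, tabs$kinetics,
                          lattice_spec(0.064, h_nm), rel_conc = 1)
  if (!isTRUE(all.equal(volume_um3, 0.064))) {
    base <- rescale_volume(base, volume_um3)
  }
  base
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$machines$ribosomes, "ribosomes,",
      x$machines$eftu, "EFTu,", length(x$trna), "tRNA species (total",
      round(sum(x$trna), 1), ") in", x$lattice$volume_um3, "um^3; rel_conc =",
      x$rel_conc, "\n")
  invisible(x)
}

#' Scale all molecule counts by a relative concentration factor
#'
#' Emulates dilution or concentration of the whole translation machinery:
#' ribosome, EFTu and every tRNA species count are multiplied by `rel_conc`
#' and rounded to the nearest integer; kinetics and lattice are unchanged.
#' `rel_conc = 0.05` reproduces the in vitro setting (reactants diluted by a
#' factor of 20).
#'
#' @param base a `scenario_config`.
#' @param rel_conc positive scaling factor.
#' @return a new `scenario_config` with scaled counts; its `rel_conc` field is
#'   multiplied by the factor.
#' @export
scale_scenario <- function(base, rel_conc) {
  stopifnot(inherits(base, "scenario_config"))
  if (!is.numeric(rel_conc) || length(rel_conc) != 1 || rel_conc <= 0) {
    stop("rel_conc must be a single positive number")
  }
  machines <- list(ribosomes = round_half_up(base$machines$ribosomes * rel_conc),
                   eftu = round_half_up(base$machines$eftu * rel_conc))
  trna <- round_half_up(base$trna * rel_conc)
  if (machines$ribosomes == 0 || sum(trna) == 0 || machines$eftu == 0) {
    stop("degenerate scenario: scaling by ", rel_conc,
         " rounds ribosome, EFTu or total tRNA count to 0")
  }
  lost <- names(base$trna)[base$trna > 0 & trna == 0]
  if (length(lost)) {
    message("scale_scenario: species annihilated by rounding at rel_conc = ",
            rel_conc, ": ", paste(lost, collapse = ", "))
  }
  scenario_config(machines, trna, base$kinetics, base$lattice,
                  rel_conc = base$rel_conc * rel_conc)
}

#' Rescale the reaction volume at constant concentrations
#'
#' All molecule counts are multiplied by the volume ratio and rounded, and the
#' lattice side is recomputed; concentrations are preserved (exactly, before
#' rounding). Per-ribosome elongation rates are an intensive property and are
#' statistically unchanged by this operation.
#'
#' @param base a `scenario_config`.
#' @param new_volume_um3 new volume in um^3; its cube root divided by the grid
#'   spacing must land within 0.5 of an even integer.
#' @export
rescale_volume <- function(base, new_volume_um3) {
  stopifnot(inherits(base, "scenario_config"), new_volume_um3 > 0)
  lat <- lattice_spec(new_volume_um3, base$lattice$h_nm, base$lattice$periodic)
  f <- new_volume_um3 / base$lattice$volume_um3
  machines <- list(ribosomes = round_half_up(base$machines$ribosomes * f),
                   eftu = round_half_up(base$machines$eftu * f))
  trna <- round_half_up(base$trna * f)
  if (machines$ribosomes == 0 || sum(trna) == 0 || machines$eftu == 0) {
    stop("degenerate scenario: volume rescale annihilates a required pool")
  }
  scenario_config(machines, trna, base$kinetics, lat, rel_conc = base$rel_conc)
}
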