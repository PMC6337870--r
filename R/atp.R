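#' Cellular amino-acid flux demand
#'
#' Product of ribosomes per cell, the actively translating fraction and the
#' per-ribosome elongation rate. With the textbook values (13,500 ribosomes,
#' 80% active, 16 aa/ribosome/s) this exceeds 170,000 amino acids per second
#' per cell.
#'
#' @param ribosomes_per_cell ribosome count (> 0 unless zero flux intended).
#' @param active_fraction fraction of ribosomes translating (0..1].
#' @param rate_aa_per_s per-ribosome elongation rate (aa/s).
#' @return amino acids per second per cell.
#' @export
flux_demand <- function(ribosomes_per_cell, active_fraction, rate_aa_per_s) {
  stopifnot(ribosomes_per_cell >= 0, active_fraction >= 0,
            active_fraction <= 1, rate_aa_per_s >= 0)
  ribosomes_per_cell * active_fraction * rate_aa_per_s
}

#' ATP-equivalent cost table
#'
#' Per-nucleotide RNA synthesis costs (UTP/TTP 6, CTP 7, ATP 11, GTP 12 ATP
#' equivalents, from the stoichiometric pathways of E. coli), an approximate
#' precursor-excluded amino-acid cost table, and the peptide-bond cost of 4
#' ATP equivalents per translation step.
#'
#' @param aa_costs optional named vector (one-letter amino-acid codes)
#'   overriding the bundled approximate table.
#' @param translation_per_step ATP equivalents per peptide bond (default 4).
#' @return list with `nt_costs`, `aa_costs`, `translation_per_step`.
#' @export
cost_table <- function(aa_costs = NULL, translation_per_step = 4) {
  if (is.null(aa_costs)) {
    tab <- read.delim(extdata_path("aa_costs_approx.tsv"))
    aa_costs <- setNames(tab$atp_equivalents, tab$aa)
  }
  stopifnot(all(aa_costs > 0), translation_per_step > 0)
  list(nt_costs = c(U = 6, T = 6, C = 7, A = 11, G = 12),
       aa_costs = aa_costs,
       translation_per_step = translation_per_step)
}

#' ATP-equivalent cost of an RNA molecule
#'
#' @param nt_counts named counts per base (names among U/T/C/A/G).
#' @param table a [cost_table()].
#' @return total ATP equivalents.
#' @export
rna_cost <- function(nt_counts, table = cost_table()) {
  stopifnot(all(nt_counts >= 0))
  if (length(nt_counts) == 0) return(0)
  unknown <- setdiff(names(nt_counts), names(table$nt_costs))
  if (length(unknown) || is.null(names(nt_counts))) {
    stop("unknown base(s): ", paste(unknown, collapse = ", "))
  }
  sum(nt_counts * table$nt_costs[names(nt_counts)])
}

#' ATP-equivalent cost of a protein
#'
#' Translation costs `translation_per_step` (default 4) ATP equivalents per
#' residue; amino-acid synthesis costs come either from an explicit
#' `synthesis_atp` total (e.g. the published 1989 ATP equivalents for EFTu)
#' or from a residue composition and the cost table.
#'
#' @param n_residues number of residues (>= 0).
#' @param aa_counts optional named residue counts (one-letter codes); must
#'   sum to `n_residues`.
#' @param synthesis_atp optional precomputed amino-acid synthesis cost.
#' @param table a [cost_table()].
#' @return list with `synthesis`, `translation`, `total` (ATP equivalents).
#' @export
protein_cost <- function(n_residues, aa_counts = NULL, synthesis_atp = NULL,
                         table = cost_table()) {
  stopifnot(n_residues >= 0)
  translation <- table$translation_per_step * n_residues
  if (n_residues == 0) return(list(synthesis = 0, translation = 0, total = 0))
  if (!is.null(aa_counts)) {
    if (sum(aa_counts) != n_residues) {
      stop("amino-acid composition (", sum(aa_counts),
           ") inconsistent with n_residues (", n_residues, ")")
    }
    synthesis <- sum(aa_counts * table$aa_costs[names(aa_counts)])
  } else if (!is.null(synthesis_atp)) {
    synthesis <- synthesis_atp
  } else {
    synthesis <- mean(table$aa_costs) * n_residues
  }
  list(synthesis = synthesis, translation = translation,
       total = synthesis + translation)
}

#' Per-molecule ATP synthesis costs of the three translation machines
#'
#' The bundled published constants: 108,461 ATP equivalents per ribosome
#' (rRNA 42,934 + ribosomal-protein amino acids 35,689 + their translation
#' 29,836; the printed total differs by 2 from the printed components and the
#' printed total is shipped), 700 per average 76-nt tRNA, 3,565 per EFTu
#' (1,989 amino-acid synthesis + 1,576 translation).
#'
#' @return named numeric vector `c(ribosome, trna, eftu)`.
#' @export
unit_costs <- function() {
  c(ribosome = 108461, trna = 700, eftu = 3565)
}

#' Split an ATP budget into added machine molecules
#'
#' `added_k = floor(share_k * budget / cost_k)` for ribosomes, tRNA and EFTu.
#' Added tRNA molecules are distributed over the species of a baseline
#' abundance table, proportionally to baseline abundance with
#' largest-remainder rounding (alternatively uniformly per species).
#'
#' @param budget ATP molecules available (>= 0).
#' @param shares numeric length 3 `(ribosome, trna, eftu)` on the simplex.
#' @param costs per-molecule costs, default [unit_costs()].
#' @param trna_baseline optional named abundance vector governing the
#'   per-species split of added tRNAs.
#' @param trna_split `"proportional"` (default) or `"uniform"`.
#' @return list with `added` (named counts: ribosome, trna, eftu), `spent`
#'   (ATP actually consumed, <= budget) and `trna_by_species` when a baseline
#'   was supplied.
#' @export
allocate_atp <- function(budget, shares, costs = unit_costs(),
                         trna_baseline = NULL,
                         trna_split = c("proportional", "uniform")) {
  trna_split <- match.arg(trna_split)
  stopifnot(budget >= 0, length(shares) == 3, all(shares >= 0),
            isTRUE(all.equal(sum(shares), 1)))
  added <- floor(shares * budget / costs)
  names(added) <- names(costs)
  out <- list(added = added, spent = sum(added * costs))
  if (!is.null(trna_baseline)) {
    n <- added[["trna"]]
    if (trna_split == "proportional") {
      w <- trna_baseline / sum(trna_baseline)
    } else {
      w <- rep(1 / length(trna_baseline), length(trna_baseline))
    }
    exact <- w * n
    base_int <- floor(exact)
    rem <- n - sum(base_int)
    if (rem > 0) {
      order_rem <- order(exact - base_int, decreasing = TRUE)
      base_int[order_rem[seq_len(rem)]] <- base_int[order_rem[seq_len(rem)]] + 1
    }
    out$trna_by_species <- setNames(base_int, names(trna_baseline))
  }
  out
}

#' Simplex grid of budget shares
#'
#' All `(i, j, k) / n` triples with `i + j + k = n`, i.e. `C(n + 2, 2)`
#' points at resolution `1/n`.
#'
#' @param resolution grid step; `1/resolution` must be an integer.
#' @return data frame with columns `share_ribosome`, `share_trna`,
#'   `share_eftu`.
#' @export
simplex_grid <- function(resolution = 1 / 8) {
  n <- 1 / resolution
  if (abs(n - round(n)) > 1e-9) stop("resolution must divide 1 evenly")
  n <- as.integer(round(n))
  pts <- expand.grid(i = 0:n, j = 0:n)
  pts <- pts[pts$i + pts$j <= n, ]
  data.frame(share_ribosome = pts$i / n, share_trna = pts$j / n,
             share_eftu = (n - pts$i - pts$j) / n)
}

augment_scenario <- function(base, alloc) {
  machines <- base$machines
  machines$ribosomes <- machines$ribosomes + alloc$added[["ribosome"]]
  machines$eftu <- machines$eftu + alloc$added[["eftu"]]
  trna <- base$trna
  if (!is.null(alloc$trna_by_species)) {
    trna <- trna + alloc$trna_by_species[names(trna)]
  }
  scenario_config(machines, trna, base$kinetics, base$lattice, base$rel_conc)
}

#' Sweep translation rate over the ATP-allocation simplex
#'
#' For every grid point of budget shares, converts the shares into added
#' ribosome/tRNA/EFTu molecules via [allocate_atp()], augments the base
#' scenario, estimates the replicate elongation rate, and normalizes it to
#' the unaltered scenario's rate (same replicate seeds). Returns the grid
#' with normalized rates and the argmax row.
#'
#' @param base a [scenario_config()].
#' @param sequence a [codon_sequence()].
#' @param budget ATP molecules per reaction volume.
#' @param resolution simplex grid step (default 1/8).
#' @param n_seeds replicates per grid point.
#' @param master_seed shared master seed.
#' @param stop_steps,burn_in_steps optional overrides.
#' @param trna_split per-species split rule for added tRNAs.
#' @return list with `grid` (data frame: shares, added counts, `norm_rate`,
#'   `se`), `baseline` rate estimate, and `argmax` (row of `grid`).
#' @export
simplex_sweep <- function(base, sequence, budget, resolution = 1 / 8,
                          n_seeds = 10, master_seed = 1, stop_steps = NULL,
                          burn_in_steps = NULL,
                          trna_split = c("proportional", "uniform")) {
  trna_split <- match.arg(trna_split)
  grid <- simplex_grid(resolution)
  baseline <- replicate_rate(base, sequence, n_seeds, master_seed,
                             stop_steps = stop_steps,
                             burn_in_steps = burn_in_steps)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    shares <- as.numeric(grid[i, ])
    alloc <- allocate_atp(budget, shares, trna_baseline = base$trna,
                          trna_split = trna_split)
    res <- tryCatch({
      cfg <- augment_scenario(base, alloc)
      est <- replicate_rate(cfg, sequence, n_seeds, master_seed,
                            stop_steps = stop_steps,
                            burn_in_steps = burn_in_steps)
      # normalized TRANSLATION rate of the volume: per-ribosome rate times
      # ribosome count, relative to the unaltered scenario
      norm <- (est$rate * round_half_up(cfg$machines$ribosomes)) /
        (baseline$rate * round_half_up(base$machines$ribosomes))
      se <- norm * sqrt((est$se / est$rate)^2 +
                          (baseline$se / baseline$rate)^2)
      c(norm_rate = norm, se = se)
    }, error = function(e) {
      warning("grid point ", i, " stalled: ", conditionMessage(e),
              call. = FALSE)
      c(norm_rate = NA_real_, se = NA_real_)
    })
    data.frame(grid[i, ],
               added_r = alloc$added[["ribosome"]],
               added_t = alloc$added[["trna"]],
               added_e = alloc$added[["eftu"]],
               norm_rate = res[["norm_rate"]], se = res[["se"]],
               row.names = NULL)
  })
  grid_out <- do.call(rbind, rows)
  argmax <- grid_out[which.max(grid_out$norm_rate), ]
  list(grid = grid_out, baseline = baseline, argmax = argmax)
}

#' Put an ATP amount into cellular production context
#'
#' Given an ATP amount in fmol per cell, the E. coli ATP pool size and
#' turnover, returns how many minutes of ATP production the amount
#' represents and which fraction of the per-doubling ATP synthesis that is.
#'
#' @param amount_fmol ATP amount (fmol per cell).
#' @param pool_amol ATP pool size (amol per cell, default 3.56).
#' @param turnover_per_min pool turnovers per minute (default 311).
#' @param doubling_min doubling time in minutes (default 38, growth rate 1.1
#'   per hour).
#' @return list with `minutes` and `fraction` (of per-doubling synthesis).
#' @export
atp_context <- function(amount_fmol, pool_amol = 3.56, turnover_per_min = 311,
                        doubling_min = 38) {
  stopifnot(amount_fmol >= 0, pool_amol > 0, turnover_per_min > 0,
            doubling_min > 0)
  minutes <- amount_fmol * 1000 / (pool_amol * turnover_per_min)
  list(minutes = minutes, fraction = minutes / doubling_min)
}
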