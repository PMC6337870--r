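#' Central log-log finite-difference sensitivity
#'
#' Generic estimator used by [elasticity()] and [fcc()]:
#' `est = (ln v_plus - ln v_minus) / (ln c_plus - ln c_minus)`, with the
#' standard error propagated from the replicate standard errors of the two
#' rates. Applied to noise-free power laws `v = k c^a` it returns `a`
#' exactly.
#'
#' @param c_minus,c_plus the two perturbed concentrations (or factors).
#' @param v_minus,v_plus the rates measured there.
#' @param se_minus,se_plus standard errors of the rates.
#' @return list with `est` and `se`.
#' @export
log_sensitivity <- function(c_minus, c_plus, v_minus, v_plus,
                            se_minus = 0, se_plus = 0) {
  stopifnot(c_minus > 0, c_plus > 0, v_minus > 0, v_plus > 0,
            c_minus != c_plus)
  dlnc <- log(c_plus) - log(c_minus)
  est <- (log(v_plus) - log(v_minus)) / dlnc
  se <- sqrt((se_plus / v_plus)^2 + (se_minus / v_minus)^2) / abs(dlnc)
  list(est = est, se = se)
}

#' Power-law exponent from a rate table
#'
#' OLS regression of `ln rate` on `ln conc`; the brute-force counterpart of
#' the two-point central difference.
#'
#' @param conc,rate positive numeric vectors.
#' @return slope of the log-log regression.
#' @export
power_law_exponent <- function(conc, rate) {
  stopifnot(all(conc > 0), all(rate > 0), length(conc) == length(rate))
  unname(coef(lm(log(rate) ~ log(conc)))[2])
}

#' Elongation rate across a relative-concentration sweep
#'
#' Scales ribosome, EFTu and all tRNA levels together by each factor in
#' `rel_concs` and estimates the replicate elongation rate at each point.
#' Degenerate scenarios (a required pool rounding to zero) are skipped with a
#' warning.
#'
#' @param base a [scenario_config()].
#' @param sequence a [codon_sequence()].
#' @param rel_concs positive factors (1 = in vivo, 0.05 = in vitro).
#' @param n_seeds replicates per point.
#' @param master_seed master seed (same replicate seeds at every point).
#' @param stop_steps,burn_in_steps window at `rel_conc = 1` (default: the
#'   scenario's kinetics values).
#' @param scale_windows scale the analysis window with the scaled ribosome
#'   count (default). The system event rate grows with the ribosome pool, so
#'   a fixed event count samples less relaxation time at high concentration;
#'   proportional windows keep per-ribosome sampling equal across the sweep
#'   (floors: 400 stop / 160 burn-in events).
#' @return data frame with columns `rel_conc`, `rate`, `se`, `n_seeds`; the
#'   per-seed rates are attached as attribute `per_seed` (long data frame).
#' @export
concentration_sweep <- function(base, sequence, rel_concs, n_seeds = 10,
                                master_seed = 1, stop_steps = NULL,
                                burn_in_steps = NULL, scale_windows = TRUE) {
  stopifnot(all(rel_concs > 0))
  if (is.null(stop_steps)) stop_steps <- base$kinetics$stop_steps
  if (is.null(burn_in_steps)) burn_in_steps <- base$kinetics$burn_in_steps
  per_seed <- list()
  rows <- lapply(rel_concs, function(rc) {
    st <- stop_steps
    bi <- burn_in_steps
    if (scale_windows) {
      st <- max(400, round(stop_steps * rc))
      bi <- max(160, round(burn_in_steps * rc))
    }
    est <- tryCatch({
      cfg <- scale_scenario(base, rc)
      replicate_rate(cfg, sequence, n_seeds = n_seeds,
                     master_seed = master_seed, stop_steps = st,
                     burn_in_steps = bi)
    }, error = function(e) {
      warning("rel_conc ", rc, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(est)) return(NULL)
    per_seed[[as.character(rc)]] <<- data.frame(rel_conc = rc,
                                                rate = est$per_seed)
    data.frame(rel_conc = rc, rate = est$rate, se = est$se,
               n_seeds = n_seeds)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "per_seed") <- do.call(rbind, c(per_seed, make.row.names = FALSE))
  out
}

perturb_scenario <- function(base, factor, target = c("substrate", "ribosomes")) {
  target <- match.arg(target)
  machines <- base$machines
  trna <- base$trna
  if (target == "substrate") {
    machines$eftu <- round_half_up(machines$eftu * factor)
    trna <- round_half_up(trna * factor)
  } else {
    machines$ribosomes <- round_half_up(machines$ribosomes * factor)
  }
  scenario_config(machines, trna, base$kinetics, base$lattice, base$rel_conc)
}

control_estimate <- function(base, sequence, delta, n_seeds, master_seed,
                             target, stop_steps, burn_in_steps) {
  stopifnot(delta > 0, delta < 1)
  lo <- perturb_scenario(base, 1 - delta, target)
  hi <- perturb_scenario(base, 1 + delta, target)
  v_lo <- replicate_rate(lo, sequence, n_seeds, master_seed,
                         stop_steps = stop_steps,
                         burn_in_steps = burn_in_steps)
  v_hi <- replicate_rate(hi, sequence, n_seeds, master_seed,
                         stop_steps = stop_steps,
                         burn_in_steps = burn_in_steps)
  # v_TL is the translation rate of the whole volume: when the ribosome pool
  # itself is perturbed, the per-ribosome normalization must be undone.
  r_lo <- round_half_up(lo$machines$ribosomes)
  r_hi <- round_half_up(hi$machines$ribosomes)
  out <- log_sensitivity(1 - delta, 1 + delta,
                         v_lo$rate * r_lo, v_hi$rate * r_hi,
                         v_lo$se * r_lo, v_hi$se * r_hi)
  if (is.finite(out$est) && out$est != 0 && out$se > abs(out$est)) {
    warning("perturbation delta = ", delta, " too small for the replicate ",
            "noise: SE/estimate = ", sprintf("%.2f", out$se / abs(out$est)),
            call. = FALSE)
  }
  out
}

#' Elasticity of the translation rate over ternary-complex concentration
#'
#' Central finite difference of `ln v` over `ln c` where the substrate pool
#' (EFTu and every tRNA species jointly, since complexes are EFTu-limited) is
#' scaled by `1 - delta` and `1 + delta` while ribosomes are held fixed.
#'
#' @param base a [scenario_config()].
#' @param sequence a [codon_sequence()].
#' @param delta relative perturbation (default 0.1).
#' @param n_seeds replicates per perturbed point.
#' @param master_seed master seed (shared by both points, paired comparison).
#' @param stop_steps,burn_in_steps optional overrides.
#' @return a `control_coefficients` list: `elasticity_T3`, `se_elasticity`,
#'   `rel_conc`.
#' @export
elasticity <- function(base, sequence, delta = 0.1, n_seeds = 10,
                       master_seed = 1, stop_steps = NULL,
                       burn_in_steps = NULL) {
  est <- control_estimate(base, sequence, delta, n_seeds, master_seed,
                          "substrate", stop_steps, burn_in_steps)
  structure(list(elasticity_T3 = est$est, se_elasticity = est$se,
                 rel_conc = base$rel_conc, delta = delta, n_seeds = n_seeds),
            class = "control_coefficients")
}

#' Flux control coefficient of the ribosome pool
#'
#' Same central-difference estimator as [elasticity()], scaling the ribosome
#' ("enzyme") count only.
#'
#' @inheritParams elasticity
#' @return a `control_coefficients` list: `fcc`, `se_fcc`, `rel_conc`.
#' @export
fcc <- function(base, sequence, delta = 0.1, n_seeds = 10, master_seed = 1,
                stop_steps = NULL, burn_in_steps = NULL) {
  est <- control_estimate(base, sequence, delta, n_seeds, master_seed,
                          "ribosomes", stop_steps, burn_in_steps)
  structure(list(fcc = est$est, se_fcc = est$se,
                 rel_conc = base$rel_conc, delta = delta, n_seeds = n_seeds),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  if (!is.null(x$elasticity_T3)) {
    cat(sprintf("elasticity_T3 = %.3f (se %.3f) at rel_conc %.3g\n",
                x$elasticity_T3, x$se_elasticity, x$rel_conc))
  }
  if (!is.null(x$fcc)) {
    cat(sprintf("FCC = %.3f (se %.3f) at rel_conc %.3g\n",
                x$fcc, x$se_fcc, x$rel_conc))
  }
  invisible(x)
}
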