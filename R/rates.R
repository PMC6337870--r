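trim_trace <- function(trace, burn_in) {
  n <- nrow(trace)
  if (n <= burn_in + 1) {
    stop("trace too short: ", n, " events with burn-in ", burn_in)
  }
  trace[(burn_in + 1):n, , drop = FALSE]
}

#' Encounter-time statistics after burn-in
#'
#' Summarizes the times between successive successful elongation events
#' (`t_enc,s`, whole reaction volume) after discarding the burn-in, during
#' which the initial random molecule placement has not yet relaxed.
#'
#' @param trace an `elongation_trace`.
#' @param burn_in number of leading elongation events to discard (default:
#'   the trace's recorded burn-in, 1000 for the in vivo defaults).
#' @return list with `mean`, `median`, `sd` (seconds) and `n` intervals.
#' @export
encounter_stats <- function(trace, burn_in = attr(trace, "burn_in_steps")) {
  kept <- trim_trace(trace, burn_in)
  dt <- diff(kept$time_s)
  list(mean = mean(dt), median = median(dt), sd = sd(dt), n = length(dt))
}

#' Ribosome-specific elongation rate from a single trace
#'
#' Ordinary least-squares slope of cumulative elongation count over event
#' times (after burn-in), normalized by the total ribosome count in the
#' volume.
#'
#' @inheritParams encounter_stats
#' @return a `rate_estimate`: list with `rate` (aa per ribosome per second),
#'   `se` (`NA` for a single trace), `n_seeds`, `window` and the raw system
#'   `slope` with its OLS standard error.
#' @export
elongation_rate <- function(trace, burn_in = attr(trace, "burn_in_steps")) {
  kept <- trim_trace(trace, burn_in)
  if (diff(range(kept$time_s)) <= 0) {
    stop("degenerate trace: all events at one time point")
  }
  fit <- lm(cumulative_steps ~ time_s, data = kept)
  slope <- unname(coef(fit)["time_s"])
  # suppress the "essentially perfect fit" note on exactly linear traces
  slope_se <- suppressWarnings(
    summary(fit)$coefficients["time_s", "Std. Error"]
  )
  n_rib <- attr(trace, "n_ribosomes")
  structure(list(rate = slope / n_rib, se = NA_real_, n_seeds = 1L,
                 window = c(burn_in + 1, nrow(trace)),
                 slope = slope, slope_se = slope_se, n_ribosomes = n_rib),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: %.3f aa/ribosome/s (se %s, n_seeds %d)\n",
              x$rate, ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)),
              x$n_seeds))
  invisible(x)
}

#' Replicate elongation rate over independent seeds
#'
#' Runs the simulation with `n_seeds` seeds derived deterministically from a
#' master seed and reports the mean rate and its standard error across
#' replicates.
#'
#' @param config a [scenario_config()].
#' @param sequence a [codon_sequence()].
#' @param n_seeds number of replicate runs (>= 2).
#' @param master_seed integer; per-replicate seeds are derived from it.
#' @param stop_steps,burn_in_steps optional overrides.
#' @param map codon -> species map.
#' @return a `rate_estimate` with `per_seed` rates attached.
#' @export
replicate_rate <- function(config, sequence, n_seeds = 10, master_seed = 1,
                           stop_steps = NULL, burn_in_steps = NULL,
                           map = codon_trna_map()) {
  stopifnot(n_seeds >= 2)
  seeds <- derive_seeds(master_seed, n_seeds)
  rates <- vapply(seq_len(n_seeds), function(i) {
    tr <- tryCatch(
      run_simulation(config, sequence, seed = seeds[i], stop_steps = stop_steps,
                     burn_in_steps = burn_in_steps, map = map),
      error = function(e) stop("replicate with seed ", seeds[i], " failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    elongation_rate(tr)$rate
  }, numeric(1))
  structure(list(rate = mean(rates), se = sd(rates) / sqrt(n_seeds),
                 n_seeds = n_seeds,
                 window = c((if (is.null(burn_in_steps))
                   config$kinetics$burn_in_steps else burn_in_steps) + 1,
                   if (is.null(stop_steps)) config$kinetics$stop_steps
                   else stop_steps),
                 per_seed = rates, seeds = seeds),
            class = "rate_estimate")
}

#' z-score comparison of two elongation-trace slopes
#'
#' Compares the OLS slopes of cumulative steps over time for two traces on a
#' common event window using the z statistic
#' `z = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with `df = n1 + n2 - 4` and a
#' two-sided Student-t p-value. The default window (events 1001..3000, 2000
#' points each) gives df = 3996.
#'
#' @param trace_a,trace_b `elongation_trace` objects covering the window.
#' @param burn_in events to discard.
#' @param window_end last event index used.
#' @return list with `z`, `df`, `p`, and the two slopes with SEs.
#' @export
compare_slopes <- function(trace_a, trace_b, burn_in = 1000,
                           window_end = 3000) {
  fit_one <- function(trace) {
    if (nrow(trace) < window_end) {
      stop("window end ", window_end, " exceeds trace length ", nrow(trace))
    }
    kept <- trace[(burn_in + 1):window_end, , drop = FALSE]
    fit <- lm(cumulative_steps ~ time_s, data = kept)
    list(b = unname(coef(fit)["time_s"]),
         se = suppressWarnings(
           summary(fit)$coefficients["time_s", "Std. Error"]
         ),
         n = nrow(kept))
  }
  a <- fit_one(trace_a)
  b <- fit_one(trace_b)
  z <- (a$b - b$b) / sqrt(a$se^2 + b$se^2)
  df <- a$n + b$n - 4
  p <- 2 * pt(-abs(z), df)
  list(z = z, df = df, p = p,
       slope_a = a$b, se_a = a$se, slope_b = b$b, se_b = b$se)
}

#' Export a rate table as TSV
#'
#' @param rates data frame (e.g. from [concentration_sweep()]).
#' @param path output file.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
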