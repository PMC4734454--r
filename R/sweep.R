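# Parameter sweeps over the LHW x LPS grid -------------------------------

#' Specification of a parameter sweep
#'
#' The default grid is the full design: LHW in {0, 180, 720, 5400,
#' 21600} minutes, LPS in {0, 0.5, 0.9, 0.95, 0.99}, 10 replicates per
#' cell (250 runs at the full 2-year horizon).  Scaled tiers substitute a
#' shorter horizon via `preset`.
#'
#' @param lhw_values LIKE-history weights (minutes).
#' @param lps_values partner selectivities in `[0, 1]`.
#' @param replicates independent runs per cell.
#' @param base_seed integer; per-run seeds are derived deterministically.
#' @param preset "full", "desk" or "smoke" run tier (see
#'   [preset_params()]).
#' @return object of class `emo_sweep_spec`.
#' @export
sweep_spec <- function(lhw_values = c(0, 180, 720, 5400, 21600),
                       lps_values = c(0, 0.5, 0.9, 0.95, 0.99),
                       replicates = 10L, base_seed = 1L,
                       preset = "full") {
  stopifnot(all(lps_values >= 0 & lps_values <= 1), replicates >= 1)
  out <- list(lhw_values = lhw_values, lps_values = lps_values,
              replicates = as.integer(replicates),
              base_seed = as.integer(base_seed), preset = preset)
  class(out) <- "emo_sweep_spec"
  out
}

#' Derive a per-run seed
#'
#' A pure function of `(base_seed, lhw, lps, replicate)`, kept below
#' 2^31.  Distinct cells and replicates get distinct seeds with
#' overwhelming probability for the grids in use.
#'
#' @param base_seed integer.
#' @param lhw,lps cell coordinates.
#' @param replicate replicate index.
#' @return integer seed.
#' @export
derive_seed <- function(base_seed, lhw, lps, replicate) {
  h <- (as.double(base_seed) * 2654435761 +
        as.double(lhw) * 97003 +
        round(lps * 1000) * 8191 +
        as.double(replicate) * 131071) %% 2147483629
  as.integer(h) + 1L
}

#' Run a sweep over the LHW x LPS grid
#'
#' Runs `replicates` independent simulations per grid cell with
#' deterministically derived seeds and returns one summary row per run.
#' Per-run failures are caught and reported; the affected cell is marked
#' incomplete.
#'
#' @param spec an [sweep_spec()] object.
#' @param params base parameters; `lhw`/`lps` and the preset horizon are
#'   overridden per cell.  Defaults to the preset named in `spec`.
#' @param progress print per-run progress to stderr.
#' @return data.frame of class `emo_sweep` with one row per run and the
#'   summary statistics as columns.
#' @export
run_sweep <- function(spec, params = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "emo_sweep_spec"))
  rows <- list()
  for (lhw in spec$lhw_values) for (lps in spec$lps_values) {
    for (rep_i in seq_len(spec$replicates)) {
      p <- if (is.null(params)) preset_params(spec$preset, lhw = lhw, lps = lps)
           else { q <- params; q$lhw <- lhw; q$lps <- lps; q }
      seed <- derive_seed(spec$base_seed, lhw, lps, rep_i)
      if (progress)
        message(sprintf("run lhw=%g lps=%g rep=%d seed=%d", lhw, lps,
                        rep_i, seed))
      s <- tryCatch(summarize_run(emo_run(p, seed)),
                    error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(s, "error")) {
        data.frame(lhw = lhw, lps = lps, replicate = rep_i, seed = seed,
                   ok = FALSE, error = conditionMessage(s),
                   group_groom_rate = NA, mean_bout_min = NA,
                   n_pref_partners_month = NA, pref_bout_months = NA,
                   pref_total_months = NA, groom_like_r = NA, tau_rw = NA)
      } else {
        data.frame(lhw = lhw, lps = lps, replicate = rep_i, seed = seed,
                   ok = TRUE, error = NA_character_,
                   group_groom_rate = s$group_groom_rate,
                   mean_bout_min = s$mean_bout_min,
                   n_pref_partners_month = s$n_pref_partners_month,
                   pref_bout_months = s$pref_bout_months,
                   pref_total_months = s$pref_total_months,
                   groom_like_r = s$groom_like_r,
                   tau_rw = s$tau_rw)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("emo_sweep", "data.frame")
  out
}

#' Aggregate a sweep table per cell
#'
#' Cell means of every summary statistic, with correlations pooled on the
#' Fisher-z scale.  The aggregation is invariant to replicate order.
#'
#' @param table an `emo_sweep` data.frame from [run_sweep()].
#' @return data.frame with one row per (lhw, lps) cell.
#' @export
aggregate_sweep <- function(table) {
  sp <- split(as.data.frame(table), list(table$lhw, table$lps), drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(
      lhw = d$lhw[1], lps = d$lps[1],
      n_runs = nrow(d), n_ok = sum(d$ok),
      group_groom_rate = mean(d$group_groom_rate, na.rm = TRUE),
      mean_bout_min = mean(d$mean_bout_min, na.rm = TRUE),
      n_pref_partners_month = mean(d$n_pref_partners_month, na.rm = TRUE),
      pref_bout_months = mean(d$pref_bout_months, na.rm = TRUE),
      pref_total_months = mean(d$pref_total_months, na.rm = TRUE),
      groom_like_r = fisher_z_mean(d$groom_like_r),
      tau_rw = mean(d$tau_rw, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lhw, out$lps), ]
}

#' Null-model invariance check
#'
#' At LPS = 0 partner choice never consults LIKE attitudes, so the
#' grooming-rate distribution must not depend on the LIKE-history weight.
#' Compares the per-run group grooming rates across the LHW values
#' present at LPS = 0 (Kruskal-Wallis) and flags a violation at
#' `alpha`.
#'
#' @param table an `emo_sweep` data.frame containing LPS = 0 cells for at
#'   least two LHW values.
#' @param alpha significance level (default 0.01).
#' @return list with `p_value`, `flagged`, and the per-LHW rate summary.
#' @export
null_model_check <- function(table, alpha = 0.01) {
  d <- as.data.frame(table)
  d <- d[d$lps == 0 & d$ok, ]
  if (length(unique(d$lhw)) < 2)
    stop("need LPS = 0 cells for at least two LHW values")
  rates <- d$group_groom_rate
  g <- factor(d$lhw)
  p <- if (length(unique(rates)) == 1) 1
       else stats::kruskal.test(rates, g)$p.value
  list(p_value = p, flagged = p < alpha,
       by_lhw = tapply(rates, g, mean))
}
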