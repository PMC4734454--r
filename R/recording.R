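# Run-level summaries and I/O -------------------------------------------

#' Summarize a simulation run
#'
#' Computes the headline statistics of a recorded run: the dyadic LIKE
#' and grooming-rate matrices averaged over the last recorded year (or
#' the whole recording when shorter), the group-mean grooming rate, the
#' mean grooming-bout duration, the mean number of preferred partners per
#' month, the group means of the preference bout duration and total
#' preference duration, the row-wise Pearson correlation between grooming
#' rates and LIKE attitudes, and the row-wise Kendall tau reciprocity of
#' the total preference durations.
#'
#' @param run an `emo_run` object from [emo_run()].
#' @param zero_for_no_bouts if `TRUE` (default) dyads without any
#'   preference bout contribute 0 to the group-mean bout duration; if
#'   `FALSE` they are excluded.
#' @return object of class `emo_run_summary`.
#' @export
summarize_run <- function(run, zero_for_no_bouts = TRUE) {
  stopifnot(inherits(run, "emo_run"))
  p <- run$params
  n <- p$n_agents
  n_samp <- run$n_intervals
  partial <- run$record_minutes < 2 * p$year_minutes
  # last-year window of sampling intervals
  per_year <- floor(p$year_minutes / p$sample_interval)
  idx <- if (n_samp > per_year) (n_samp - per_year + 1):n_samp
         else seq_len(max(n_samp, 0))
  like_mat <- groom_rate <- matrix(NA_real_, n, n)
  if (length(idx)) {
    like_mat <- apply(run$like_samples[, , idx, drop = FALSE], c(1, 2), mean)
    rates <- hourly_rates(run$groom_interval[, , idx, drop = FALSE],
                          p$sample_interval)
    groom_rate <- rates$dyadic
    diag(groom_rate) <- NA
    group_rate <- rates$group_mean
  } else group_rate <- NA_real_
  mean_bout_min <- if (nrow(run$bouts)) mean(run$bouts$duration) else NA_real_

  n_mon <- run$n_months
  if (n_mon > 0) {
    pref <- preference_series(run$groom_month[, , seq_len(n_mon), drop = FALSE],
                              p$pref_threshold)
    n_pref_month <- mean(apply(pref, c(1, 3), sum))  # per actor per month
    dur <- preference_durations(pref)
    mb <- dur$mean_bout[upper.tri(dur$mean_bout) | lower.tri(dur$mean_bout)]
    if (!zero_for_no_bouts) mb <- mb[mb > 0]
    pref_bout_months <- if (length(mb)) mean(mb) else NA_real_
    pref_total_months <- mean(dur$total, na.rm = TRUE)
    tau_rw <- suppressWarnings(as.numeric(tau_rw_reciprocity(dur$total)))
    total_matrix <- dur$total
  } else {
    pref <- NULL
    n_pref_month <- pref_bout_months <- pref_total_months <- tau_rw <- NA_real_
    total_matrix <- NULL
  }
  groom_like_r <- if (length(idx))
    suppressWarnings(as.numeric(rowwise_pearson(groom_rate, like_mat)))
  else NA_real_

  out <- list(
    seed = run$seed, lhw = p$lhw, lps = p$lps,
    record_minutes = run$record_minutes,
    n_months = n_mon, n_intervals = n_samp, partial = partial,
    like_mat = like_mat, groom_rate = groom_rate,
    group_groom_rate = group_rate,
    mean_bout_min = mean_bout_min,
    n_bouts = nrow(run$bouts),
    n_pref_partners_month = n_pref_month,
    pref_bout_months = pref_bout_months,
    pref_total_months = pref_total_months,
    groom_like_r = groom_like_r,
    tau_rw = tau_rw,
    pref_total_matrix = total_matrix
  )
  class(out) <- "emo_run_summary"
  out
}

#' @rdname summarize_run
#' @param object,... method arguments.
#' @export
summary.emo_run <- function(object, ...) summarize_run(object, ...)

#' @export
print.emo_run <- function(x, ...) {
  cat("<emo_run>\n")
  cat(sprintf("  seed %d | LHW = %g min, LPS = %g\n",
              x$seed, x$params$lhw, x$params$lps))
  cat(sprintf("  recorded %g min (%.2f months) after %g min stabilization\n",
              x$record_minutes, x$record_minutes / x$params$month_minutes,
              x$stab_minutes))
  cat(sprintf("  %d activations, %d grooming bouts, %d attacks (%d fights)\n",
              x$counters$activations, x$counters$bouts,
              x$counters$attacks, x$counters$fights))
  cat(sprintf("  %d LIKE samples, %d monthly blocks\n",
              x$n_intervals, x$n_months))
  invisible(x)
}

#' @export
print.emo_run_summary <- function(x, ...) {
  cat("<emo_run_summary>\n")
  cat(sprintf("  LHW = %g min, LPS = %g, %.2f recorded months%s\n",
              x$lhw, x$lps, x$record_minutes / 21000,
              if (x$partial) " (partial horizon)" else ""))
  cat(sprintf("  group grooming rate:   %.3f min/h\n", x$group_groom_rate))
  cat(sprintf("  mean grooming bout:    %.2f min (%d bouts)\n",
              x$mean_bout_min, x$n_bouts))
  cat(sprintf("  preferred partners:    %.2f per actor-month\n",
              x$n_pref_partners_month))
  cat(sprintf("  preference bout:       %.2f months (mean)\n",
              x$pref_bout_months))
  cat(sprintf("  total preference:      %.2f months (mean)\n",
              x$pref_total_months))
  cat(sprintf("  grooming~LIKE r (rw):  %.3f\n", x$groom_like_r))
  cat(sprintf("  reciprocity tau_rw:    %.3f\n", x$tau_rw))
  invisible(x)
}

#' Plot dyadic matrices of a run
#'
#' Heatmaps of the year-averaged grooming-rate and LIKE matrices (actors
#' as rows ordered by dominance, receivers as columns).
#'
#' @param x an `emo_run` object.
#' @param which "groom", "like", or both.
#' @param ... ignored.
#' @export
plot.emo_run <- function(x, which = c("groom", "like"), ...) {
  s <- summarize_run(x)
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  shade <- grDevices::hcl.colors(64, "Blues 3", rev = TRUE)
  for (w in which) {
    m <- if (w == "groom") s$groom_rate else s$like_mat
    graphics::image(t(m)[, nrow(m):1], col = shade, axes = FALSE,
                    main = if (w == "groom") "grooming rate (min/h)"
                           else "LIKE attitude")
    graphics::mtext("receiver rank", 1, 1)
    graphics::mtext("actor rank", 2, 1)
  }
  invisible(x)
}

#' Write a run to CSV files
#'
#' Serializes a run into a directory: `like_samples.csv` (time, actor,
#' receiver, value), `groom_minutes.csv` (interval, actor, receiver,
#' minutes), `bouts.csv`, optionally `events.csv`, and a
#' `manifest.json` echoing seed and parameters.
#'
#' @param run an `emo_run` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- run$params$n_agents
  if (run$n_intervals > 0) {
    ls <- run$like_samples
    df <- data.frame(
      time = rep(run$sample_times, each = n * n),
      actor = rep(rep(seq_len(n), n), run$n_intervals),
      receiver = rep(rep(seq_len(n), each = n), run$n_intervals),
      value = as.vector(ls))
    utils::write.csv(df[df$actor != df$receiver, ],
                     file.path(dir, "like_samples.csv"), row.names = FALSE)
    gm <- run$groom_interval
    df <- data.frame(
      interval = rep(seq_len(run$n_intervals), each = n * n),
      actor = rep(rep(seq_len(n), n), run$n_intervals),
      receiver = rep(rep(seq_len(n), each = n), run$n_intervals),
      minutes = as.vector(gm))
    utils::write.csv(df[df$actor != df$receiver, ],
                     file.path(dir, "groom_minutes.csv"), row.names = FALSE)
  }
  utils::write.csv(run$bouts, file.path(dir, "bouts.csv"), row.names = FALSE)
  if (!is.null(run$events))
    utils::write.csv(run$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  manifest <- list(seed = run$seed, lhw = run$params$lhw,
                   lps = run$params$lps,
                   record_minutes = run$record_minutes,
                   stab_minutes = run$stab_minutes,
                   n_agents = run$params$n_agents)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
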