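# Model parameters ------------------------------------------------------

#' Model parameters for the emotional-bookkeeping simulator
#'
#' Builds and validates the full parameter set of the model: group size,
#' world geometry, perception distances, all per-minute emotion rates, the
#' instantaneous emotion-event increments, the context-dependent arousal
#' limits, the behavioral base weights used in action selection, scheduling
#' constants, and the two swept parameters `lhw` (the LIKE-history weight,
#' in minutes, equal to the single-interval half-life of LIKE decay) and
#' `lps` (the LIKE partner selectivity in `[0, 1]`).
#'
#' Time units follow the model's calendar: 1 time unit = 1 minute, a day is
#' 12 hours (720 min), a week 7 days, a year 50 weeks (252000 min), and a
#' month is one twelfth of a year (21000 min).
#'
#' Defaults not stated by the underlying model description (event-increment
#' magnitudes, arousal limits per context, behavioral base weights, the
#' sharpening exponent `gamma`, sigmoid slopes `eta`/`eta_counter`) are
#' documented package defaults chosen to honor every stated ordering and
#' sign constraint; see the methods vignette.
#'
#' @param n_agents number of individuals (default 20).
#' @param lhw LIKE-history weight in minutes, `>= 0`. Also the half-life of
#'   LIKE decay over a single spanning update.
#' @param lps LIKE partner selectivity in `[0, 1]`; 0 is the null model in
#'   which LIKE plays no role in partner choice.
#' @param ... overrides for any other parameter listed in Details; unknown
#'   names are an error.
#'
#' @details Overridable parameters (units, default):
#' world_size (m, 300, torus); speed (m/s, 0.6); interact_dist (m, 1);
#' pers_dist (m, 5); near_dist (m, 20); max_dist (m, 50); far_dist (m, 100);
#' min_others (3); view_angle (deg, 120); max_angle (deg, 360);
#' default_arousal (0.09); arousal_rate (/min, 0.02);
#' anxiety_default_decay (/min, 0.002); anxiety_groom_give_decay (/min, 0.01);
#' anxiety_groom_receive_decay (/min, 0.02); sat_receive_inc (/min, 0.1);
#' sat_give_inc (/min, 0.05); sat_default_dec (/min, 0.02);
#' partner_sat_dec (/min, 0.02); eta (4); eta_counter (4); gamma (3);
#' groom_schedule_mean (min, 7.5); groom_schedule_sd (min, 0.375);
#' move_step_seconds (s, 3); react_mean_seconds (s, 0.1);
#' react_sd_seconds (s, 0.005); act_delay_mean (min, 1); act_delay_sd (min,
#' 0.05); stab_multiplier (10); stab_minutes (override of the stabilization
#' formula, NA = use formula); record_minutes (504000);
#' sample_interval (min, 2520); pref_threshold (0.10); event_increments
#' (data.frame kind/arousal/anxiety); arousal_limits (named numeric:
#' being_groomed, grooming, dominant_near, default); base_weights (named
#' numeric over behaviors); motiv_anxiety_coef (1.0); motiv_sat_coef (0.5);
#' aggr_anxiety_coef (1.0); subm_anxiety_coef (1.0); scan_base (0.05);
#' approach_bias_pow (2, exponent of the near-distance approach bias);
#' walk_turn_deg (30); walk_bout_mean (min, 1); walk_bout_sd (min, 0.05);
#' dom_values (numeric length n_agents, default evenly spaced 0.05..1);
#' init_disc_diameter (m, 50); like_policy ("lazy" or "per_activation").
#'
#' @return an object of class `emo_params` (a validated named list).
#' @examples
#' p <- emo_params(lhw = 720, lps = 0.99)
#' p$lhw
#' @export
emo_params <- function(n_agents = 20L, lhw = 720, lps = 0.5, ...) {
  p <- list(
    n_agents = as.integer(n_agents),
    world_size = 300,
    minute = 1,
    day_minutes = 720,
    week_days = 7,
    year_weeks = 50,
    speed = 0.6,
    interact_dist = 1,
    pers_dist = 5,
    near_dist = 20,
    max_dist = 50,
    far_dist = 100,
    min_others = 3L,
    view_angle = 120,
    max_angle = 360,
    default_arousal = 0.09,
    arousal_rate = 0.02,
    anxiety_default_decay = 0.002,
    anxiety_groom_give_decay = 0.01,
    anxiety_groom_receive_decay = 0.02,
    sat_receive_inc = 0.1,
    sat_give_inc = 0.05,
    sat_default_dec = 0.02,
    partner_sat_dec = 0.02,
    lhw = as.numeric(lhw),
    lps = as.numeric(lps),
    eta = 4,
    eta_counter = 4,
    gamma = 3,
    groom_schedule_mean = 7.5,
    groom_schedule_sd = 0.375,
    move_step_seconds = 3,
    react_mean_seconds = 0.1,
    react_sd_seconds = 0.005,
    act_delay_mean = 1,
    act_delay_sd = 0.05,
    stab_multiplier = 10,
    stab_minutes = NA_real_,
    record_minutes = 504000,
    sample_interval = 2520,
    pref_threshold = 0.10,
    event_increments = default_event_increments(),
    arousal_limits = c(being_groomed = 0.0, grooming = 0.04,
                       dominant_near = 0.3, default = 0.09),
    base_weights = default_base_weights(),
    motiv_anxiety_coef = 1.0,
    motiv_sat_coef = 0.5,
    aggr_anxiety_coef = 1.0,
    subm_anxiety_coef = 1.0,
    scan_base = 0.05,
    approach_bias_pow = 2,
    walk_turn_deg = 30,
    walk_bout_mean = 1,
    walk_bout_sd = 0.05,
    dom_values = NULL,
    init_disc_diameter = 50,
    like_policy = "lazy"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (is.null(p$dom_values))
    p$dom_values <- seq(0.05, 1, length.out = p$n_agents)
  # derived calendar quantities
  p$week_minutes <- p$day_minutes * p$week_days
  p$year_minutes <- p$week_minutes * p$year_weeks
  p$month_minutes <- p$year_minutes / 12
  class(p) <- "emo_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(is.numeric(p$n_agents), length(p$n_agents) == 1)
  if (p$n_agents < 1) stop("n_agents must be positive")
  if (!is.numeric(p$lhw) || p$lhw < 0) stop("lhw must be >= 0")
  if (!is.numeric(p$lps) || p$lps < 0 || p$lps > 1)
    stop("lps must lie in [0, 1]")
  rates <- c(p$arousal_rate, p$anxiety_default_decay,
             p$anxiety_groom_give_decay, p$anxiety_groom_receive_decay,
             p$sat_receive_inc, p$sat_give_inc, p$sat_default_dec,
             p$partner_sat_dec)
  if (any(rates < 0)) stop("all emotion rates must be >= 0")
  d <- c(p$interact_dist, p$pers_dist, p$near_dist, p$max_dist)
  if (any(diff(d) < 0) || p$max_dist > p$far_dist)
    stop("distances must be ordered interact <= pers <= near <= max <= far")
  if (p$view_angle > p$max_angle) stop("view_angle must be <= max_angle")
  if (length(p$dom_values) != p$n_agents)
    stop("dom_values must have length n_agents")
  if (any(p$dom_values < 0.05 - 1e-12) || any(p$dom_values > 1 + 1e-12))
    stop("dominance strengths must lie in [0.05, 1]")
  ei <- p$event_increments
  if (!is.data.frame(ei) || !all(c("kind", "arousal", "anxiety") %in% names(ei)))
    stop("event_increments must be a data.frame with kind/arousal/anxiety")
  da <- function(k) ei$arousal[match(k, ei$kind)]
  dx <- function(k) ei$anxiety[match(k, ei$kind)]
  if (!isTRUE(da("receive_attack") > da("observe_fight")))
    stop("event table must give receive_attack a larger arousal increment than observe_fight")
  if (!all(dx(c("win_fight", "receive_submission", "receive_affil_signal")) < 0))
    stop("win_fight, receive_submission and receive_affil_signal must decrease anxiety")
  if (!p$like_policy %in% c("lazy", "per_activation"))
    stop("like_policy must be 'lazy' or 'per_activation'")
  bw <- p$base_weights
  need <- c("groom", "affil_signal", "approach", "attack", "aggr_signal",
            "leave", "subm_signal", "avoid", "rest", "random_walk")
  if (!all(need %in% names(bw)) || any(bw < 0))
    stop("base_weights must name all behaviors and be non-negative")
  invisible(p)
}

#' Instantaneous emotion-event increments
#'
#' The default table of instantaneous arousal/anxiety changes triggered by
#' discrete social events.  Magnitudes are package defaults constrained by
#' the stated orderings: receiving an attack raises arousal more than
#' observing an escalated fight, and winning a fight, receiving submission
#' or receiving an affiliative signal lower anxiety.
#'
#' @return data.frame with columns `kind`, `arousal`, `anxiety`.
#' @export
default_event_increments <- function() {
  data.frame(
    kind = c("receive_attack", "give_attack", "receive_aggr_signal",
             "lose_fight", "win_fight", "observe_fight",
             "receive_submission", "receive_affil_signal"),
    arousal = c(0.4, 0.3, 0.2, 0.0, 0.0, 0.2, -0.05, -0.05),
    anxiety = c(0.3, 0.15, 0.2, 0.3, -0.1, 0.1, -0.1, -0.1),
    stringsAsFactors = FALSE
  )
}

#' Behavioral base weights for action selection
#'
#' Package-default relative weights of the behavior classes entering the
#' action-selection distribution.  Calibrated once so that a
#' default-parameter run yields mean grooming-bout durations inside the
#' 5.7-6.3 min band; see the methods vignette.
#'
#' @return named numeric vector.
#' @export
default_base_weights <- function() {
  c(groom = 0.8, affil_signal = 1.05, approach = 0.6,
    attack = 0.3, aggr_signal = 0.5,
    leave = 0.08, subm_signal = 0.63, avoid = 0.10,
    rest = 2.1, random_walk = 0.1)
}

#' Scaled run presets
#'
#' Named presets fixing the recorded horizon (and, for the scaled tiers, a
#' shortened stabilization period): `"smoke"` records one week,
#' `"desk"` two months, `"full"` the full two years with the
#' LHW-dependent stabilization formula.
#'
#' @param name one of "smoke", "desk", "full".
#' @param ... passed on to [emo_params()].
#' @return an `emo_params` object.
#' @export
preset_params <- function(name = c("desk", "smoke", "full"), ...) {
  name <- match.arg(name)
  base <- emo_params(...)
  switch(name,
    smoke = {
      base$record_minutes <- base$week_minutes      # 5040 min
      base$stab_minutes <- 720                      # one simulated day
    },
    desk = {
      base$record_minutes <- 2 * base$month_minutes # 42000 min
      base$stab_minutes <- 6000                     # the 100-hour minimum
    },
    full = {
      base$record_minutes <- 2 * base$year_minutes  # 504000 min
      base$stab_minutes <- NA_real_
    })
  base
}

#' @export
print.emo_params <- function(x, ...) {
  cat("<emo_params>\n")
  cat(sprintf("  agents: %d on a %g m torus\n", x$n_agents, x$world_size))
  cat(sprintf("  LHW: %g min (half-life of LIKE decay), LPS: %g\n",
              x$lhw, x$lps))
  cat(sprintf("  recorded horizon: %g min (%.2f months), sample every %g min\n",
              x$record_minutes, x$record_minutes / x$month_minutes,
              x$sample_interval))
  stab <- if (is.na(x$stab_minutes))
    sprintf("max(6000, %g * LHW) = %g", x$stab_multiplier,
            stabilization_duration(x$lhw, x))
  else sprintf("%g (fixed)", x$stab_minutes)
  cat("  stabilization:", stab, "min\n")
  invisible(x)
}

# Read/write parameter configs as flat YAML ------------------------------

#' Read model parameters from a YAML config file
#'
#' The file holds a flat mapping mirroring the parameter names of
#' [emo_params()]; `event_increments` may be given as a list of
#' kind/arousal/anxiety records.  Keys absent from the file keep their
#' defaults; `overrides` (e.g. parsed CLI flags) take precedence over the
#' file.
#'
#' @param path YAML file path.
#' @param overrides named list applied after the file.
#' @return an `emo_params` object.
#' @export
read_params_yaml <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$event_increments) && !is.data.frame(cfg$event_increments))
    cfg$event_increments <- do.call(rbind, lapply(cfg$event_increments,
                                                  as.data.frame))
  for (nm in c("arousal_limits", "base_weights"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg[names(overrides)] <- overrides
  args <- cfg[setdiff(names(cfg), c("n_agents", "lhw", "lps"))]
  do.call(emo_params, c(list(
    n_agents = cfg$n_agents %||% 20L,
    lhw = cfg$lhw %||% 720,
    lps = cfg$lps %||% 0.5), args))
}

#' Write model parameters to a YAML config file
#'
#' @param params an `emo_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  p <- unclass(params)
  ei <- p$event_increments
  p$event_increments <- lapply(seq_len(nrow(ei)), function(k)
    list(kind = ei$kind[k], arousal = ei$arousal[k], anxiety = ei$anxiety[k]))
  p$arousal_limits <- as.list(p$arousal_limits)
  p$base_weights <- as.list(p$base_weights)
  p$week_minutes <- p$year_minutes <- p$month_minutes <- NULL
  yaml::write_yaml(p, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
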