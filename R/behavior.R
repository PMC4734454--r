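# Behavior engine: perception, grouping, action selection, movement -----

#' Perceive candidate interaction partners
#'
#' The up-to-10 nearest individually recognizable group members: those
#' within the maximum perceivable distance (50 m) and within the agent's
#' current view angle; anyone within interaction distance (1 m) is
#' perceived regardless of angle.  Candidates are sorted by distance.
#'
#' @param ego agent index.
#' @param x,y position vectors of all agents (torus coordinates).
#' @param heading ego's heading in degrees (counter-clockwise from +x).
#' @param view ego's current view angle in degrees (120, or 360 when
#'   scanning).
#' @param params an [emo_params()] object.
#' @return data.frame with columns `id`, `dist`, `bearing`, at most 10
#'   rows, ordered by distance.
#' @export
perceive_candidates <- function(ego, x, y, heading, view, params) {
  w <- params$world_size
  dx <- wrap_delta(x - x[ego], w)
  dy <- wrap_delta(y - y[ego], w)
  d <- sqrt(dx * dx + dy * dy)
  d[ego] <- Inf
  bearing <- (atan2(dy, dx) * 180 / pi) %% 360
  in_view <- angle_offset(bearing, heading) <= view / 2
  ok <- (d <= params$interact_dist) |
        (d <= params$max_dist & in_view)
  ids <- which(ok)
  if (length(ids) > 1) ids <- ids[order(d[ids], ids)]
  if (length(ids) > 10) ids <- ids[seq_len(10)]
  data.frame(id = ids, dist = d[ids], bearing = bearing[ids])
}

#' Grouping criterion
#'
#' Grouping (approaching a random group member) is required when fewer
#' than `min_others` (3) group members are within `near_dist` (20 m,
#' judged over the full 360 degrees), or when any group member is farther
#' away than `far_dist` (100 m).
#'
#' @inheritParams perceive_candidates
#' @return logical: should ego perform grouping?
#' @export
check_grouping <- function(ego, x, y, params) {
  w <- params$world_size
  dx <- wrap_delta(x - x[ego], w)
  dy <- wrap_delta(y - y[ego], w)
  d2 <- dx * dx + dy * dy
  d2[ego] <- NA
  near <- sum(d2 <= params$near_dist^2, na.rm = TRUE)
  near < params$min_others || any(d2 > params$far_dist^2, na.rm = TRUE)
}

# behavior codes used internally and in event logs
BEHAVIORS <- c("groom", "affil_signal", "approach",
               "attack", "aggr_signal",
               "leave", "subm_signal", "avoid",
               "rest", "random_walk")

# Internal fast weight computation shared by the simulator and the
# exported action_distribution().  `like` may be NULL when lps == 0 (the
# null model must never read LIKE values).  `groom_ok` flags candidates
# not currently being groomed by a third party.
action_weights <- function(dist, fear, like, arousal, anxiety, satisfaction,
                           params, groom_ok = NULL, like_ref = NULL) {
  bw <- params$base_weights
  k <- length(dist)
  m_act <- 0.1 + 0.9 * arousal
  if (k) {
    m_aff <- (1 + params$motiv_anxiety_coef * anxiety) *
             (1 - params$motiv_sat_coef * satisfaction)
    # selectivity: each partner's affiliation weight is scaled by its LIKE
    # mixture relative to the best available mixture, sharpened by gamma --
    # at LPS = 0 the factor is identically 1 and LIKE is never consulted
    mix <- if (params$lps > 0) {
      m <- (1 - params$lps) + params$lps * like
      ref <- (1 - params$lps) + params$lps *
        max(if (is.null(like_ref)) like else like_ref, 0)
      (m / ref)^params$gamma
    } else 1
    g1  <- dist <= params$interact_dist
    g5  <- dist <= params$pers_dist
    g50 <- dist <= params$max_dist & dist > params$interact_dist
    if (is.null(groom_ok)) groom_ok <- rep(TRUE, k)
    aggf <- stats::plogis(-params$eta * fear) *
            pmax(0, 1 - params$aggr_anxiety_coef * anxiety)
    subf <- stats::plogis(params$eta * fear) *
            (1 + params$subm_anxiety_coef * anxiety)
    aff <- m_act * m_aff * mix
    # approaches favor nearby partners (spatial assortment)
    near_bias <- pmax(0, 1 - dist / params$max_dist)^params$approach_bias_pow
    w <- c(bw[["groom"]]        * aff * (g1 & groom_ok),
           bw[["affil_signal"]] * aff * g5,
           bw[["approach"]]     * aff * near_bias * g50,
           bw[["attack"]]       * m_act * aggf * g1,
           bw[["aggr_signal"]]  * m_act * aggf * g5,
           bw[["leave"]]        * m_act * subf * g1,
           bw[["subm_signal"]]  * m_act * subf * g5,
           bw[["avoid"]]        * m_act * subf * g5)
    beh <- rep(1:8, each = k)
    tgt <- rep.int(seq_len(k), 8)
    keep <- w > 0
    w <- c(w[keep], bw[["rest"]] * (1 - 0.9 * arousal),
           bw[["random_walk"]] * m_act)
    beh <- c(beh[keep], 9L, 10L)
    tgt <- c(tgt[keep], 0L, 0L)
  } else {
    w <- c(bw[["rest"]] * (1 - 0.9 * arousal), bw[["random_walk"]] * m_act)
    beh <- c(9L, 10L)
    tgt <- c(0L, 0L)
  }
  list(beh = beh, tgt = tgt, w = w)
}

#' Action-selection distribution
#'
#' The probability distribution over behavior-partner combinations from
#' which an activated agent samples.  Affiliative weights (groom,
#' affiliative signal, approach) scale with an affiliation motivation
#' that increases with anxiety and decreases with satisfaction, and with
#' the selectivity mixture `((1 - lps) + lps * LIKE)^gamma`; aggression
#' weights decrease with the FEAR attitude and with anxiety; submissive
#' weights increase with FEAR and anxiety.  Distance gates restrict
#' grooming/attacking/leaving to 1 m, signalling/avoiding to 5 m and
#' approaching to 50 m.  Resting competes with all active behaviors; the
#' probability of being active increases with arousal.  At `lps = 0` the
#' distribution is invariant to every LIKE value.
#'
#' @param cands data.frame from [perceive_candidates()].
#' @param fear ego's FEAR attitudes toward the candidates (same order).
#' @param like ego's LIKE attitudes toward the candidates, or `NULL` when
#'   `params$lps == 0`.
#' @param arousal,anxiety,satisfaction ego's current emotional state.
#' @param params an [emo_params()] object.
#' @param groom_ok logical per candidate: free to be groomed by ego
#'   (default all `TRUE`).
#' @param like_ref ego's highest current LIKE attitude (over all
#'   partners), the reference for the relative selectivity factor;
#'   defaults to the maximum of `like`.
#' @return data.frame with `behavior`, `target` (agent id, `NA` for rest
#'   and random walk) and `prob`; probabilities sum to 1.
#' @export
action_distribution <- function(cands, fear, like, arousal, anxiety,
                                satisfaction, params, groom_ok = NULL,
                                like_ref = NULL) {
  if (params$lps == 0) like <- NULL
  aw <- action_weights(cands$dist, fear, like, arousal, anxiety,
                       satisfaction, params, groom_ok, like_ref)
  tot <- sum(aw$w)
  data.frame(
    behavior = BEHAVIORS[aw$beh],
    target = ifelse(aw$tgt > 0, cands$id[aw$tgt], NA_integer_),
    prob = aw$w / tot
  )
}

#' Escalated-fight win probability
#'
#' Probability that `i` beats `j` in an escalated fight:
#' `1 / (1 + exp(-eta * (dom_i - dom_j)))`.  Antisymmetric:
#' `fight_win_prob(a, b) + fight_win_prob(b, a) == 1`.
#'
#' @param dom_i,dom_j dominance strengths.
#' @param eta slope of the sigmoid (default 4).
#' @return win probability in `(0, 1)`.
#' @export
fight_win_prob <- function(dom_i, dom_j, eta = 4) {
  stats::plogis(eta * (dom_i - dom_j))
}

#' Counter-attack probability
#'
#' Probability that an attacked individual counter-attacks rather than
#' flees: logistic in the victim-minus-attacker dominance difference, so
#' an attack from a lower-ranking individual (positive difference) makes a
#' counter-attack more likely, and it is exactly 0.5 at equal rank.
#'
#' @param dom_victim,dom_attacker dominance strengths.
#' @param eta_counter slope (default 4).
#' @return probability in `(0, 1)`.
#' @export
counter_attack_prob <- function(dom_victim, dom_attacker, eta_counter = 4) {
  stats::plogis(eta_counter * (dom_victim - dom_attacker))
}

#' Scanning probability
#'
#' Probability that a resting agent scans (expanding its view angle to 360
#' degrees); strictly increasing in arousal.
#'
#' @param arousal current arousal level.
#' @param scan_base baseline probability at zero arousal.
#' @return probability in `[0, 1]`.
#' @export
scan_probability <- function(arousal, scan_base = 0.05) {
  scan_base + (1 - scan_base) * arousal
}

#' Execute one movement step
#'
#' Moves a position at the constant movement speed (0.6 m/s) for
#' `dt_seconds`, either toward (`approach`, `grouping`) or away from
#' (`avoid`, `leave`, `flee`) a target position, or along `heading` for a
#' `random_walk`.  Positions wrap on the torus.
#'
#' @param pos `c(x, y)` current position.
#' @param target_pos `c(x, y)` of the reference individual (ignored for
#'   random walks).
#' @param kind one of "approach", "grouping", "avoid", "leave", "flee",
#'   "random_walk".
#' @param dt_seconds step duration in seconds.
#' @param params an [emo_params()] object.
#' @param heading current heading in degrees (used for random walks).
#' @return list with the new `pos` and `heading`.
#' @export
execute_movement <- function(pos, target_pos, kind, dt_seconds, params,
                             heading = 0) {
  step <- params$speed * dt_seconds
  w <- params$world_size
  h <- switch(kind,
    approach = ,
    grouping = torus_bearing(pos[1], pos[2], target_pos[1], target_pos[2], w),
    avoid = ,
    leave = ,
    flee = (torus_bearing(pos[1], pos[2], target_pos[1], target_pos[2], w) +
            180) %% 360,
    random_walk = heading,
    stop("unknown movement kind: ", kind))
  rad <- h * pi / 180
  list(pos = c(wrap_pos(pos[1] + step * cos(rad), w),
               wrap_pos(pos[2] + step * sin(rad), w)),
       heading = h)
}
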