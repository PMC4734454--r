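# Emotion dynamics: continuous relaxation, event increments, LIKE -------

#' Context-dependent arousal limit
#'
#' The arousal level an agent drifts toward given its lasting social
#' context.  Being groomed takes precedence over grooming, which takes
#' precedence over having a dominant individual within personal distance.
#'
#' @param receiving,giving logical (or partner id != 0): grooming contexts.
#' @param dominant_near logical: a higher-ranking individual within 5 m.
#' @param limits named numeric as in `emo_params()$arousal_limits`.
#' @return the target arousal level.
#' @export
ctx_arousal_limit <- function(receiving, giving, dominant_near, limits) {
  if (isTRUE(as.logical(receiving))) limits[["being_groomed"]]
  else if (isTRUE(as.logical(giving))) limits[["grooming"]]
  else if (isTRUE(as.logical(dominant_near))) limits[["dominant_near"]]
  else limits[["default"]]
}

# linear, rate-limited approach of `x` toward `target`, never overshooting
approach_limit <- function(x, target, rate, dt) {
  step <- rate * dt
  x + sign(target - x) * pmin(abs(target - x), step)
}

#' Relax an agent's emotional state over a time interval
#'
#' Applies the continuous-time dynamics over `dt` minutes: arousal moves
#' linearly (0.02/min) toward the context-dependent limit; anxiety decays
#' toward 0 at 0.01/min while giving grooming, 0.02/min while receiving,
#' 0.002/min otherwise; satisfaction rises at 0.1/min (receiving) or
#' 0.05/min (giving) toward 1, else falls at 0.02/min toward 0; each
#' partner-specific satisfaction rises at 0.1/min toward 1 only for the
#' partner currently grooming the agent, and falls at 0.02/min toward 0
#' for everyone else.  All levels stay in `[0, 1]`.
#'
#' @param state list with numeric `arousal`, `anxiety`, `satisfaction` and
#'   (optionally) a numeric vector `partner_sat`.
#' @param dt interval in minutes, `>= 0`.
#' @param ctx list with `receiving_from` (partner index or 0),
#'   `giving_to` (partner index or 0) and `dominant_near` (logical).
#' @param params an [emo_params()] object.
#' @return the updated `state` list.
#' @export
relax_emotions <- function(state, dt, ctx, params) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(state)
  recv <- !is.null(ctx$receiving_from) && ctx$receiving_from > 0
  give <- !is.null(ctx$giving_to) && ctx$giving_to > 0
  lim <- ctx_arousal_limit(recv, give, isTRUE(ctx$dominant_near),
                           params$arousal_limits)
  state$arousal <- clip01(approach_limit(state$arousal, lim,
                                         params$arousal_rate, dt))
  xrate <- if (recv) params$anxiety_groom_receive_decay
           else if (give) params$anxiety_groom_give_decay
           else params$anxiety_default_decay
  state$anxiety <- clip01(approach_limit(state$anxiety, 0, xrate, dt))
  state$satisfaction <- clip01(
    if (recv) approach_limit(state$satisfaction, 1, params$sat_receive_inc, dt)
    else if (give) approach_limit(state$satisfaction, 1, params$sat_give_inc, dt)
    else approach_limit(state$satisfaction, 0, params$sat_default_dec, dt))
  if (!is.null(state$partner_sat)) {
    ps <- approach_limit(state$partner_sat, 0, params$partner_sat_dec, dt)
    if (recv) {
      j <- ctx$receiving_from
      ps[j] <- approach_limit(state$partner_sat[j], 1,
                              params$sat_receive_inc, dt)
    }
    state$partner_sat <- clip01(ps)
  }
  state
}

#' Apply an instantaneous emotion event
#'
#' Adds the configured arousal/anxiety increments for a discrete social
#' event (receiving an attack, observing an escalated fight, ...), clipping
#' both levels to `[0, 1]`.
#'
#' @param state list with `arousal` and `anxiety`.
#' @param kind event kind; must appear in `params$event_increments$kind`.
#' @param params an [emo_params()] object.
#' @return the updated `state`.
#' @export
apply_event <- function(state, kind, params) {
  ei <- params$event_increments
  k <- match(kind, ei$kind)
  if (is.na(k)) stop("unknown emotion event kind: ", kind)
  state$arousal <- clip01(state$arousal + ei$arousal[k])
  state$anxiety <- clip01(state$anxiety + ei$anxiety[k])
  state
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' LIKE attitude update
#'
#' The central emotional-bookkeeping update.  The new LIKE value combines
#' the previous LIKE (weighted by the LIKE-history weight `lhw`, in
#' minutes) with the current partner-specific satisfaction (weighted by
#' the elapsed time `dt`), and is floored at the current partner
#' satisfaction:
#'
#' \deqn{LIKE(t_n) = \max\left\{\frac{lhw \cdot LIKE(t_{n-1}) + dt \cdot
#'   PSAT(t_n)}{lhw + dt},\; PSAT(t_n)\right\}}
#'
#' With `partner_sat_now = 0`, `lhw` is the half-life of LIKE over a
#' single spanning update: `update_like(1, 0, lhw, lhw) == 0.5`.  With
#' `lhw = 0`, LIKE simply equals the current partner satisfaction.
#' Vectorized over all arguments.
#'
#' @param like_prev previous LIKE value(s) in `[0, 1]`.
#' @param partner_sat_now current partner-specific satisfaction in `[0, 1]`.
#' @param dt minutes since the previous update, `> 0`.
#' @param lhw LIKE-history weight in minutes, `>= 0`.
#' @return updated LIKE value(s) in `[0, 1]`, always
#'   `>= partner_sat_now`.
#' @examples
#' update_like(1.0, 0, 180, 180)  # 0.5: lhw is the half-life
#' @export
update_like <- function(like_prev, partner_sat_now, dt, lhw) {
  if (any(dt <= 0)) stop("dt must be > 0")
  if (any(lhw < 0)) stop("lhw must be >= 0")
  pmax((lhw * like_prev + dt * partner_sat_now) / (lhw + dt),
       partner_sat_now)
}

#' Apply a grooming interval to both partners
#'
#' Convenience wrapper advancing actor and receiver state over `dt`
#' minutes of ongoing grooming (actor grooms receiver): the receiver's
#' satisfaction and partner-specific satisfaction toward the actor rise
#' at 0.1/min, its anxiety falls at 0.02/min and its LIKE toward the
#' actor is updated; the actor's satisfaction rises at 0.05/min and its
#' anxiety falls at 0.01/min.
#'
#' @param actor,receiver state lists as in [relax_emotions()]; the
#'   receiver's `partner_sat` and `like` are vectors indexed by partner.
#' @param actor_id index of the actor in the receiver's partner vectors.
#' @param dt grooming minutes, `> 0`.
#' @param params an [emo_params()] object.
#' @return list with updated `actor` and `receiver`.
#' @export
groom_tick <- function(actor, receiver, actor_id, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  actor <- relax_emotions(actor, dt, list(giving_to = 1), params)
  receiver <- relax_emotions(receiver, dt, list(receiving_from = actor_id),
                             params)
  if (!is.null(receiver$like))
    receiver$like[actor_id] <- update_like(receiver$like[actor_id],
                                           receiver$partner_sat[actor_id],
                                           dt, params$lhw)
  list(actor = actor, receiver = receiver)
}

# internal variant tolerating dt == 0 (returns the floor-respecting value)
like_step <- function(like_prev, ps_now, dt, lhw) {
  num <- lhw * like_prev + dt * ps_now
  den <- lhw + dt
  out <- ifelse(den > 0, num / den, ps_now)
  pmax(out, ps_now)
}
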