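# Continuous-time scheduling primitives ----------------------------------

#' Stabilization period before recording starts
#'
#' Higher LIKE-history weights slow the LIKE dynamics and need longer
#' burn-in; the stabilization period is
#' `max(6000, stab_multiplier * lhw)` minutes, i.e. never shorter than
#' 100 simulated hours.  A finite `params$stab_minutes` overrides the
#' formula (used by the scaled presets).
#'
#' @param lhw LIKE-history weight in minutes, `>= 0`.
#' @param params an [emo_params()] object.
#' @return the stabilization duration in minutes.
#' @examples
#' stabilization_duration(21600, emo_params())  # 216000
#' @export
stabilization_duration <- function(lhw, params) {
  stopifnot(lhw >= 0)
  if (!is.na(params$stab_minutes)) return(params$stab_minutes)
  max(100 * 60, params$stab_multiplier * lhw)
}

#' Next scheduled agent
#'
#' Returns the queue entry with the lowest activation time; ties are broken
#' by the lowest agent id, so runs are reproducible.
#'
#' @param times numeric vector of next activation times, indexed by agent.
#' @return list with `agent_id` and `time`.
#' @export
pop_next <- function(times) {
  if (length(times) == 0 || all(!is.finite(times)))
    stop("empty schedule: halt")
  i <- which.min(times)  # which.min returns the first (lowest id) on ties
  list(agent_id = i, time = times[[i]])
}

# truncated-normal delay: resample while <= 0
rtrunc_norm <- function(mean, sd) {
  repeat {
    d <- stats::rnorm(1, mean, sd)
    if (d > 0) return(d)
  }
}

#' Reschedule delay after a behavior
#'
#' Draws the time (minutes) until the next self-activation of an agent
#' that just performed `behavior`: a grooming or resting bout start is
#' followed up after Normal(7.5, 0.375) min; a movement continuation after
#' one 3-s step; a reaction to a received signal or an observed fight after
#' Normal(0.1, 0.005) s; a discrete social act after Normal(1, 0.05) min.
#' All draws are truncated at `> 0`.
#'
#' @param behavior one of "groom", "rest", "move", "react", "act".
#' @param params an [emo_params()] object.
#' @return delay in minutes.
#' @export
reschedule_delay <- function(behavior, params) {
  switch(behavior,
    groom = ,
    rest = rtrunc_norm(params$groom_schedule_mean, params$groom_schedule_sd),
    move = params$move_step_seconds / 60,
    react = rtrunc_norm(params$react_mean_seconds / 60,
                        params$react_sd_seconds / 60),
    act = rtrunc_norm(params$act_delay_mean, params$act_delay_sd),
    stop("unknown behavior kind: ", behavior))
}
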