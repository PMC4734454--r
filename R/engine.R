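# Event-driven simulation engine ----------------------------------------

# Movement kind codes
MV_APPROACH <- 1L; MV_AVOID <- 2L; MV_LEAVE <- 3L; MV_FLEE <- 4L
MV_GROUPING <- 5L; MV_WALK <- 6L

#' Run one simulation
#'
#' Executes the event-driven main loop: the agent with the lowest
#' scheduled time is activated; time-dependent state (arousal, anxiety,
#' satisfaction, partner-specific satisfaction, LIKE attitudes) is brought
#' up to date lazily; the agent executes a pending movement step, or
#' checks the grouping criterion, or selects and performs an action; all
#' affected agents are rescheduled.  The run comprises a stabilization
#' period (see [stabilization_duration()]) followed by `record_minutes` of
#' recorded time, during which dyadic LIKE attitudes are sampled every
#' `sample_interval` minutes and dyadic grooming minutes are accumulated
#' per sampling interval and per month.
#'
#' All randomness flows through R's global RNG, seeded once from `seed`:
#' two runs with identical parameters and seed are bit-identical.
#'
#' @param params an [emo_params()] object.
#' @param seed integer seed.
#' @param record_minutes recorded horizon (minutes); defaults to
#'   `params$record_minutes`.
#' @param log_events if `TRUE`, keep the full behavior-event log (time,
#'   actor, behavior, target) in the result.
#' @return an object of class `emo_run`; see [summary.emo_run()].
#' @export
emo_run <- function(params, seed, record_minutes = params$record_minutes,
                    log_events = FALSE) {
  stopifnot(inherits(params, "emo_params"))
  set.seed(as.integer(seed))
  n <- params$n_agents
  W <- params$world_size
  lhw <- params$lhw
  lps <- params$lps
  lazy_like <- identical(params$like_policy, "lazy")
  lim <- params$arousal_limits
  bw <- params$base_weights
  ei <- params$event_increments
  ev_idx <- stats::setNames(seq_len(nrow(ei)), ei$kind)
  ev_da <- ei$arousal
  ev_dx <- ei$anxiety
  interact2 <- params$interact_dist^2
  pers2 <- params$pers_dist^2
  near2 <- params$near_dist^2
  max2 <- params$max_dist^2
  far2 <- params$far_dist^2
  step_min <- params$move_step_seconds / 60
  step_m <- params$speed * params$move_step_seconds

  pop <- init_population(params)
  dom <- pop$dom
  x <- pop$x; y <- pop$y
  heading <- pop$heading; view <- pop$view
  arousal <- pop$arousal; anxiety <- pop$anxiety
  satisfaction <- pop$satisfaction
  ps <- pop$partner_sat; like <- pop$like
  fear <- pop$fear
  next_time <- pop$my_time
  last_upd <- rep(0, n)
  like_upd <- matrix(0, n, n)
  activity <- integer(n)            # 0 idle/rest, 1 moving, 2 grooming
  move_kind <- integer(n); move_target <- integer(n)
  move_end_plan <- rep(Inf, n)
  give_to <- integer(n); recv_from <- integer(n)
  bout_t0 <- rep(NA_real_, n)
  dominant_near <- logical(n)
  arousal_limit <- rep(lim[["default"]], n)

  stab <- stabilization_duration(lhw, params)
  t_end <- stab + record_minutes
  n_samp <- floor(record_minutes / params$sample_interval)
  sample_times <- if (n_samp > 0) stab + params$sample_interval * seq_len(n_samp) else numeric(0)
  n_mon <- floor(record_minutes / params$month_minutes)
  like_samples <- array(NA_real_, c(n, n, n_samp))
  gm_int <- array(0, c(n, n, max(n_samp, 1L)))
  gm_mon <- array(0, c(n, n, max(n_mon, 1L)))
  snap_times <- stab + params$year_minutes * c(1, 2)
  snap_times <- snap_times[snap_times <= t_end + 1e-9]
  snapshots <- vector("list", length(snap_times))
  samp_idx <- 1L; snap_idx <- 1L

  # bout log (grown by doubling)
  bcap <- 4096L; bn <- 0L
  b_actor <- integer(bcap); b_recv <- integer(bcap)
  b_t0 <- numeric(bcap); b_dur <- numeric(bcap)
  # event log
  ecap <- if (log_events) 8192L else 0L; en <- 0L
  e_time <- numeric(ecap); e_actor <- integer(ecap)
  e_beh <- integer(ecap); e_tgt <- integer(ecap)

  n_activations <- 0; n_like_reads <- 0; n_attacks <- 0; n_fights <- 0
  n_signals <- 0
  now <- 0

  log_event <- function(actor, beh, tgt) {
    if (!log_events) return(invisible())
    if (en == ecap) {
      ecap <<- ecap * 2L
      length(e_time) <<- ecap; length(e_actor) <<- ecap
      length(e_beh) <<- ecap; length(e_tgt) <<- ecap
    }
    en <<- en + 1L
    e_time[en] <<- now; e_actor[en] <<- actor
    e_beh[en] <<- beh; e_tgt[en] <<- tgt
    invisible()
  }

  relax_agent <- function(i, t) {
    dt <- t - last_upd[i]
    if (dt <= 0) return(invisible())
    rj <- recv_from[i]; gj <- give_to[i]
    arousal[i] <<- clip01(approach_limit(arousal[i], arousal_limit[i],
                                         params$arousal_rate, dt))
    xrate <- if (rj > 0) params$anxiety_groom_receive_decay
             else if (gj > 0) params$anxiety_groom_give_decay
             else params$anxiety_default_decay
    anxiety[i] <<- clip01(approach_limit(anxiety[i], 0, xrate, dt))
    satisfaction[i] <<- clip01(
      if (rj > 0) approach_limit(satisfaction[i], 1, params$sat_receive_inc, dt)
      else if (gj > 0) approach_limit(satisfaction[i], 1, params$sat_give_inc, dt)
      else approach_limit(satisfaction[i], 0, params$sat_default_dec, dt))
    row <- pmax(0, ps[i, ] - params$partner_sat_dec * dt)
    if (rj > 0) row[rj] <- min(1, ps[i, rj] + params$sat_receive_inc * dt)
    ps[i, ] <<- row
    last_upd[i] <<- t
    if (lazy_like) {
      if (rj > 0) {  # keep the running max for the active dyad
        like[i, rj] <<- like_step(like[i, rj], row[rj], t - like_upd[i, rj], lhw)
        like_upd[i, rj] <<- t
      }
    } else {        # per-activation policy: rebase the whole row
      like[i, ] <<- like_step(like[i, ], row, t - like_upd[i, ], lhw)
      like_upd[i, ] <<- t
      like[i, i] <<- 0
    }
    invisible()
  }

  like_view <- function(i, js, t) {
    like_step(like[i, js], ps[i, js], t - like_upd[i, js], lhw)
  }

  refresh_limit <- function(i) {
    arousal_limit[i] <<- if (recv_from[i] > 0) lim[["being_groomed"]]
      else if (give_to[i] > 0) lim[["grooming"]]
      else if (dominant_near[i]) lim[["dominant_near"]]
      else lim[["default"]]
    invisible()
  }

  apply_inc <- function(i, kind) {
    k <- ev_idx[[kind]]
    arousal[i] <<- min(1, max(0, arousal[i] + ev_da[k]))
    anxiety[i] <<- min(1, max(0, anxiety[i] + ev_dx[k]))
    invisible()
  }

  # accumulate grooming minutes g -> r over [a, b], clipped to the
  # recording window and split across interval/month bins
  accrue <- function(g, r, a, b) {
    a <- max(a, stab); b <- min(b, t_end)
    if (b <= a) return(invisible())
    if (n_samp > 0) {
      wdt <- params$sample_interval
      i0 <- min(floor((a - stab) / wdt), n_samp - 1)
      i1 <- min(floor((b - stab - 1e-9) / wdt), n_samp - 1)
      for (k in i0:i1) {
        lo <- stab + k * wdt; hi <- lo + wdt
        gm_int[g, r, k + 1L] <<- gm_int[g, r, k + 1L] +
          max(0, min(b, hi) - max(a, lo))
      }
    }
    if (n_mon > 0) {
      wdt <- params$month_minutes
      i0 <- min(floor((a - stab) / wdt), n_mon - 1)
      i1 <- min(floor((b - stab - 1e-9) / wdt), n_mon - 1)
      for (k in i0:i1) {
        lo <- stab + k * wdt; hi <- lo + wdt
        gm_mon[g, r, k + 1L] <<- gm_mon[g, r, k + 1L] +
          max(0, min(b, hi) - max(a, lo))
      }
    }
    invisible()
  }

  end_groom <- function(g, t) {
    r <- give_to[g]
    if (r == 0) return(invisible())
    relax_agent(g, t); relax_agent(r, t)
    # commit the receiver's LIKE toward the groomer at the bout end
    like[r, g] <<- like_step(like[r, g], ps[r, g], t - like_upd[r, g], lhw)
    like_upd[r, g] <<- t
    accrue(g, r, bout_t0[g], t)
    if (t > stab) {
      if (bn == bcap) {
        bcap <<- bcap * 2L
        length(b_actor) <<- bcap; length(b_recv) <<- bcap
        length(b_t0) <<- bcap; length(b_dur) <<- bcap
      }
      bn <<- bn + 1L
      b_actor[bn] <<- g; b_recv[bn] <<- r
      b_t0[bn] <<- bout_t0[g]; b_dur[bn] <<- t - bout_t0[g]
    }
    give_to[g] <<- 0L; recv_from[r] <<- 0L
    if (activity[g] == 2L) activity[g] <<- 0L
    bout_t0[g] <<- NA_real_
    refresh_limit(g); refresh_limit(r)
    invisible()
  }

  # break the bout in which i is the receiver (i is about to move/fight)
  break_received <- function(i, t) {
    if (recv_from[i] > 0) end_groom(recv_from[i], t)
    invisible()
  }

  start_groom <- function(i, j) {
    relax_agent(j, now)
    # rebase the receiver's LIKE toward i before partner satisfaction rises
    like[j, i] <<- like_step(like[j, i], ps[j, i], now - like_upd[j, i], lhw)
    like_upd[j, i] <<- now
    give_to[i] <<- j; recv_from[j] <<- i
    bout_t0[i] <<- now
    activity[i] <<- 2L
    view[i] <<- params$view_angle; view[j] <<- params$view_angle
    refresh_limit(i); refresh_limit(j)
    log_event(i, 1L, j)
    next_time[i] <<- now + rtrunc_norm(params$groom_schedule_mean,
                                       params$groom_schedule_sd)
    invisible()
  }

  start_move <- function(i, kind, target) {
    break_received(i, now)
    activity[i] <<- 1L
    move_kind[i] <<- kind; move_target[i] <<- target
    view[i] <<- params$view_angle
    if (kind == MV_WALK) {
      move_end_plan[i] <<- now + rtrunc_norm(params$walk_bout_mean,
                                             params$walk_bout_sd)
    } else {
      # travel-time budget: targets move too, so a pursuit at equal speeds
      # need not close -- give up after the straight-line travel time plus
      # a two-minute slack rather than chase forever
      dxv <- wrap_delta(x[target] - x[i], W)
      dyv <- wrap_delta(y[target] - y[i], W)
      d0 <- sqrt(dxv * dxv + dyv * dyv)
      move_end_plan[i] <<- now + d0 / (params$speed * 60) + 2
    }
    log_event(i, if (kind == MV_WALK) 10L else 10L + kind, target)
    next_time[i] <<- now + step_min
    invisible()
  }

  proximity_update <- function(i) {
    dxv <- wrap_delta(x - x[i], W); dyv <- wrap_delta(y - y[i], W)
    d2 <- dxv * dxv + dyv * dyv; d2[i] <- Inf
    nearby <- which(d2 <= pers2)
    relax_agent(i, now)
    dominant_near[i] <<- any(dom[nearby] > dom[i])
    refresh_limit(i)
    for (k in nearby[dom[nearby] < dom[i]]) {
      dk <- wrap_delta(x - x[k], W); dk2 <- dk * dk
      dyk <- wrap_delta(y - y[k], W); dk2 <- dk2 + dyk * dyk
      dk2[k] <- Inf
      relax_agent(k, now)
      dominant_near[k] <<- any(dk2 <= pers2 & dom > dom[k])
      refresh_limit(k)
    }
    invisible()
  }

  end_move <- function(i) {
    activity[i] <<- 0L
    move_kind[i] <<- 0L; move_target[i] <<- 0L
    move_end_plan[i] <<- Inf
    proximity_update(i)
    next_time[i] <<- now + rtrunc_norm(params$act_delay_mean,
                                       params$act_delay_sd)
    invisible()
  }

  movement_step <- function(i) {
    k <- move_kind[i]
    if (k == MV_WALK) {
      heading[i] <<- (heading[i] +
        stats::runif(1, -params$walk_turn_deg, params$walk_turn_deg)) %% 360
      rad <- heading[i] * pi / 180
      x[i] <<- wrap_pos(x[i] + step_m * cos(rad), W)
      y[i] <<- wrap_pos(y[i] + step_m * sin(rad), W)
      if (now >= move_end_plan[i]) end_move(i)
      else next_time[i] <<- now + step_min
      return(invisible())
    }
    tg <- move_target[i]
    dxv <- wrap_delta(x[tg] - x[i], W); dyv <- wrap_delta(y[tg] - y[i], W)
    d <- sqrt(dxv * dxv + dyv * dyv)
    toward <- k == MV_APPROACH || k == MV_GROUPING
    if (toward) {
      adv <- min(step_m, max(d - params$interact_dist / 2, 0))
    } else adv <- step_m
    h <- (atan2(dyv, dxv) * 180 / pi) %% 360
    if (!toward) h <- (h + 180) %% 360
    heading[i] <<- h
    rad <- h * pi / 180
    x[i] <<- wrap_pos(x[i] + adv * cos(rad), W)
    y[i] <<- wrap_pos(y[i] + adv * sin(rad), W)
    d <- d - if (toward) adv else -adv
    done <- if (k == MV_APPROACH)
      d <= params$interact_dist || d > params$max_dist
    else if (k == MV_GROUPING)
      d <= params$interact_dist || !check_grouping(i, x, y, params)
    else d > params$pers_dist
    if (done || now >= move_end_plan[i]) end_move(i)
    else next_time[i] <<- now + step_min
    invisible()
  }

  do_attack <- function(a, v) {
    n_attacks <<- n_attacks + 1
    log_event(a, 4L, v)
    relax_agent(v, now)
    if (give_to[v] > 0) end_groom(v, now)
    break_received(v, now)
    break_received(a, now)
    apply_inc(v, "receive_attack"); apply_inc(a, "give_attack")
    view[a] <<- params$view_angle; view[v] <<- params$view_angle
    if (stats::runif(1) < counter_attack_prob(dom[v], dom[a],
                                              params$eta_counter)) {
      n_fights <<- n_fights + 1
      win_a <- stats::runif(1) < fight_win_prob(dom[a], dom[v], params$eta)
      winner <- if (win_a) a else v; loser <- if (win_a) v else a
      # bystanders within personal distance observe the escalated fight
      dxv <- wrap_delta(x - x[a], W); dyv <- wrap_delta(y - y[a], W)
      d2 <- dxv * dxv + dyv * dyv
      for (k in which(d2 <= pers2)) {
        if (k == a || k == v) next
        relax_agent(k, now)
        apply_inc(k, "observe_fight")
        next_time[k] <<- min(next_time[k],
          now + rtrunc_norm(params$react_mean_seconds / 60,
                            params$react_sd_seconds / 60))
      }
    } else {
      winner <- a; loser <- v
    }
    apply_inc(winner, "win_fight"); apply_inc(loser, "lose_fight")
    if (give_to[loser] > 0) end_groom(loser, now)
    start_flee <- function(l, w) {
      activity[l] <<- 1L; move_kind[l] <<- MV_FLEE; move_target[l] <<- w
      move_end_plan[l] <<- now + 1   # at most a minute of flight
      next_time[l] <<- now + step_min
    }
    start_flee(loser, winner)
    log_event(loser, 14L, winner)  # flee
    next_time[winner] <<- now + rtrunc_norm(params$act_delay_mean,
                                            params$act_delay_sd)
    invisible()
  }

  give_signal <- function(i, j, kind) {
    n_signals <<- n_signals + 1
    relax_agent(j, now)
    apply_inc(j, kind)
    next_time[j] <<- min(next_time[j],
      now + rtrunc_norm(params$react_mean_seconds / 60,
                        params$react_sd_seconds / 60))
    next_time[i] <<- now + rtrunc_norm(params$act_delay_mean,
                                       params$act_delay_sd)
    invisible()
  }

  action_select <- function(i) {
    dxv <- wrap_delta(x - x[i], W); dyv <- wrap_delta(y - y[i], W)
    d2 <- dxv * dxv + dyv * dyv; d2[i] <- Inf
    # refresh ego's dominant-proximity context from current distances
    dominant_near[i] <<- any(d2 <= pers2 & dom > dom[i])
    refresh_limit(i)
    # grouping has priority over action selection
    if (sum(d2 <= near2) < params$min_others || any(d2[-i] > far2)) {
      tgt <- if (n > 1) sample((1:n)[-i], 1L) else i
      start_move(i, MV_GROUPING, tgt)
      return(invisible())
    }
    sel <- which(d2 <= max2)
    if (length(sel)) {
      bearing <- (atan2(dyv[sel], dxv[sel]) * 180 / pi) %% 360
      in_view <- angle_offset(bearing, heading[i]) <= view[i] / 2
      ok <- d2[sel] <= interact2 | in_view
      sel <- sel[ok]
    }
    if (length(sel) > 1) sel <- sel[order(d2[sel], sel)]
    if (length(sel) > 10) sel <- sel[1:10]
    dist <- sqrt(d2[sel])
    lk <- NULL; lk_ref <- NULL
    if (lps > 0 && length(sel)) {
      # candidate LIKEs plus ego's best LIKE overall: selectivity is
      # relative to the most valued partner ego currently has
      row <- like_view(i, seq_len(n)[-i], now)
      lk <- like_view(i, sel, now)
      lk_ref <- max(row)
      n_like_reads <<- n_like_reads + n - 1L + length(sel)
    }
    grm_ok <- recv_from[sel] == 0L | recv_from[sel] == i
    aw <- action_weights(dist, fear[i, sel], lk, arousal[i], anxiety[i],
                         satisfaction[i], params, grm_ok, lk_ref)
    pick <- if (length(aw$w) == 1L) 1L
            else sample.int(length(aw$w), 1L, prob = aw$w)
    beh <- aw$beh[pick]
    j <- if (aw$tgt[pick] > 0) sel[aw$tgt[pick]] else 0L
    switch(beh,
      start_groom(i, j),                               # 1 groom
      { log_event(i, 2L, j); give_signal(i, j, "receive_affil_signal") },
      start_move(i, MV_APPROACH, j),                   # 3 approach
      do_attack(i, j),                                 # 4 attack
      { log_event(i, 5L, j); give_signal(i, j, "receive_aggr_signal") },
      start_move(i, MV_LEAVE, j),                      # 6 leave
      { log_event(i, 7L, j); give_signal(i, j, "receive_submission") },
      start_move(i, MV_AVOID, j),                      # 8 avoid
      { # 9 rest (with possible scanning); a received bout continues
        activity[i] <<- 0L
        view[i] <<- if (stats::runif(1) <
                        scan_probability(arousal[i], params$scan_base))
          params$max_angle else params$view_angle
        log_event(i, 9L, 0L)
        next_time[i] <<- now + rtrunc_norm(params$groom_schedule_mean,
                                           params$groom_schedule_sd)
      },
      start_move(i, MV_WALK, 0L))                      # 10 random walk
    invisible()
  }

  sample_like_now <- function(ts) {
    dtv <- ts - last_upd
    # row i of ps belongs to agent i, so its dt expands along rows
    psv <- ps - params$partner_sat_dec * matrix(dtv, n, n)
    psv[psv < 0] <- 0
    rr <- which(recv_from > 0)
    for (i in rr)
      psv[i, recv_from[i]] <-
        min(1, ps[i, recv_from[i]] + params$sat_receive_inc * dtv[i])
    lv <- like_step(like, psv, ts - like_upd, lhw)
    diag(lv) <- NA_real_
    lv
  }

  # main loop ------------------------------------------------------------
  repeat {
    i <- which.min(next_time)
    t <- next_time[i]
    while (samp_idx <= n_samp && sample_times[samp_idx] <= t) {
      like_samples[, , samp_idx] <- sample_like_now(sample_times[samp_idx])
      samp_idx <- samp_idx + 1L
    }
    while (snap_idx <= length(snap_times) && snap_times[snap_idx] <= t) {
      snapshots[[snap_idx]] <- sample_like_now(snap_times[snap_idx])
      snap_idx <- snap_idx + 1L
    }
    if (t > t_end) break
    now <- t
    n_activations <- n_activations + 1
    if (activity[i] == 1L) {
      movement_step(i)
      next
    }
    relax_agent(i, now)
    if (give_to[i] > 0) end_groom(i, now)  # scheduled end of a giving bout
    action_select(i)
  }

  # close grooming bouts still open at the end of the observation window
  for (g in which(give_to > 0)) {
    now <- t_end
    end_groom(g, t_end)
  }

  bouts <- data.frame(actor = b_actor[seq_len(bn)],
                      receiver = b_recv[seq_len(bn)],
                      start = b_t0[seq_len(bn)],
                      duration = b_dur[seq_len(bn)])
  events <- if (log_events) {
    beh_names <- c(BEHAVIORS, "approach_move", "avoid_move", "leave_move",
                   "flee", "grouping")
    data.frame(time = e_time[seq_len(en)], actor = e_actor[seq_len(en)],
               behavior = beh_names[e_beh[seq_len(en)]],
               target = e_tgt[seq_len(en)])
  } else NULL

  out <- list(
    params = params, seed = as.integer(seed),
    stab_minutes = stab, record_minutes = record_minutes,
    sample_times = sample_times,
    like_samples = like_samples,
    groom_interval = gm_int, n_intervals = n_samp,
    groom_month = gm_mon, n_months = n_mon,
    bouts = bouts, snapshots = snapshots,
    events = events,
    final = list(x = x, y = y, arousal = arousal, anxiety = anxiety,
                 satisfaction = satisfaction, like = like,
                 partner_sat = ps, activity = activity,
                 move_kind = move_kind, move_target = move_target,
                 heading = heading),
    counters = list(activations = n_activations, like_reads = n_like_reads,
                    attacks = n_attacks, fights = n_fights,
                    signals = n_signals, bouts = bn)
  )
  class(out) <- "emo_run"
  out
}
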