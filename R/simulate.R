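#' Behavioural specification of a simulated crocodile
#'
#' Three movement regimes are simulated, mirroring the ranging strategies
#' seen in adult estuarine crocodiles during the breeding and nesting
#' season:
#' \describe{
#'   \item{`site_fidelic_male`}{a mean-reverting (Ornstein-Uhlenbeck-like)
#'     along-river walk about `territory_centre_km`, with stationary scale
#'     `territory_scale_km`;}
#'   \item{`nomadic_male`}{a persistent directional walk that keeps its
#'     travel direction with probability `persistence` per hour, chooses
#'     branches uniformly at confluences and reflects at channel ends;}
#'   \item{`breeding_female`}{the mean-reverting walk plus scheduled
#'     long-distance excursions: directed travel to `destination_km`, a
#'     dwell of `dwell_h` hours, and (if `returns`) directed travel home.}
#' }
#' Hourly step sizes are scaled separately for day (08:00-18:00) and night
#' (18:00-08:00), matching the crocodilian preference for nocturnal travel.
#'
#' @param id Individual label.
#' @param sex `"male"` or `"female"`.
#' @param behaviour One of `"site_fidelic_male"`, `"nomadic_male"`,
#'   `"breeding_female"`.
#' @param total_length_m Total body length (m).
#' @param territory_centre_km Along-river position of the territory centre /
#'   nomad release point, km from the river mouth (main channel).
#' @param territory_scale_km Stationary SD of the mean-reverting walk (km).
#' @param step_scale_day_m_per_h,step_scale_night_m_per_h Hourly step SD
#'   (m/h) by time of day.
#' @param persistence Probability (per hour) that a nomad keeps its travel
#'   direction; must be in \[0, 1\].
#' @param excursion_schedule Females only: a list of lists with fields
#'   `start` (date), `destination_km`, `dwell_h`, `returns` (logical).
#' @param excursion_speed_m_per_h Directed travel speed during excursions.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(id, sex, behaviour, total_length_m,
                       territory_centre_km, territory_scale_km = 1,
                       step_scale_day_m_per_h = 200,
                       step_scale_night_m_per_h = 330,
                       persistence = 0.9,
                       excursion_schedule = list(),
                       excursion_speed_m_per_h = 1500) {
  behaviour <- match.arg(behaviour, c("site_fidelic_male", "nomadic_male", "breeding_female"))
  stopifnot(sex %in% c("male", "female"),
            step_scale_day_m_per_h >= 0, step_scale_night_m_per_h >= 0,
            persistence >= 0, persistence <= 1, territory_scale_km > 0)
  structure(list(id = id, sex = sex, behaviour = behaviour,
                 total_length_m = total_length_m,
                 territory_centre_km = territory_centre_km,
                 territory_scale_km = territory_scale_km,
                 step_scale_day_m_per_h = step_scale_day_m_per_h,
                 step_scale_night_m_per_h = step_scale_night_m_per_h,
                 persistence = persistence,
                 excursion_schedule = excursion_schedule,
                 excursion_speed_m_per_h = excursion_speed_m_per_h),
            class = "agent_spec")
}

#' GPS observation model
#'
#' Twice-daily GPS fixes (08:00 and 18:00 by default) with isotropic planar
#' error. With probability `bad_fix_fraction` a fix is poor quality: it is
#' assigned an SDOP above `sdop_good_max` and a much larger error SD, so the
#' downstream SDOP filter measurably improves positional accuracy.
#'
#' @param fix_times_local Clock hours of the scheduled fixes.
#' @param good_fix_error_sd_m Error SD (m) of good fixes (default 12, the
#'   stationary-test accuracy of the tags at SDOP <= 3).
#' @param bad_fix_fraction Proportion of poor-quality fixes (default 0.07).
#' @param bad_fix_error_sd_m Error SD (m) of poor fixes (default 250).
#' @param sdop_good_max SDOP at/below which a fix counts as good (default 3).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(fix_times_local = c(8, 18),
                              good_fix_error_sd_m = 12,
                              bad_fix_fraction = 0.07,
                              bad_fix_error_sd_m = 250,
                              sdop_good_max = 3) {
  stopifnot(bad_fix_fraction >= 0, bad_fix_fraction < 1,
            good_fix_error_sd_m >= 0, bad_fix_error_sd_m >= 0)
  structure(list(fix_times_local = sort(fix_times_local),
                 good_fix_error_sd_m = good_fix_error_sd_m,
                 bad_fix_fraction = bad_fix_fraction,
                 bad_fix_error_sd_m = bad_fix_error_sd_m,
                 sdop_good_max = sdop_good_max),
            class = "observation_model")
}

# --- river network as node/edge structure for the nomadic walk ------------

# Edges between mouth / confluences / tips. Each edge maps to a branch
# s-interval so positions translate back to centreline coordinates.
river_edges <- function(river) {
  main_len <- max(river$branches[[1]]$s)
  junc_s <- sort(river$topology$attach_s[!is.na(river$topology$attach_s)])
  node_at <- function(branch, s) sprintf("b%d@%.0f", branch, s)
  nodes <- c(node_at(1, 0), vapply(junc_s, function(s) node_at(1, s), ""), node_at(1, main_len))
  brk <- c(0, junc_s, main_len)
  edges <- list()
  for (k in seq_len(length(brk) - 1))
    edges[[length(edges) + 1]] <- list(a = node_at(1, brk[k]), b = node_at(1, brk[k + 1]),
                                       branch = 1L, s_a = brk[k], s_b = brk[k + 1],
                                       len = brk[k + 1] - brk[k])
  topo <- river$topology[!is.na(river$topology$parent), , drop = FALSE]
  for (i in seq_len(nrow(topo))) {
    br <- topo$branch[i]
    tlen <- max(river$branches[[br]]$s)
    edges[[length(edges) + 1]] <- list(a = node_at(1, topo$attach_s[i]),
                                       b = sprintf("tip%d", br),
                                       branch = br, s_a = 0, s_b = tlen, len = tlen)
  }
  adj <- list()
  for (e in seq_along(edges)) {
    for (nm in c(edges[[e]]$a, edges[[e]]$b))
      adj[[nm]] <- c(adj[[nm]] %||% integer(0), e)
  }
  list(edges = edges, adj = adj)
}

ou_rho <- function(sigma2_mean, scale_m) sqrt(max(0, 1 - sigma2_mean / scale_m^2))

#' Simulate the true trajectory of one crocodile
#'
#' Movement is one-dimensional along the river and mapped to planar
#' coordinates on the centreline, so every true position lies inside the
#' channel. Site-fidelic males and females move on the main channel;
#' nomadic males roam the whole branching network. See [agent_spec()] for
#' the three regimes.
#'
#' @param agent An [agent_spec()].
#' @param river A [generate_river()] object.
#' @param start_date,end_date Dates (inclusive); the trajectory runs from
#'   00:00 on `start_date` to 24:00 on `end_date`.
#' @param dt_h Time step in hours; must divide 24.
#' @param seed Optional integer seed (local RNG stream).
#' @return A data frame of class `trajectory`: `time`, `x`, `y`, `branch`,
#'   `s_m` (along-branch position), with the agent attached as an attribute.
#' @export
simulate_agent <- function(agent, river, start_date, end_date, dt_h = 1, seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"), inherits(river, "river"))
  if (dt_h <= 0 || 24 %% dt_h != 0) stopf("dt_h must be a positive divisor of 24")
  t0 <- as_time(paste(start_date, "00:00:00"))
  t1 <- as_time(paste(end_date, "00:00:00")) + 86400
  if (!(t0 < t1)) stopf("start_date must precede end_date")
  times <- seq(t0, t1, by = dt_h * 3600)
  n <- length(times)
  hrs <- hour_of(times)
  is_day <- hrs > 8 & hrs <= 18
  sig <- ifelse(is_day, agent$step_scale_day_m_per_h, agent$step_scale_night_m_per_h) * dt_h
  main_len <- max(river$branches[[1]]$s)
  c0 <- agent$territory_centre_km * 1000
  if (c0 < 0 || c0 > main_len) stopf("territory_centre_km lies beyond the river extent")
  with_seed(seed, {
    if (agent$behaviour == "nomadic_male") {
      net <- river_edges(river)
      # locate start on the main channel
      eidx <- which(vapply(net$edges, function(e) e$branch == 1L && e$s_a <= c0 && c0 <= e$s_b, TRUE))[1]
      e <- net$edges[[eidx]]
      pos <- c0 - e$s_a
      dir <- sample(c(-1, 1), 1)
      keep <- agent$persistence^dt_h
      branch <- integer(n); s_m <- numeric(n)
      for (t in seq_len(n)) {
        if (t > 1) {
          if (stats::runif(1) > keep) dir <- -dir
          d <- abs(stats::rnorm(1, 0, sig[t]))
          while (d > 0) {
            room <- if (dir > 0) e$len - pos else pos
            if (d <= room) { pos <- pos + dir * d; d <- 0 }
            else {
              d <- d - room
              node <- if (dir > 0) e$b else e$a
              pos <- if (dir > 0) e$len else 0
              inc <- setdiff(net$adj[[node]], eidx)
              if (!length(inc)) { dir <- -dir }        # channel end: reflect
              else {
                eidx <- if (length(inc) == 1) inc else sample(inc, 1)
                e <- net$edges[[eidx]]
                if (e$a == node) { pos <- 0; dir <- 1 } else { pos <- e$len; dir <- -1 }
              }
            }
          }
        }
        branch[t] <- e$branch
        s_m[t] <- e$s_a + pos * (if (e$s_b >= e$s_a) 1 else -1)
      }
    } else {
      # mean-reverting walk on the main channel; per-step autocorrelation is
      # solved from the step-size mix so the stationary SD equals
      # territory_scale_km
      scale_m <- agent$territory_scale_km * 1000
      rho <- ou_rho(mean(sig^2), scale_m)
      sched <- agent$excursion_schedule
      if (length(sched)) {
        for (ex in sched)
          if (ex$destination_km * 1000 < 0 || ex$destination_km * 1000 > main_len)
            stopf("excursion destination %.1f km lies beyond the river extent", ex$destination_km)
        ex_start <- as_time(paste(vapply(sched, function(e) as.character(e$start), ""), "00:00:00"))
      }
      s_m <- numeric(n); branch <- rep(1L, n)
      cur <- c0
      mode <- "home"; ex_i <- 0; dwell_until <- NA; target <- NA
      home_scale <- scale_m
      for (t in seq_len(n)) {
        if (t > 1) {
          if (length(sched) && ex_i < length(sched) && mode == "home" &&
              times[t] >= ex_start[ex_i + 1]) {
            ex_i <- ex_i + 1
            mode <- "travel_out"; target <- sched[[ex_i]]$destination_km * 1000
          }
          if (mode %in% c("travel_out", "travel_back")) {
            step <- agent$excursion_speed_m_per_h * dt_h
            if (abs(target - cur) <= step) {
              cur <- target
              if (mode == "travel_out") {
                mode <- "dwell"
                dwell_until <- times[t] + sched[[ex_i]]$dwell_h * 3600
              } else mode <- "home"
            } else cur <- cur + sign(target - cur) * step
          } else if (mode == "dwell") {
            anchor <- target
            rho_d <- ou_rho(mean(sig^2), 300)   # tight dwell about the destination
            cur <- anchor + rho_d * (cur - anchor) + stats::rnorm(1, 0, min(sig[t], 100))
            if (isTRUE(sched[[ex_i]]$returns) && times[t] >= dwell_until) {
              mode <- "travel_back"; target <- c0
            }
          } else {
            cur <- c0 + rho * (cur - c0) + stats::rnorm(1, 0, sig[t])
          }
          cur <- min(max(cur, 0), main_len)
        }
        s_m[t] <- cur
      }
    }
    xy <- do.call(rbind, lapply(split(seq_len(n), branch), function(ii) {
      p <- river_position(river, s_m[ii], branch[ii][1])
      data.frame(i = ii, x = p$x, y = p$y)
    }))
    xy <- xy[order(xy$i), ]
    out <- data.frame(time = times, x = xy$x, y = xy$y, branch = branch, s_m = s_m)
    attr(out, "agent") <- agent
    class(out) <- c("trajectory", "data.frame")
    out
  })
}

#' Observe a trajectory through the GPS model
#'
#' Emits one fix per scheduled clock time covered by the trajectory. Each
#' fix is the true position plus isotropic Gaussian error; with probability
#' `bad_fix_fraction` the fix is poor quality (SDOP drawn above
#' `sdop_good_max`, error SD `bad_fix_error_sd_m`), otherwise good (SDOP at
#' or below `sdop_good_max`, error SD `good_fix_error_sd_m`).
#'
#' @param traj A [simulate_agent()] trajectory.
#' @param model An [observation_model()].
#' @param seed Optional integer seed (local RNG stream).
#' @return A data frame of fixes: `id`, `timestamp`, `x`, `y`, `sdop`.
#' @export
observe_gps <- function(traj, model, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(model, "observation_model"))
  agent <- attr(traj, "agent")
  days <- seq(as.Date(min(traj$time)), as.Date(max(traj$time)), by = "day")
  sched <- sort(as_time(outer(as.character(days), sprintf("%02d:00:00", model$fix_times_local), paste)))
  sched <- sched[sched >= min(traj$time) & sched <= max(traj$time)]
  m <- match(as.numeric(sched), as.numeric(traj$time))
  if (anyNA(m)) stopf("trajectory does not cover all scheduled fix times")
  with_seed(seed, {
    k <- length(m)
    bad <- stats::runif(k) < model$bad_fix_fraction
    sd <- ifelse(bad, model$bad_fix_error_sd_m, model$good_fix_error_sd_m)
    sdop <- ifelse(bad,
                   stats::runif(k, model$sdop_good_max + 0.5, model$sdop_good_max + 7),
                   stats::runif(k, 0.5, model$sdop_good_max))
    data.frame(id = agent$id,
               timestamp = sched,
               x = traj$x[m] + stats::rnorm(k, 0, sd),
               y = traj$y[m] + stats::rnorm(k, 0, sd),
               sdop = sdop)
  })
}

#' Default simulated cohort
#'
#' Twelve adults mirroring the tracked study group: five site-fidelic males,
#' three nomadic males and four breeding females, with territory centres
#' spread along the main channel. Three females make a returning
#' reconnaissance trip in December followed by a permanent move to the same
#' (downriver) nesting site in January; the fourth makes a single permanent
#' upriver move in January.
#'
#' @return A list of [agent_spec()] objects.
#' @export
default_cohort <- function() {
  sf <- function(id, tl, centre)
    agent_spec(id, "male", "site_fidelic_male", tl, centre,
               territory_scale_km = 0.8,
               step_scale_day_m_per_h = 250, step_scale_night_m_per_h = 350)
  nm <- function(id, tl, centre)
    agent_spec(id, "male", "nomadic_male", tl, centre,
               step_scale_day_m_per_h = 200, step_scale_night_m_per_h = 330,
               persistence = 0.9)
  fe <- function(id, tl, centre, sched)
    agent_spec(id, "female", "breeding_female", tl, centre,
               territory_scale_km = 0.5,
               step_scale_day_m_per_h = 50, step_scale_night_m_per_h = 60,
               excursion_schedule = sched)
  trip <- function(start, dest, dwell, returns)
    list(start = start, destination_km = dest, dwell_h = dwell, returns = returns)
  list(
    nm("M1", 3.2, 45), nm("M2", 3.7, 75), nm("M3", 3.9, 100),
    sf("M4", 4.3, 30), sf("M5", 3.9, 55), sf("M6", 3.7, 70),
    sf("M7", 4.1, 90), sf("M8", 4.5, 115),
    fe("F1", 3.0, 35, list(trip("2011-01-10", 75, 48, FALSE))),
    fe("F2", 2.9, 48, list(trip("2010-12-12", 18, 36, TRUE),
                           trip("2011-01-02", 18, 48, FALSE))),
    fe("F3", 3.2, 62, list(trip("2010-12-15", 34, 40, TRUE),
                           trip("2011-01-05", 34, 48, FALSE))),
    fe("F4", 2.6, 90, list(trip("2010-12-18", 48, 30, TRUE),
                           trip("2011-01-08", 48, 48, FALSE)))
  )
}

#' Default river for the simulated study
#'
#' @param seed Seed for the river geometry (default 1).
#' @return A [river_spec()]: 150 km main channel, two tributaries, widths
#'   150-400 m.
#' @export
default_river_spec <- function(seed = 1)
  river_spec(150, n_tributaries = 2, channel_width_m = c(150, 400), seed = seed)

#' Simulate a full cohort and its telemetry
#'
#' Runs [simulate_agent()] and [observe_gps()] for every agent over the
#' default study period (01 September - 28 February) under a single seed.
#'
#' @param river A [generate_river()] object.
#' @param agents List of [agent_spec()]s (default [default_cohort()]).
#' @param start_date,end_date Study period bounds.
#' @param model An [observation_model()].
#' @param seed Integer seed; agent `i` uses `seed * 100 + i` for movement
#'   and `seed * 100 + 50 + i` for observation, keeping every derived seed
#'   well below 2^31.
#' @return A list: `fixes` (all individuals' fixes, one data frame),
#'   `truth` (named list of trajectories), `agents`.
#' @export
simulate_cohort <- function(river, agents = default_cohort(),
                            start_date = "2010-09-01", end_date = "2011-02-28",
                            model = observation_model(), seed = 1) {
  truth <- list(); fixes <- list()
  for (i in seq_along(agents)) {
    tr <- simulate_agent(agents[[i]], river, start_date, end_date,
                         dt_h = 1, seed = seed * 100 + i)
    truth[[agents[[i]]$id]] <- tr
    fixes[[i]] <- observe_gps(tr, model, seed = seed * 100 + 50 + i)
  }
  list(fixes = do.call(rbind, fixes), truth = truth, agents = agents)
}

#' Cohort metadata table
#'
#' @param agents List of [agent_spec()]s.
#' @return Data frame: id, sex, behaviour, total_length_m,
#'   snout_vent_length_m (approximated as half the total length).
#' @export
cohort_metadata <- function(agents = default_cohort()) {
  data.frame(id = vapply(agents, `[[`, "", "id"),
             sex = vapply(agents, `[[`, "", "sex"),
             behaviour = vapply(agents, `[[`, "", "behaviour"),
             total_length_m = vapply(agents, `[[`, 0, "total_length_m"),
             snout_vent_length_m = vapply(agents, `[[`, 0, "total_length_m") / 2)
}
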