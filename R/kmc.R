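#' Single-file hopping model
#'
#' Continuous-time Markov jump model of K+ ions hopping between the seven
#' binding sites S6 (cavity) through S0 (extracellular mouth), with
#' hard-core exclusion (hops only to adjacent sites below capacity, no
#' passing), short-range repulsion, voltage bias, and concentration-like
#' entry rates from both reservoirs. Rates, in 1/ns:
#' \itemize{
#'   \item hop from site i to an adjacent allowed site:
#'     `k0 * exp(-depth[i]) * exp(+/- bias/2)` (+ for outward moves, i.e.
#'     towards S0/EXTRA)
#'   \item entry INTRA->S6: `k_in_intra * exp(+bias/2)`; entry EXTRA->S0:
#'     `k_in_extra * exp(-bias/2)`
#'   \item exit S0->EXTRA: `k_out_extra * exp(-depth[S0]) * exp(+bias/2)`;
#'     exit S6->INTRA: `k_out_intra * exp(-depth[S6]) * exp(-bias/2)`;
#'     both exits additionally carry the crowding factor
#'     `exp(crowding * (n_pore - crowding_ref))`
#' }
#' A destination site is allowed when it is below capacity and no other
#' ion sits within `repulsion_range` sites of it (multiple occupancy of
#' one site is governed by capacity alone, so the S0 doublet remains
#' possible). The default range of 1 emulates the ion-ion electrostatic
#' repulsion that keeps filter ions separated by a vacancy; together with
#' the deep wells at S0, S2 and S4 it makes `K:0:2:4` the resting
#' configuration and drives conduction through the knock-on shuffle. The
#' crowding factor is the kinetic face of the same repulsion: a
#' supernumerary ion destabilizes the outermost one (fast knock-on
#' detachment), while a depleted pore holds on to its remaining ions.
#' Site depths (dimensionless, kT units) slow every escape from a site.
#' Defaults describe a moderately driven outward-conducting channel in
#' which push and pull conductions both occur.
#'
#' Ion identities are fresh integers on entry and retired on exit; the
#' reservoirs are infinite.
#'
#' @param centers site center z (Angstrom), named S0..S6 (must match the
#'   site model used for analysis; defaults match [default_site_model()])
#' @param depths per-site well depths (kT), named S0..S6
#' @param k0 base hop attempt rate (1/ns)
#' @param bias voltage bias per hop (dimensionless, ~ qV per step / kT;
#'   positive drives ions outward)
#' @param k_in_intra,k_in_extra entry rates (1/ns), proportional to the
#'   reservoir concentrations
#' @param k_out_extra,k_out_intra exit rate scales (1/ns)
#' @param capacity per-site capacities (default S0 = 2, others 1)
#' @param repulsion_range blocking distance: a move is rejected when
#'   another ion occupies a site within this many positions of the
#'   destination (0 restores plain single-site exclusion)
#' @param crowding exit-rate coupling to the pore ion count (kT per ion)
#' @param crowding_ref reference count at which the crowding factor is 1
#' @param jitter_sd Gaussian positional jitter of sampled frames
#'   (Angstrom); must stay below half the minimal center spacing
#' @param init_sites sites seeded with one ion each at t = 0
#' @param bulk_z length-2 axial positions used to render reservoir ions in
#'   sampled frames (intra, extra)
#' @return a `hop_model` list
#' @export
hop_model <- function(centers = c(S0 = 14.4, S1 = 11.2, S2 = 8.0,
                                  S3 = 4.8, S4 = 1.6, S5 = -1.75,
                                  S6 = -9.75),
                      depths = c(S0 = 2.5, S1 = 0, S2 = 2.5, S3 = 0,
                                 S4 = 2.5, S5 = 0, S6 = 0),
                      k0 = 20, bias = 2,
                      k_in_intra = 0.4, k_in_extra = 0.1,
                      k_out_extra = 1, k_out_intra = 0.1,
                      capacity = c(S0 = 2L, S1 = 1L, S2 = 1L, S3 = 1L,
                                   S4 = 1L, S5 = 1L, S6 = 1L),
                      repulsion_range = 1L, crowding = 2,
                      crowding_ref = 3L,
                      jitter_sd = 0.25,
                      init_sites = c(0L, 2L, 4L),
                      bulk_z = c(intra = -18, extra = 18)) {
  sites <- paste0("S", 0:6)
  centers <- centers[sites]; depths <- depths[sites]
  capacity <- capacity[sites]
  stopifnot(!anyNA(centers), !anyNA(depths), !anyNA(capacity),
            k0 >= 0, k_in_intra >= 0, k_in_extra >= 0,
            k_out_extra >= 0, k_out_intra >= 0, jitter_sd >= 0)
  gap <- min(abs(diff(centers)))
  if (jitter_sd >= gap / 2) {
    stop(sprintf(
      "jitter_sd %.2f A would corrupt site assignment (min center gap %.2f A)",
      jitter_sd, gap))
  }
  structure(list(centers = centers, depths = depths, k0 = k0, bias = bias,
                 k_in_intra = k_in_intra, k_in_extra = k_in_extra,
                 k_out_extra = k_out_extra, k_out_intra = k_out_intra,
                 capacity = as.integer(capacity),
                 repulsion_range = as.integer(repulsion_range),
                 crowding = crowding, crowding_ref = as.integer(crowding_ref),
                 jitter_sd = jitter_sd,
                 init_sites = as.integer(init_sites), bulk_z = bulk_z),
            class = "hop_model")
}

#' Push- and pull-dominated model variants
#'
#' The push regime emulates a high intracellular ion concentration:
#' intracellular entry is accelerated and extracellular exit slowed by a
#' factor `1 + strength` each, so a new ion usually associates before the
#' outermost ion leaves and conductions pass through four-ion
#' intermediates. The pull regime is the inverse (a strong outward field
#' emptying S0 first: two-ion intermediates). At `strength = 0` both reduce
#' to the base model.
#'
#' @param strength non-negative regime strength
#' @param base the base `hop_model`
#' @return a `hop_model`
#' @export
make_push_regime <- function(strength = 10, base = hop_model()) {
  stopifnot(strength >= 0)
  base$k_in_intra <- base$k_in_intra * (1 + strength)
  base$k_out_extra <- base$k_out_extra / (1 + strength)
  base
}

#' @rdname make_push_regime
#' @export
make_pull_regime <- function(strength = 10, base = hop_model()) {
  stopifnot(strength >= 0)
  base$k_in_intra <- base$k_in_intra / (1 + strength)
  base$k_out_extra <- base$k_out_extra * (1 + strength)
  base
}

# destination `to` (0-based site) admissible for an ion coming from
# `from` (0-based site, or NA for reservoir entries)?
.kmc_allowed <- function(m, occ, to, from = NA_integer_) {
  if (occ[to + 1L] >= m$capacity[to + 1L]) return(FALSE)
  r <- m$repulsion_range
  if (r > 0L) {
    for (j in max(0L, to - r):min(6L, to + r)) {
      if (j == to) next                   # same-site stacking: capacity rule
      if (!is.na(from) && j == from) next # the mover itself does not block
      if (occ[j + 1L] > 0L) return(FALSE)
    }
  }
  TRUE
}

# enumerate the possible moves of an occupancy state; occ = integer count
# per site index 1..7 (S0..S6)
.kmc_moves <- function(m, occ) {
  half <- m$bias / 2
  kinds <- character(0L); sitev <- integer(0L); rates <- numeric(0L)
  add <- function(kind, site, rate) {
    if (rate > 0) {
      kinds <<- c(kinds, kind); sitev <<- c(sitev, site)
      rates <<- c(rates, rate)
    }
  }
  crowd <- exp(m$crowding * (sum(occ) - m$crowding_ref))
  for (i in 0:6) {
    ii <- i + 1L
    if (occ[ii] == 0L) next
    esc <- m$k0 * exp(-m$depths[ii])
    if (i > 0L && .kmc_allowed(m, occ, i - 1L, i)) {    # outward hop i->i-1
      add("hop_out", i, esc * exp(half))
    }
    if (i < 6L && .kmc_allowed(m, occ, i + 1L, i)) {    # inward hop i->i+1
      add("hop_in", i, esc * exp(-half))
    }
    if (i == 0L) add("exit_extra", 0L,
                     m$k_out_extra * exp(-m$depths[1L]) * exp(half) * crowd)
    if (i == 6L) add("exit_intra", 6L,
                     m$k_out_intra * exp(-m$depths[7L]) * exp(-half) * crowd)
  }
  if (.kmc_allowed(m, occ, 6L)) add("entry_intra", 6L,
                                    m$k_in_intra * exp(half))
  if (.kmc_allowed(m, occ, 0L)) add("entry_extra", 0L,
                                    m$k_in_extra * exp(-half))
  list(kind = kinds, site = sitev, rate = rates)
}

#' Simulate a single-file hopping trajectory (kinetic Monte Carlo)
#'
#' Exact Gillespie simulation of the jump process defined by a
#' [hop_model()]: exponential waiting times, event chosen with probability
#' proportional to its rate. The exact event log is the ground truth; the
#' returned trajectory samples ion positions on a regular frame grid with
#' Gaussian jitter around the site centers. To make entry and exit sides
#' observable to downstream analysis, an ion is also rendered at its
#' reservoir-side bulk position for the frames in the one-frame margin
#' around its entry and exit. Events between frames are intentionally
#' invisible in the sampled trajectory.
#'
#' The event log is independent of `frame_interval_ps`: all simulation
#' randomness is consumed before any jitter is drawn.
#'
#' @param model a `hop_model`
#' @param t_end_ns simulated time (ns)
#' @param seed RNG seed
#' @param frame_interval_ps frame spacing of the sampled trajectory (ps)
#' @return a list:
#'   \item{trajectory}{an `ion_trajectory`}
#'   \item{log}{data.table `time_ns`, `ion_id`, `kind`, `from`, `to`
#'     (regions) -- the exact ground truth}
#'   \item{conductions}{data.table of ground-truth conductions: `ion_id`,
#'     `direction`, `t_enter_ns`, `t_exit_ns`, `mechanism`,
#'     `intermediate_lifetime_ns`, `initial_resident`}
#' @export
simulate_hopping <- function(model, t_end_ns, seed = 1L,
                             frame_interval_ps = 20) {
  stopifnot(inherits(model, "hop_model"), t_end_ns > 0)
  with_seed(seed, {
    log <- .kmc_run(model, t_end_ns)
    traj <- .kmc_frames(model, log, t_end_ns, frame_interval_ps)
    list(trajectory = traj, log = log,
         conductions = .kmc_ground_truth(log, model))
  })
}

.kmc_run <- function(m, t_end) {
  cap <- 4096L
  ev_t <- numeric(cap); ev_ion <- integer(cap)
  ev_kind <- character(cap); ev_from <- character(cap)
  ev_to <- character(cap)
  n_ev <- 0L
  push_ev <- function(t, ion, kind, from, to) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_ion) <<- cap
      length(ev_kind) <<- cap; length(ev_from) <<- cap; length(ev_to) <<- cap
    }
    ev_t[n_ev] <<- t; ev_ion[n_ev] <<- ion; ev_kind[n_ev] <<- kind
    ev_from[n_ev] <<- from; ev_to[n_ev] <<- to
  }
  site_name <- function(i) paste0("S", i)

  # per-site ion stacks; S0 kept ordered inner -> outer
  ions <- vector("list", 7L)
  occ <- integer(7L)
  next_id <- 1L
  for (s in m$init_sites) {
    ions[[s + 1L]] <- c(ions[[s + 1L]], next_id)
    occ[s + 1L] <- occ[s + 1L] + 1L
    next_id <- next_id + 1L
  }

  t <- 0
  repeat {
    mv <- .kmc_moves(m, occ)
    total <- sum(mv$rate)
    if (total <= 0) break
    t <- t + rexp(1L, total)
    if (t >= t_end) break
    k <- findInterval(runif(1L) * total, cumsum(mv$rate),
                      left.open = TRUE) + 1L
    kind <- mv$kind[k]; i <- mv$site[k]; ii <- i + 1L
    if (kind == "hop_out") {
      ion <- ions[[ii]][1L]                       # inner-most leaves first
      ions[[ii]] <- ions[[ii]][-1L]
      ions[[i]] <- c(ions[[i]], ion)              # arrives as inner at i-1?
      # ordering only matters at S0: an ion hopping up from S1 is inner
      if (i == 1L && length(ions[[1L]]) > 1L) {
        ions[[1L]] <- c(ion, setdiff(ions[[1L]], ion))
      }
      occ[ii] <- occ[ii] - 1L; occ[i] <- occ[i] + 1L
      push_ev(t, ion, "hop", site_name(i), site_name(i - 1L))
    } else if (kind == "hop_in") {
      ion <- tail(ions[[ii]], 1L)                 # outer-most moves inward
      ions[[ii]] <- ions[[ii]][-length(ions[[ii]])]
      ions[[ii + 1L]] <- c(ions[[ii + 1L]], ion)
      occ[ii] <- occ[ii] - 1L; occ[ii + 1L] <- occ[ii + 1L] + 1L
      push_ev(t, ion, "hop", site_name(i), site_name(i + 1L))
    } else if (kind == "exit_extra") {
      ion <- tail(ions[[1L]], 1L)                 # outer S0 ion exits
      ions[[1L]] <- ions[[1L]][-length(ions[[1L]])]
      occ[1L] <- occ[1L] - 1L
      push_ev(t, ion, "exit_extra", "S0", "EXTRA")
    } else if (kind == "exit_intra") {
      ion <- ions[[7L]][1L]
      ions[[7L]] <- ions[[7L]][-1L]
      occ[7L] <- occ[7L] - 1L
      push_ev(t, ion, "exit_intra", "S6", "INTRA")
    } else if (kind == "entry_intra") {
      ions[[7L]] <- c(ions[[7L]], next_id)
      occ[7L] <- occ[7L] + 1L
      push_ev(t, next_id, "entry_intra", "INTRA", "S6")
      next_id <- next_id + 1L
    } else {                                      # entry_extra
      ions[[1L]] <- c(ions[[1L]], next_id)        # arrives as outer
      occ[1L] <- occ[1L] + 1L
      push_ev(t, next_id, "entry_extra", "EXTRA", "S0")
      next_id <- next_id + 1L
    }
  }
  keep <- seq_len(n_ev)
  init <- data.table(time_ns = 0, ion_id = seq_along(m$init_sites),
                     kind = "seed", from = paste0("S", m$init_sites),
                     to = paste0("S", m$init_sites))
  rbind(init,
        data.table(time_ns = ev_t[keep], ion_id = ev_ion[keep],
                   kind = ev_kind[keep], from = ev_from[keep],
                   to = ev_to[keep]))
}

# piecewise site intervals per ion from the event log
.kmc_segments <- function(log, t_end) {
  segs <- list()
  for (sub in split(log, by = "ion_id")) {
    setorder(sub, time_ns)
    t_cur <- NA_real_; site_cur <- NA_character_
    side_in <- NA_character_
    rows <- list()
    for (j in seq_len(nrow(sub))) {
      kind <- sub$kind[j]
      if (kind == "seed") {
        t_cur <- 0; site_cur <- sub$to[j]
      } else if (kind %in% c("entry_intra", "entry_extra")) {
        t_cur <- sub$time_ns[j]; site_cur <- sub$to[j]
        side_in <- if (kind == "entry_intra") "intra" else "extra"
      } else if (kind == "hop") {
        rows[[length(rows) + 1L]] <-
          data.table(t0 = t_cur, t1 = sub$time_ns[j], site = site_cur)
        t_cur <- sub$time_ns[j]; site_cur <- sub$to[j]
      } else {                                    # exit
        rows[[length(rows) + 1L]] <-
          data.table(t0 = t_cur, t1 = sub$time_ns[j], site = site_cur)
        rows[[length(rows) + 1L]] <-
          data.table(t0 = sub$time_ns[j], t1 = NA_real_,
                     site = if (kind == "exit_intra") "INTRA" else "EXTRA")
        t_cur <- NA_real_; site_cur <- NA_character_
      }
    }
    if (!is.na(t_cur)) {
      rows[[length(rows) + 1L]] <-
        data.table(t0 = t_cur, t1 = t_end, site = site_cur)
    }
    seg <- rbindlist(rows)
    seg[, `:=`(ion_id = sub$ion_id[1L], entry_side = side_in)]
    segs[[length(segs) + 1L]] <- seg
  }
  rbindlist(segs)
}

.kmc_frames <- function(m, log, t_end, frame_interval_ps) {
  dt_ns <- frame_interval_ps / 1e3
  frame_t <- seq(0, t_end, by = dt_ns)
  n_frames <- length(frame_t)
  segs <- .kmc_segments(log, t_end)
  rows <- list()
  for (sub in split(segs, by = "ion_id")) {
    setorder(sub, t0)
    in_pore <- sub[site %like% "^S"]
    if (nrow(in_pore) == 0L) next
    t_in <- min(in_pore$t0); t_out <- max(in_pore$t1)
    lo <- max(1L, ceiling((t_in - dt_ns) / dt_ns) + 1L)
    hi <- min(n_frames, floor((t_out + dt_ns) / dt_ns) + 1L)
    if (lo > hi) next
    ts <- frame_t[lo:hi]
    idx <- findInterval(ts, sub$t0)
    site <- sub$site[pmax(idx, 1L)]
    # frames in the one-frame margin before entry / after exit: bulk side
    pre <- ts < t_in
    post <- ts >= t_out & site %in% c("INTRA", "EXTRA")
    z <- numeric(length(ts))
    pore <- !pre & !(site %in% c("INTRA", "EXTRA"))
    z[pore] <- m$centers[site[pore]]
    if (any(pre)) {
      side <- sub$entry_side[1L]
      if (is.na(side)) side <- "intra"            # seeded ions have no entry
      z[pre] <- m$bulk_z[[side]]
    }
    if (any(post)) {
      z[post] <- ifelse(site[post] == "INTRA",
                        m$bulk_z[["intra"]], m$bulk_z[["extra"]])
    }
    keep <- pore | pre | post
    rows[[length(rows) + 1L]] <-
      data.table(frame = (lo:hi)[keep] - 1L, time_ps = ts[keep] * 1e3,
                 ion_id = sub$ion_id[1L],
                 z = z[keep] + rnorm(sum(keep), 0, m$jitter_sd))
  }
  out <- rbindlist(rows)
  # anchor the frame grid so frame_interval/duration are well defined even
  # if the first/last frames hold no ions
  validate_ion_trajectory(out)
}

# ground-truth conductions from the exact event log
.kmc_ground_truth <- function(log, m, resting = length(m$init_sites)) {
  ev <- log[kind != "hop"]
  setorder(ev, time_ns)
  delta <- fcase(ev$kind %in% c("entry_intra", "entry_extra", "seed"), 1L,
                 default = -1L)
  count <- cumsum(delta)           # pore ion count after each event
  n <- nrow(ev)
  # entry bookkeeping per ion
  entry_side <- fcase(ev$kind == "entry_intra", "intra",
                      ev$kind == "entry_extra", "extra",
                      default = NA_character_)
  side_of <- list(); t_in_of <- list()
  recs <- list()
  for (j in seq_len(n)) {
    id <- as.character(ev$ion_id[j])
    k <- ev$kind[j]
    if (k %in% c("seed", "entry_intra", "entry_extra")) {
      side_of[[id]] <- entry_side[j]
      t_in_of[[id]] <- ev$time_ns[j]
    } else {
      exit_side <- if (k == "exit_intra") "intra" else "extra"
      in_side <- side_of[[id]]
      if (is.null(in_side)) in_side <- NA_character_
      if (is.na(in_side) || in_side != exit_side) {
        c_pre <- count[j] + 1L                    # count just before exit
        mech <- if (c_pre > resting) "III-IV-III" else "III-II-III"
        # intermediate: continuous-time run of count != resting around exit
        lt <- .gt_lifetime(count, ev$time_ns, j, resting)
        recs[[length(recs) + 1L]] <- data.table(
          ion_id = ev$ion_id[j],
          direction = if (exit_side == "extra") "outward" else "inward",
          t_enter_ns = if (is.null(t_in_of[[id]])) 0 else t_in_of[[id]],
          t_exit_ns = ev$time_ns[j], mechanism = mech,
          intermediate_lifetime_ns = lt$lifetime,
          truncated = lt$truncated,
          initial_resident = is.na(in_side))
      }
      side_of[[id]] <- NULL
    }
  }
  if (length(recs) == 0L) {
    return(data.table(ion_id = integer(), direction = character(),
                      t_enter_ns = numeric(), t_exit_ns = numeric(),
                      mechanism = character(),
                      intermediate_lifetime_ns = numeric(),
                      truncated = logical(),
                      initial_resident = logical()))
  }
  rbindlist(recs)
}

# exact lifetime of the non-resting excursion tied to the exit at event j;
# truncated = the excursion touches the start or end of the log
.gt_lifetime <- function(count, times, j, resting) {
  n <- length(count)
  c_pre <- count[j] + 1L
  if (c_pre > resting) {
    s <- j - 1L                    # last event before exit; count[s] = c_pre
    while (s >= 1L && count[s] != resting) s <- s - 1L
    t_start <- if (s >= 1L) times[s + 1L] else times[1L]
    e <- j
    while (e <= n && count[e] != resting) e <- e + 1L
    t_end <- if (e <= n) times[e] else times[n]
    list(lifetime = t_end - t_start, truncated = s < 1L || e > n)
  } else {
    e <- j
    while (e <= n && count[e] != resting) e <- e + 1L
    t_end <- if (e <= n) times[e] else times[n]
    list(lifetime = t_end - times[j], truncated = e > n)
  }
}
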