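#' Boundary-crossing events
#'
#' Scans each ion's region sequence and emits one event per crossing of a
#' pore boundary, ordered by time:
#' \describe{
#'   \item{assoc_intra}{the ion entered the pore from the intracellular
#'     fluid (INTRA to S6)}
#'   \item{dissoc_extra}{the ion detached from S0 into the extracellular
#'     fluid}
#'   \item{assoc_extra}{entry from the extracellular side (EXTRA to S0)}
#'   \item{dissoc_intra}{any pore-to-INTRA exit (from S6 or, in fast inward
#'     events, S5)}
#' }
#' When an ion first appears (or last disappears) inside the pore without a
#' bulk observation, the crossing side is inferred from the nearest pore
#' end (sites S4--S6 imply the intracellular side, S0--S2 the extracellular
#' side) and the event is marked `inferred`. An ion already in the pore at
#' the first frame generates no entry event; an ion still in the pore at the
#' last frame generates no exit event.
#'
#' @param seq a `state_sequence`
#' @return data.table `time_ps`, `frame`, `ion_id`, `kind`, `inferred`,
#'   where `frame` is the first frame in the new region
#' @export
boundary_events <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  .boundary_steps(seq)
}

.boundary_steps <- function(seq) {
  asn <- seq$assignments
  st <- seq$states
  f_first <- st$frame[1L]
  f_last <- st$frame[nrow(st)]
  t_of <- function(f) st$time_ps[f - f_first + 1L]

  out <- vector("list", uniqueN(asn$ion_id))
  i <- 0L
  for (sub in split(asn[order(frame)], by = "ion_id")) {
    f <- sub$frame
    reg <- sub$region
    site <- sub$site
    n <- length(f)
    ev_frame <- integer(0L); ev_kind <- character(0L); ev_inf <- logical(0L)
    add <- function(frame, kind, inferred = FALSE) {
      ev_frame <<- c(ev_frame, frame)
      ev_kind <<- c(ev_kind, kind)
      ev_inf <<- c(ev_inf, inferred)
    }
    if (!is.na(site[1L]) && f[1L] > f_first) {
      add(f[1L], if (site[1L] > 3L) "assoc_intra" else "assoc_extra", TRUE)
    }
    if (n > 1L) {
      for (j in 2:n) {
        p <- reg[j - 1L]; q <- reg[j]
        p_pore <- !is.na(site[j - 1L]); q_pore <- !is.na(site[j])
        if (p_pore && q_pore) next
        if (p == q) next
        if (!p_pore && q_pore) {
          add(f[j], if (p == "INTRA") "assoc_intra" else "assoc_extra")
        } else if (p_pore && !q_pore) {
          add(f[j], if (q == "INTRA") "dissoc_intra" else "dissoc_extra")
        } else if (p == "INTRA" && q == "EXTRA") {
          add(f[j], "assoc_intra"); add(f[j], "dissoc_extra")
        } else if (p == "EXTRA" && q == "INTRA") {
          add(f[j], "assoc_extra"); add(f[j], "dissoc_intra")
        }
      }
    }
    if (!is.na(site[n]) && f[n] < f_last) {
      add(f[n] + 1L, if (site[n] > 3L) "dissoc_intra" else "dissoc_extra",
          TRUE)
    }
    i <- i + 1L
    if (length(ev_frame) > 0L) {
      out[[i]] <- data.table(frame = ev_frame, ion_id = sub$ion_id[1L],
                             kind = ev_kind, inferred = ev_inf)
    }
  }
  ev <- rbindlist(out)
  if (nrow(ev) == 0L) {
    return(data.table(time_ps = numeric(), frame = integer(),
                      ion_id = asn$ion_id[0L], kind = character(),
                      inferred = logical()))
  }
  ev[, time_ps := t_of(frame)]
  setcolorder(ev, c("time_ps", "frame", "ion_id", "kind", "inferred"))
  setorder(ev, time_ps, ion_id)
  ev[]
}

#' Detect completed permeation events
#'
#' A conduction is one completed traversal: an ion whose pore-entry side
#' differs from its pore-exit side. Back-running -- an ion dissociating to
#' one reservoir and re-entering from the same side as its next boundary
#' event -- cancels the exit: the ion is treated as never having left, so
#' the pair contributes no conduction and the ion keeps its original entry
#' side. An ion that entered and exited on the same side (a failed entry)
#' likewise contributes nothing. Ions already resident in the pore at the
#' first frame have unknown entry side; when they exit they are counted
#' (direction taken from the exit side) and flagged `initial_resident`.
#'
#' @param events boundary events from [boundary_events()]
#' @param seq the `state_sequence` the events came from
#' @return a `conduction_events` data.table: `ion_id`, `direction`
#'   (`"outward"` / `"inward"`), `t_enter_ps`, `t_exit_ps`, `exit_frame`,
#'   `initial_resident`, plus empty classification columns. Attribute
#'   `n_backrun` counts cancelled same-side exits.
#' @export
detect_conductions <- function(events, seq) {
  stopifnot(inherits(seq, "state_sequence"))
  t0 <- seq$states$time_ps[1L]
  recs <- list()
  n_backrun <- 0L
  for (sub in split(events, by = "ion_id")) {
    setorder(sub, time_ps)
    entry_side <- NA_character_   # NA = initial resident (or unknown)
    t_enter <- t0
    initial <- TRUE
    pending <- NULL               # provisional exit awaiting cancellation
    for (j in seq_len(nrow(sub))) {
      kind <- sub$kind[j]
      side <- if (endsWith(kind, "intra")) "intra" else "extra"
      if (startsWith(kind, "assoc")) {
        if (!is.null(pending)) {
          if (pending$exit_side == side) {
            n_backrun <- n_backrun + 1L       # back-running: cancel exit
          } else {
            recs[[length(recs) + 1L]] <- .finalize_exit(pending)
            entry_side <- side; t_enter <- sub$time_ps[j]; initial <- FALSE
          }
          pending <- NULL
        } else {
          entry_side <- side; t_enter <- sub$time_ps[j]; initial <- FALSE
        }
      } else {                                 # dissoc
        pending <- list(ion_id = sub$ion_id[j], entry_side = entry_side,
                        exit_side = side, t_enter = t_enter,
                        t_exit = sub$time_ps[j], exit_frame = sub$frame[j],
                        initial = initial)
      }
    }
    if (!is.null(pending)) {
      recs[[length(recs) + 1L]] <- .finalize_exit(pending)
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (length(recs) == 0L) {
    cond <- data.table(ion_id = events$ion_id[0L], direction = character(),
                       t_enter_ps = numeric(), t_exit_ps = numeric(),
                       exit_frame = integer(), initial_resident = logical())
  } else {
    cond <- rbindlist(recs)
    setorder(cond, t_exit_ps)
  }
  cond[, `:=`(mechanism = rep(NA_character_, .N),
              intermediate_group = rep(NA_character_, .N),
              lifetime_ns = rep(NA_real_, .N))]
  setattr(cond, "n_backrun", n_backrun)
  setattr(cond, "class", c("conduction_events", class(data.table())))
  cond[]
}

# a finalized exit is a conduction when the sides differ or the entry side
# is unknown (initial resident); a same-side entry/exit is a failed entry
.finalize_exit <- function(p) {
  if (!is.na(p$entry_side) && p$entry_side == p$exit_side) return(NULL)
  data.table(ion_id = p$ion_id,
             direction = if (p$exit_side == "extra") "outward" else "inward",
             t_enter_ps = p$t_enter, t_exit_ps = p$t_exit,
             exit_frame = p$exit_frame, initial_resident = p$initial)
}

#' Classify conduction mechanisms
#'
#' For each conduction, the pore ion count on the frame just before the
#' permeating ion's exit decides the mechanism relative to the resting
#' count (3 by default): a count above resting means the replacement ion
#' associated before the dissociation -- the push, III-IV-III mechanism,
#' with a four-ion (or larger) intermediate; a count at resting means the
#' dissociation came first and the pore passes through a two-ion
#' intermediate before a new ion associates -- the pull, III-II-III
#' mechanism. The intermediate lifetime is the time spent outside the
#' resting ion count within that cycle: the contiguous run of
#' non-resting-count frames ending at the exit (push) or starting at it
#' (pull). A cycle cut off by the start or end of the trajectory, or an
#' exit exactly compensated within one frame interval, is `unclassified`
#' and excluded from ratios.
#'
#' @param conductions a `conduction_events` table from [detect_conductions()]
#' @param seq the `state_sequence`
#' @param resting resting pore ion count (default 3)
#' @return `conductions` with `mechanism` (`"III-IV-III"`, `"III-II-III"`
#'   or `"unclassified"`), `intermediate_group` (`"IV"` / `"II"`) and
#'   `lifetime_ns` filled in
#' @export
classify_mechanisms <- function(conductions, seq, resting = 3L) {
  stopifnot(inherits(seq, "state_sequence"))
  cond <- copy(conductions)
  if (nrow(cond) == 0L) return(cond)
  st <- seq$states
  cnt <- st$ion_count
  N <- length(cnt)
  dt_ps <- seq$frame_interval
  f_first <- st$frame[1L]

  for (r in seq_len(nrow(cond))) {
    ix <- cond$exit_frame[r] - f_first + 1L
    if (is.na(ix) || ix <= 1L || ix > N) {
      set(cond, r, "mechanism", "unclassified"); next
    }
    c_pre <- cnt[ix - 1L]
    if (c_pre > resting) {
      s <- ix - 1L
      while (s > 1L && cnt[s - 1L] != resting) s <- s - 1L
      e <- ix - 1L
      while (e < N && cnt[e + 1L] != resting) e <- e + 1L
      set(cond, r, "mechanism", "III-IV-III")
      set(cond, r, "intermediate_group", "IV")
      set(cond, r, "lifetime_ns", (e - s + 1L) * dt_ps / 1e3)
    } else if (c_pre == resting) {
      if (cnt[ix] >= resting) {
        set(cond, r, "mechanism", "unclassified")  # compensated in-frame
        next
      }
      e <- ix
      while (e < N && cnt[e + 1L] != resting) e <- e + 1L
      if (e == N && cnt[N] != resting) {
        set(cond, r, "mechanism", "unclassified")  # ends mid-cycle
        next
      }
      set(cond, r, "mechanism", "III-II-III")
      set(cond, r, "intermediate_group", "II")
      set(cond, r, "lifetime_ns", (e - ix + 1L) * dt_ps / 1e3)
    } else {
      s <- ix - 1L
      while (s > 1L && cnt[s - 1L] != resting) s <- s - 1L
      e <- ix
      while (e < N && cnt[e + 1L] != resting) e <- e + 1L
      if (e == N && cnt[N] != resting) {
        set(cond, r, "mechanism", "unclassified")
        next
      }
      set(cond, r, "mechanism", "III-II-III")
      set(cond, r, "intermediate_group", "II")
      set(cond, r, "lifetime_ns", (e - s + 1L) * dt_ps / 1e3)
    }
  }
  cond[]
}

#' Fraction of push (III-IV-III) conductions
#'
#' @param conductions classified `conduction_events`
#' @return list with `n_push`, `n_pull`, `n_unclassified`, `ratio`
#'   (n_push / (n_push + n_pull)) and `percent`
#' @export
mechanism_ratio <- function(conductions) {
  n_push <- sum(conductions$mechanism == "III-IV-III", na.rm = TRUE)
  n_pull <- sum(conductions$mechanism == "III-II-III", na.rm = TRUE)
  n_un <- sum(is.na(conductions$mechanism) |
                conductions$mechanism == "unclassified")
  if (n_push + n_pull == 0L) {
    stop("no classified conductions: mechanism ratio undefined")
  }
  ratio <- n_push / (n_push + n_pull)
  list(n_push = n_push, n_pull = n_pull, n_unclassified = n_un,
       ratio = ratio, percent = 100 * ratio)
}

#' Intermediate-lifetime summaries per mechanism
#'
#' @param conductions classified `conduction_events`
#' @return data.table with one row per mechanism: `n`, `mean_ns`, `q25_ns`,
#'   `median_ns`, `q75_ns`, `max_ns`
#' @export
lifetime_distribution <- function(conductions) {
  cl <- conductions[mechanism %in% c("III-IV-III", "III-II-III") &
                      !is.na(lifetime_ns)]
  if (nrow(cl) == 0L) stop("no classified conductions with lifetimes")
  cl[, .(n = .N, mean_ns = mean(lifetime_ns),
         q25_ns = unname(quantile(lifetime_ns, 0.25)),
         median_ns = unname(quantile(lifetime_ns, 0.5)),
         q75_ns = unname(quantile(lifetime_ns, 0.75)),
         max_ns = max(lifetime_ns)),
     by = mechanism]
}

#' Export conduction events as CSV
#'
#' @param conductions a `conduction_events` table
#' @param path output path
#' @export
write_conduction_events <- function(conductions, path) {
  fwrite(conductions[, .(ion_id, direction, t_enter_ps, t_exit_ps,
                         mechanism, lifetime_ns)], path)
  invisible(path)
}
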