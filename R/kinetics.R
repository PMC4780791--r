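#' Single-channel current from a net permeation count
#'
#' I = n e / T with e the elementary charge. Sign convention: outward
#' conductions are positive, inward negative, so pass
#' `n_outward - n_inward`.
#'
#' @param n_net signed net number of permeation events (outward minus
#'   inward)
#' @param duration_us analysed duration in microseconds
#' @return current in pA
#' @export
permeation_current <- function(n_net, duration_us) {
  if (!is.numeric(duration_us) || duration_us <= 0) {
    stop("duration must be positive")
  }
  n_net * .E_CHARGE * 1e18 / duration_us
}

#' Per-block event counts for bootstrap resampling
#'
#' Partitions the analysed time span into contiguous blocks of
#' `block_size_ps` and counts signed events (outward +1, inward -1) per
#' block.
#'
#' @param times_ps event times (ps), referenced to `t0_ps`
#' @param signs +1 / -1 per event (default all +1)
#' @param duration_ps total analysed span in ps
#' @param block_size_ps block size in ps (100 ps is the conventional
#'   choice for these trajectories)
#' @param t0_ps start of the span
#' @return integer vector of per-block net counts
#' @export
event_block_series <- function(times_ps, signs = NULL, duration_ps,
                               block_size_ps = 100, t0_ps = 0) {
  n_blocks <- floor(duration_ps / block_size_ps)
  if (n_blocks < 2L) stop("block size leaves fewer than 2 blocks")
  if (is.null(signs)) signs <- rep(1, length(times_ps))
  idx <- floor((times_ps - t0_ps) / block_size_ps) + 1L
  keep <- idx >= 1L & idx <= n_blocks
  out <- numeric(n_blocks)
  if (any(keep)) {
    agg <- rowsum(signs[keep], idx[keep])
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

# local block resample: replicate sums of a block series where each block
# position draws uniformly from positions within +/- window of itself
.local_block_boot_sums <- function(series, n_boot, window,
                                   chunk = 5e6L) {
  B <- length(series)
  lo <- pmax(seq_len(B) - window, 1L)
  span <- pmin(seq_len(B) + window, B) - lo + 1L
  sums <- numeric(n_boot)
  done <- 0L
  per_chunk <- max(1L, as.integer(chunk %/% B))
  while (done < n_boot) {
    m <- min(per_chunk, n_boot - done)
    u <- runif(B * m)
    j <- rep(lo, m) + floor(u * rep(span, m))
    sums[done + seq_len(m)] <- colSums(matrix(series[j], nrow = B))
    done <- done + m
  }
  sums
}

#' Local block bootstrap standard error of the current
#'
#' Resamples the per-block event series preserving local time structure:
#' each replicate rebuilds the series by drawing, for every block position,
#' a block uniformly from the positions within `locality_window` blocks of
#' it, then recomputes the current. The SE is the standard deviation of the
#' replicate currents. With a large window this reduces to the ordinary
#' (i.i.d.) block bootstrap.
#'
#' @param series per-block signed event counts ([event_block_series()])
#' @param block_size_ps block size in ps
#' @param n_boot number of bootstrap replicates
#' @param locality_window half-width of the local resampling window, in
#'   blocks
#' @param seed RNG seed (the result is reproducible bit-for-bit)
#' @return standard error of the current, in pA
#' @export
block_bootstrap_se <- function(series, block_size_ps = 100, n_boot = 1e4,
                               locality_window = 10L, seed = 1L) {
  if (length(series) < 2L) stop("need at least 2 blocks")
  duration_us <- length(series) * block_size_ps * 1e-6
  sums <- with_seed(seed,
                    .local_block_boot_sums(series, as.integer(n_boot),
                                           as.integer(locality_window)))
  stats::sd(permeation_current(sums, duration_us))
}

#' Local block bootstrap error of the mechanism ratio
#'
#' Applies the same local block scheme to per-event mechanism labels:
#' blocks carry (push count, classified-event count); each replicate's
#' ratio is the resampled push count over the resampled classified count.
#' Replicates with no classified events are dropped.
#'
#' @param conductions classified `conduction_events`
#' @param duration_ps analysed span in ps
#' @param t0_ps start of the span
#' @inheritParams block_bootstrap_se
#' @return standard error of the push fraction (in [0, 0.5])
#' @export
mechanism_ratio_se <- function(conductions, duration_ps, t0_ps = 0,
                               block_size_ps = 100, n_boot = 1e4,
                               locality_window = 10L, seed = 1L) {
  cl <- conductions[mechanism %in% c("III-IV-III", "III-II-III")]
  if (nrow(cl) == 0L) stop("no classified conductions")
  push <- event_block_series(cl$t_exit_ps,
                             as.numeric(cl$mechanism == "III-IV-III"),
                             duration_ps, block_size_ps, t0_ps)
  tot <- event_block_series(cl$t_exit_ps, rep(1, nrow(cl)),
                            duration_ps, block_size_ps, t0_ps)
  B <- length(tot)
  w <- as.integer(locality_window)
  ratios <- with_seed(seed, {
    lo <- pmax(seq_len(B) - w, 1L)
    span <- pmin(seq_len(B) + w, B) - lo + 1L
    n_boot <- as.integer(n_boot)
    out <- numeric(n_boot)
    for (r in seq_len(n_boot)) {
      j <- lo + floor(runif(B) * span)
      tt <- sum(tot[j])
      out[r] <- if (tt > 0) sum(push[j]) / tt else NA_real_
    }
    out
  })
  stats::sd(ratios[!is.na(ratios)])
}

#' Free-energy difference between two occupancy groups
#'
#' `delta_g(P_a, P_b)` returns G_b - G_a = -R T log(P_b / P_a) in kJ/mol,
#' from the Boltzmann inversion of the occupancy probabilities. A negative
#' value means group b is more stable (more occupied); the conventional
#' report `delta_g(P_II, P_IV)` is therefore negative when the four-ion
#' states dominate the two-ion states.
#'
#' @param P_a,P_b occupancy probabilities (> 0)
#' @param temperature_K temperature in kelvin (default 300, the usual
#'   simulation ensemble temperature; R T = 2.494 kJ/mol there)
#' @return free-energy difference in kJ/mol
#' @export
delta_g <- function(P_a, P_b, temperature_K = 300) {
  if (any(P_a <= 0) || any(P_b <= 0)) {
    stop(paste("zero occupancy probability gives an infinite free-energy",
               "difference; consider flooring occupancies or pooling states"))
  }
  -.R_GAS * temperature_K * log(P_b / P_a)
}

#' Total occupancy of a state group
#'
#' @param graph a grouped `state_graph` (see [group_states()])
#' @param group group tag (`"II"`, `"IIIr"`, `"IIIe"`, `"IV"`, `"V"`);
#'   `"III"` pools IIIr and IIIe
#' @return summed occupancy probability
#' @export
group_occupancy <- function(graph, group) {
  stopifnot(inherits(graph, "state_graph"))
  tags <- if (identical(group, "III")) c("IIIr", "IIIe") else group
  sum(graph$nodes[group %in% tags, occupancy])
}

#' Full per-condition summary
#'
#' Runs the whole analysis on one trajectory: state sequence, grouped
#' graph, conduction detection and classification, current with local
#' block bootstrap SE, mechanism ratio with bootstrap SE, the II-vs-IV
#' free-energy difference, mean pore ion count and mean intermediate
#' lifetimes.
#'
#' @param condition free-text label for the condition
#' @param traj an `ion_trajectory`
#' @param model a `site_model`
#' @param voltage_mV membrane voltage for bookkeeping (NA if unknown)
#' @param resting resting pore ion count
#' @param block_size_ps,n_boot,locality_window,seed bootstrap controls
#' @param temperature_K temperature for [delta_g()]
#' @return a list (JSON-serializable) with counts, current_pA,
#'   current_se_pA, push_ratio, push_ratio_se, deltaG_II_IV_kJmol,
#'   mean_pore_ions, mean lifetimes and the run parameters. Ratio and
#'   delta-G fields are NA (with a `flags` note) when undefined.
#' @export
summarize_condition <- function(condition, traj, model,
                                voltage_mV = NA_real_, resting = 3L,
                                block_size_ps = 100, n_boot = 1e4,
                                locality_window = 10L, seed = 1L,
                                temperature_K = 300) {
  seq <- state_sequence(traj, model)
  graph <- group_states(build_state_graph(seq))
  ev <- boundary_events(seq)
  cond <- classify_mechanisms(detect_conductions(ev, seq), seq,
                              resting = resting)
  n_out <- sum(cond$direction == "outward")
  n_in <- sum(cond$direction == "inward")
  duration_ps <- attr(traj, "duration")
  duration_us <- duration_ps * 1e-6
  t0 <- seq$states$time_ps[1L]

  flags <- character(0L)
  current <- permeation_current(n_out - n_in, duration_us)
  series <- event_block_series(cond$t_exit_ps,
                               fifelse(cond$direction == "outward", 1, -1),
                               duration_ps, block_size_ps, t0)
  current_se <- block_bootstrap_se(series, block_size_ps, n_boot,
                                   locality_window, seed)

  ratio <- tryCatch(mechanism_ratio(cond), error = function(e) NULL)
  if (is.null(ratio)) {
    flags <- c(flags, "no classified conductions: ratio undefined")
    ratio <- list(n_push = 0L, n_pull = 0L,
                  n_unclassified = nrow(cond), ratio = NA_real_)
    ratio_se <- NA_real_
  } else {
    ratio_se <- mechanism_ratio_se(cond, duration_ps, t0, block_size_ps,
                                   n_boot, locality_window, seed)
  }

  p2 <- group_occupancy(graph, "II")
  p4 <- group_occupancy(graph, "IV")
  dg <- if (p2 > 0 && p4 > 0) delta_g(p2, p4, temperature_K) else {
    flags <- c(flags, "group II or IV never occupied: deltaG undefined")
    NA_real_
  }

  lt <- tryCatch(lifetime_distribution(cond), error = function(e) NULL)
  mean_lt <- function(mech) {
    if (is.null(lt) || !mech %in% lt$mechanism) NA_real_
    else lt[mechanism == mech, mean_ns]
  }

  list(condition = condition, voltage_mV = voltage_mV,
       duration_us = duration_us,
       n_outward = n_out, n_inward = n_in,
       n_backrun = attr(cond, "n_backrun"),
       current_pA = current, current_se_pA = current_se,
       n_push = ratio$n_push, n_pull = ratio$n_pull,
       n_unclassified = ratio$n_unclassified,
       push_ratio = ratio$ratio, push_ratio_se = ratio_se,
       deltaG_II_IV_kJmol = dg,
       mean_pore_ions = mean_pore_ions(seq),
       mean_lifetime_push_ns = mean_lt("III-IV-III"),
       mean_lifetime_pull_ns = mean_lt("III-II-III"),
       resting = resting, temperature_K = temperature_K,
       block_size_ps = block_size_ps, n_boot = n_boot,
       locality_window = locality_window, seed = seed,
       flags = flags)
}
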