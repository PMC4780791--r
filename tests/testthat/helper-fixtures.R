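# Constructed trajectories for boundary/classification tests. Site centers
# follow the default site model: S0 14.4, S1 11.2, S2 8.0, S3 4.8, S4 1.6,
# S5 -1.75, S6 -9.75; bulk INTRA -18, bulk EXTRA +18.
Z <- c(S0 = 14.4, S1 = 11.2, S2 = 8.0, S3 = 4.8, S4 = 1.6,
       S5 = -1.75, S6 = -9.75, INTRA = -18, EXTRA = 18)

# build an ion_trajectory from per-ion z vectors (NA = absent at that frame)
traj_from_tracks <- function(tracks, dt = 20) {
  n <- max(vapply(tracks, length, integer(1L)))
  rows <- lapply(seq_along(tracks), function(i) {
    z <- tracks[[i]]
    keep <- !is.na(z)
    data.frame(frame = which(keep) - 1L,
               time_ps = (which(keep) - 1L) * dt,
               ion_id = i, z = z[keep])
  })
  d <- do.call(rbind, rows)
  ion_trajectory(d$frame, d$time_ps, d$ion_id, d$z)
}

# resting pore (K:0:2:4) plus a push cycle: newcomer associates at `t_in`
# frames, resident S0 ion dissociates at `t_out` frames (t_in < t_out)
push_cycle_traj <- function(t_in, t_out, n = 200L, dt = 20) {
  stopifnot(t_in < t_out, t_out < n)
  ion1 <- c(rep(Z["S0"], t_out), Z["EXTRA"], rep(NA, n - t_out - 1L))
  ion4 <- c(rep(NA, t_in - 1L), Z["INTRA"], rep(Z["S6"], n - t_in))
  traj_from_tracks(list(ion1, rep(Z["S2"], n), rep(Z["S4"], n), ion4),
                   dt = dt)
}

# pull cycle: S0 ion dissociates at `t_out` frames, replacement associates
# at `t_in` frames (t_out < t_in)
pull_cycle_traj <- function(t_out, t_in, n = 400L, dt = 20) {
  stopifnot(t_out < t_in, t_in < n)
  ion1 <- c(rep(Z["S0"], t_out), Z["EXTRA"], rep(NA, n - t_out - 1L))
  ion4 <- c(rep(NA, t_in - 1L), Z["INTRA"], rep(Z["S6"], n - t_in))
  traj_from_tracks(list(ion1, rep(Z["S2"], n), rep(Z["S4"], n), ion4),
                   dt = dt)
}
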