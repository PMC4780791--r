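#' Deterministic fixture suite
#'
#' A small set of synthetic trajectories with known ground truth,
#' regenerated bit-identically from `seed`. Each element carries the
#' sampled `trajectory`, the exact event `log` and ground-truth
#' `conductions` (KMC fixtures), or an `expected` list (constructed
#' fixtures):
#' \describe{
#'   \item{push}{push regime (strength 10): conductions dominated by
#'     four-ion intermediates}
#'   \item{pull}{pull regime (strength 10): two-ion intermediates dominate}
#'   \item{mixed}{the baseline model, both mechanisms}
#'   \item{inward}{inward-biased model: extracellular entry, intracellular
#'     exit, negative current}
#'   \item{backrun}{a constructed trajectory in which the S0 ion twice
#'     dissociates to the extracellular fluid and back-runs into the pore:
#'     two same-side pairs, zero conductions}
#' }
#'
#' @param seed base RNG seed
#' @param t_end_ns length of each KMC fixture (ns)
#' @return named list of fixtures
#' @export
fixture_suite <- function(seed = 1L, t_end_ns = 60) {
  inward <- hop_model(bias = -2, k_in_intra = 0.1, k_in_extra = 0.4,
                      k_out_extra = 0.1, k_out_intra = 1)
  list(
    push = simulate_hopping(make_push_regime(10), t_end_ns, seed = seed),
    pull = simulate_hopping(make_pull_regime(10), t_end_ns, seed = seed + 1L),
    mixed = simulate_hopping(hop_model(), t_end_ns, seed = seed + 2L),
    inward = simulate_hopping(inward, t_end_ns, seed = seed + 3L),
    backrun = backrun_fixture()
  )
}

#' Constructed back-running fixture
#'
#' Three ions rest at S0, S2 and S4; the S0 ion leaves to the
#' extracellular bulk for 100 ps twice and returns both times. The
#' trajectory therefore contains two dissoc/assoc same-side pairs and no
#' completed conduction.
#'
#' @param frame_interval_ps frame spacing (ps)
#' @param n_frames number of frames
#' @return list with `trajectory` and `expected` (`n_backrun`,
#'   `n_conductions`)
#' @export
backrun_fixture <- function(frame_interval_ps = 10, n_frames = 400L) {
  away <- c(100:109, 250:259)               # frames the S0 ion spends outside
  frames <- 0:(n_frames - 1L)
  z0 <- ifelse(frames %in% away, 18, 14.4)
  traj <- ion_trajectory(
    frame = rep(frames, 3L),
    time_ps = rep(frames * frame_interval_ps, 3L),
    ion_id = rep(1:3, each = n_frames),
    z = c(z0, rep(8.0, n_frames), rep(1.6, n_frames)))
  list(trajectory = traj,
       expected = list(n_backrun = 2L, n_conductions = 0L))
}
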