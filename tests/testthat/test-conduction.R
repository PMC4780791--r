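sm <- default_site_model()

test_that("boundary crossings generate one ordered event each", {
  # one ion walks INTRA -> S6 -> ... -> S0 -> EXTRA through a full traverse
  path <- c(rep(Z["INTRA"], 5), rep(Z["S6"], 5), rep(Z["S4"], 5),
            rep(Z["S2"], 5), rep(Z["S0"], 5), rep(Z["EXTRA"], 5))
  sq <- state_sequence(traj_from_tracks(list(path)), sm)
  ev <- boundary_events(sq)
  expect_equal(ev$kind, c("assoc_intra", "dissoc_extra"))
  expect_true(all(diff(ev$time_ps) > 0))

  # oscillating across the S0/EXTRA boundary: three dissoc/assoc pairs
  osc <- c(rep(Z["S0"], 5), rep(c(rep(Z["EXTRA"], 3), rep(Z["S0"], 3)), 3))
  ev2 <- boundary_events(state_sequence(traj_from_tracks(list(osc)), sm))
  expect_equal(sum(ev2$kind == "dissoc_extra"), 3L)
  expect_equal(sum(ev2$kind == "assoc_extra"), 3L)
})

test_that("conductions require opposite entry and exit sides", {
  tr <- push_cycle_traj(t_in = 50L, t_out = 100L)
  sq <- state_sequence(tr, sm)
  cond <- detect_conductions(boundary_events(sq), sq)
  expect_equal(nrow(cond), 1L)
  expect_equal(cond$direction, "outward")
  expect_true(cond$initial_resident)        # the S0 ion was seeded

  # back-running: exit EXTRA then re-entry EXTRA cancels the exit
  br <- backrun_fixture()
  sqb <- state_sequence(br$trajectory, sm)
  condb <- detect_conductions(boundary_events(sqb), sqb)
  expect_equal(nrow(condb), br$expected$n_conductions)
  expect_equal(attr(condb, "n_backrun"), br$expected$n_backrun)
})

test_that("constructed push and pull cycles classify with exact lifetimes", {
  # association 1 ns before dissociation: push, 1 ns four-ion intermediate
  tr <- push_cycle_traj(t_in = 50L, t_out = 100L, dt = 20)
  sq <- state_sequence(tr, sm)
  cond <- classify_mechanisms(detect_conductions(boundary_events(sq), sq), sq)
  expect_equal(cond$mechanism, "III-IV-III")
  expect_equal(cond$intermediate_group, "IV")
  expect_equal(cond$lifetime_ns, 1)

  # dissociation, 5 ns two-ion gap, then association: pull
  tr2 <- pull_cycle_traj(t_out = 100L, t_in = 350L, dt = 20)
  sq2 <- state_sequence(tr2, sm)
  cond2 <- classify_mechanisms(detect_conductions(boundary_events(sq2), sq2),
                               sq2)
  expect_equal(cond2$mechanism, "III-II-III")
  expect_equal(cond2$intermediate_group, "II")
  expect_equal(cond2$lifetime_ns, 5)

  # trajectory that ends inside the two-ion intermediate: unclassified
  tr3 <- traj_from_tracks(list(
    c(rep(Z["S0"], 100), Z["EXTRA"], rep(NA, 49)),
    rep(Z["S2"], 150), rep(Z["S4"], 150)))
  sq3 <- state_sequence(tr3, sm)
  cond3 <- classify_mechanisms(detect_conductions(boundary_events(sq3), sq3),
                               sq3)
  expect_equal(cond3$mechanism, "unclassified")
})

test_that("mechanism ratio and lifetime summaries are bookkept correctly", {
  tr <- push_cycle_traj(t_in = 50L, t_out = 100L)
  sq <- state_sequence(tr, sm)
  cond <- classify_mechanisms(detect_conductions(boundary_events(sq), sq), sq)
  r <- mechanism_ratio(cond)
  expect_equal(r$n_push + r$n_pull + r$n_unclassified, nrow(cond))
  expect_equal(r$ratio, 1)

  lt <- lifetime_distribution(cond)
  expect_equal(lt$n, 1L)
  expect_equal(lt$mean_ns, 1)

  none <- cond[0]
  expect_error(mechanism_ratio(none), "undefined|no classified")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_conduction_events(cond, csv)
  expect_equal(data.table::fread(csv)$mechanism, "III-IV-III")
})

test_that("the pipeline recovers the generator's ground truth", {
  sim <- simulate_hopping(hop_model(), t_end_ns = 80, seed = 101)
  sq <- state_sequence(sim$trajectory, sm)
  cond <- classify_mechanisms(detect_conductions(boundary_events(sq), sq), sq)
  gt <- sim$conductions

  expect_equal(nrow(cond), nrow(gt))
  merged <- merge(cond[, .(ion_id, direction, mechanism)],
                  gt[, .(ion_id, direction, gt_mech = mechanism,
                         lifetime = intermediate_lifetime_ns, truncated)],
                  by = c("ion_id", "direction"))
  expect_equal(nrow(merged), nrow(gt))
  cls <- merged[mechanism != "unclassified"]
  expect_gt(nrow(cls), 10L)
  expect_equal(cls$mechanism, cls$gt_mech)
  # abstentions are only allowed where the recovery precondition fails:
  # the cycle was cut by a trajectory edge, or the intermediate was too
  # short for the frame rate (dwell < 5 frame intervals)
  dt_ns <- attr(sim$trajectory, "frame_interval") / 1e3
  un <- merged[mechanism == "unclassified"]
  expect_true(all(un$truncated | un$lifetime < 5 * dt_ns))
})

test_that("classification is stable under two-fold frame subsampling", {
  m <- make_push_regime(10)     # long intermediates, safely resolvable
  fine <- simulate_hopping(m, t_end_ns = 60, seed = 33,
                           frame_interval_ps = 20)
  coarse <- simulate_hopping(m, t_end_ns = 60, seed = 33,
                             frame_interval_ps = 40)
  # identical event log by construction, different sampling
  expect_equal(fine$log, coarse$log)
  cf <- classify_mechanisms(
    detect_conductions(boundary_events(
      state_sequence(fine$trajectory, sm)),
      state_sequence(fine$trajectory, sm)),
    state_sequence(fine$trajectory, sm))
  cc <- classify_mechanisms(
    detect_conductions(boundary_events(
      state_sequence(coarse$trajectory, sm)),
      state_sequence(coarse$trajectory, sm)),
    state_sequence(coarse$trajectory, sm))
  expect_equal(cc[, .(ion_id, direction, mechanism)],
               cf[, .(ion_id, direction, mechanism)])
})

test_that("time reversal swaps direction and preserves the mechanism", {
  sim <- simulate_hopping(make_push_regime(10), t_end_ns = 60, seed = 9)
  tr <- sim$trajectory
  f_max <- max(tr$frame)
  dt <- attr(tr, "frame_interval")
  rev <- ion_trajectory(frame = f_max - tr$frame,
                        time_ps = (f_max - tr$frame) * dt,
                        ion_id = tr$ion_id, z = tr$z)
  fwd_sq <- state_sequence(tr, sm)
  rev_sq <- state_sequence(rev, sm)
  fwd <- classify_mechanisms(
    detect_conductions(boundary_events(fwd_sq), fwd_sq), fwd_sq)
  bwd <- classify_mechanisms(
    detect_conductions(boundary_events(rev_sq), rev_sq), rev_sq)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(sum(bwd$direction == "inward"),
               sum(fwd$direction == "outward"))
  expect_equal(sum(bwd$mechanism == "III-IV-III"),
               sum(fwd$mechanism == "III-IV-III"))
})
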