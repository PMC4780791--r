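sm <- default_site_model()

test_that("binding-state labels are canonical multiset labels", {
  n <- 10L
  tr <- traj_from_tracks(list(rep(Z["S0"], n), rep(Z["S2"], n),
                              rep(Z["S4"], n)))
  sq <- state_sequence(tr, sm)
  expect_equal(unique(sq$states$label), "K:0:2:4")
  expect_equal(unique(sq$states$ion_count), 3L)

  # no pore ions: the empty state
  bulk <- traj_from_tracks(list(rep(Z["INTRA"], n), rep(Z["EXTRA"], n)))
  expect_equal(unique(state_sequence(bulk, sm)$states$label), "K:")

  # two ions in S0 (capacity 2) plus S2, S4, S5: five-ion state
  five <- traj_from_tracks(list(rep(13.5, n), rep(15.2, n), rep(Z["S2"], n),
                                rep(Z["S4"], n), rep(Z["S5"], n)))
  s5 <- state_sequence(five, sm)
  expect_equal(unique(s5$states$label), "K:0:0:2:4:5")
  expect_equal(unique(s5$states$ion_count), 5L)

  # permuting ion identities never changes the labels
  perm <- traj_from_tracks(list(rep(Z["S4"], n), rep(Z["S0"], n),
                                rep(Z["S2"], n)))
  expect_equal(state_sequence(perm, sm)$states$label, sq$states$label)
})

test_that("site-capacity violations raise a diagnostic", {
  n <- 5L
  bad <- traj_from_tracks(list(rep(7.8, n), rep(8.2, n)))  # two ions in S2
  expect_error(state_sequence(bad, sm), "capacity exceeded.*S2")
})

test_that("state graphs count transitions and weight nodes by occupancy", {
  n <- 10L
  const <- state_sequence(traj_from_tracks(list(rep(Z["S2"], n))), sm)
  g <- build_state_graph(const)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$occupancy, 1)
  expect_equal(nrow(g$edges), 0L)

  # A,B,A,B alternation: edges A->B (2) and B->A (1)
  zab <- rep(c(Z["S2"], Z["S3"]), 2)
  sq <- state_sequence(traj_from_tracks(list(zab)), sm)
  g2 <- build_state_graph(sq)
  expect_equal(nrow(g2$nodes), 2L)
  expect_equal(sum(g2$nodes$occupancy), 1)
  ab <- g2$edges[from == "K:2" & to == "K:3", count]
  ba <- g2$edges[from == "K:3" & to == "K:2", count]
  expect_equal(ab, 2L)
  expect_equal(ba, 1L)
  expect_equal(sum(g2$edges$count), 3L)  # number of observed state changes
})

test_that("edge flags follow the crossing ion", {
  tr <- push_cycle_traj(t_in = 50L, t_out = 100L)
  g <- build_state_graph(state_sequence(tr, sm))
  expect_equal(g$edges[flag == "influx", sum(count)], 1L)
  expect_equal(g$edges[flag == "efflux", sum(count)], 1L)
  expect_equal(g$edges[flag %in% c("entry_extra", "exit_intra"), sum(count)],
               0L)
})

test_that("mean pore ion count is the time average", {
  n <- 10L
  three <- state_sequence(traj_from_tracks(list(
    rep(Z["S0"], n), rep(Z["S2"], n), rep(Z["S4"], n))), sm)
  expect_equal(mean_pore_ions(three), 3)

  # half the frames hold 2 ions, half hold 3
  half <- traj_from_tracks(list(
    rep(Z["S0"], n), rep(Z["S2"], n),
    c(rep(Z["S4"], n / 2), rep(Z["INTRA"], n / 2))))
  expect_equal(mean_pore_ions(state_sequence(half, sm)), 2.5)
})

test_that("state grouping tags II/III/IV/V and splits IIIr from IIIe", {
  # hand-built full push cycle with a knock-on shuffle back to rest
  blocks <- list(
    list(t = 100L, z = list(Z["S0"], Z["S2"], Z["S4"], NA)),      # resting
    list(t = 1L,  z = list(Z["S0"], Z["S2"], Z["S4"], Z["INTRA"])),
    list(t = 20L, z = list(Z["S0"], Z["S2"], Z["S4"], Z["S6"])),  # IV
    list(t = 10L, z = list(Z["EXTRA"], Z["S2"], Z["S4"], Z["S6"])),
    list(t = 10L, z = list(NA, Z["S1"], Z["S4"], Z["S6"])),
    list(t = 10L, z = list(NA, Z["S0"], Z["S4"], Z["S6"])),
    list(t = 10L, z = list(NA, Z["S0"], Z["S3"], Z["S6"])),
    list(t = 10L, z = list(NA, Z["S0"], Z["S2"], Z["S6"])),
    list(t = 10L, z = list(NA, Z["S0"], Z["S2"], Z["S5"])),
    list(t = 120L, z = list(NA, Z["S0"], Z["S2"], Z["S4"])))       # resting
  tracks <- lapply(1:4, function(i) {
    unlist(lapply(blocks, function(b) rep(b$z[[i]], b$t)))
  })
  sq <- state_sequence(traj_from_tracks(tracks), sm)
  g <- group_states(build_state_graph(sq))
  tag <- function(lbl) g$nodes[label == lbl, group]
  expect_equal(tag("K:0:2:4"), "IIIr")
  expect_equal(tag("K:0:2:4:6"), "IV")
  for (lbl in c("K:2:4:6", "K:1:4:6", "K:0:4:6", "K:0:3:6", "K:0:2:6",
                "K:0:2:5")) {
    expect_equal(tag(lbl), "IIIe")
  }
  # grouping partitions the nodes
  expect_false(any(is.na(g$nodes$group)))

  n <- 10L
  two <- traj_from_tracks(list(rep(Z["S0"], n), rep(Z["S2"], n)))
  g2 <- group_states(build_state_graph(state_sequence(two, sm)))
  expect_equal(g2$nodes$group, "II")

  five <- traj_from_tracks(list(rep(13.5, n), rep(15.2, n), rep(Z["S2"], n),
                                rep(Z["S4"], n), rep(Z["S6"], n)))
  g5 <- group_states(build_state_graph(state_sequence(five, sm)))
  expect_equal(g5$nodes$group, "V")
})

test_that("debouncing removes sub-dwell flicker but keeps assignments", {
  n <- 30L
  z <- rep(Z["S2"], n)
  z[15] <- Z["S3"]                       # one-frame flicker across S2/S3
  sq <- state_sequence(traj_from_tracks(list(z)), sm)
  expect_equal(uniqueN(sq$states$label), 2L)
  sm2 <- debounce_states(sq, min_frames = 2L)
  expect_equal(unique(sm2$states$label), "K:2")
  expect_equal(unique(sm2$states$ion_count), 1L)
  expect_identical(sm2$assignments, sq$assignments)
  expect_equal(nrow(build_state_graph(sm2)$edges), 0L)
})

test_that("graph exports round-trip through GraphML and DOT", {
  tr <- push_cycle_traj(t_in = 50L, t_out = 100L)
  g <- group_states(build_state_graph(state_sequence(tr, sm)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_state_graph(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, g$nodes$label)
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(sum(igraph::E(back)$count), sum(g$edges$count))

  dot <- withr::local_tempfile(fileext = ".dot")
  write_state_graph(g, dot, "dot")
  expect_true(any(grepl("->", readLines(dot), fixed = TRUE)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  sq <- state_sequence(tr, sm)
  write_state_sequence(sq, tsv)
  expect_equal(nrow(data.table::fread(tsv)), nrow(sq$states))
})
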