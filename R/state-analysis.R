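#' Per-frame ion-binding states
#'
#' Assigns every ion observation to a region of the site model and collapses
#' each frame into a canonical binding-state label: `"K:"` followed by the
#' colon-joined, sorted indices of occupied sites with multiplicity
#' (`K:0:2:4` for ions at S0, S2 and S4; `K:0:0:2:4` for two ions at S0).
#' Ions in the bulk regions (INTRA/EXTRA) are excluded from the label, and a
#' frame with no pore ions is the empty state `K:`.
#'
#' Frames are taken as the full contiguous range between the first and last
#' observed frame; frames with no listed ions are empty states.
#'
#' @param traj an `ion_trajectory`
#' @param model a `site_model`
#' @return a `state_sequence`: list with
#'   \item{states}{data.table `frame`, `time_ps`, `label`, `ion_count`
#'     (pore ions only), one row per frame}
#'   \item{assignments}{data.table `frame`, `time_ps`, `ion_id`, `z`,
#'     `region`, `site` (0--6 for S0--S6, NA in bulk), every observation}
#'   \item{model, frame_interval}{the inputs used}
#' @export
state_sequence <- function(traj, model) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(model, "site_model"))
  dt <- as.data.table(traj)
  interval <- attr(traj, "frame_interval")
  asn <- copy(dt)
  asn[, region := assign_site(z, model)]
  asn[, site := .site_index(region)]

  pore <- asn[!is.na(site)]
  occ <- pore[, .N, by = .(frame, site)]
  cap <- model$capacity[paste0("S", occ$site)]
  over <- occ[occ$N > cap]
  if (nrow(over) > 0L) {
    stop(sprintf(
      "site capacity exceeded at frame %d: %d ions in S%d (capacity %d)",
      over$frame[1L], over$N[1L], over$site[1L],
      model$capacity[[paste0("S", over$site[1L])]]))
  }

  frames <- seq(min(dt$frame), max(dt$frame))
  t0 <- dt$time_ps[match(min(dt$frame), dt$frame)]
  times <- t0 + (frames - frames[1L]) * if (is.na(interval)) 0 else interval
  lab <- pore[order(frame, site),
              .(label = paste0("K:", paste(site, collapse = ":")),
                ion_count = .N),
              by = frame]
  states <- data.table(frame = frames, time_ps = times)
  states[lab, `:=`(label = i.label, ion_count = i.ion_count), on = "frame"]
  states[is.na(label), `:=`(label = "K:", ion_count = 0L)]

  structure(list(states = states[], assignments = asn[],
                 model = model, frame_interval = interval),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  top <- x$states[, .N, by = label][order(-N)][1L]
  cat(sprintf(
    "<state_sequence> %d frames, %d distinct states, modal %s (%.1f%%)\n",
    nrow(x$states), uniqueN(x$states$label),
    top$label, 100 * top$N / nrow(x$states)))
  invisible(x)
}

#' Mean number of pore ions
#'
#' Time-average of the per-frame pore ion count.
#'
#' @param seq a `state_sequence`
#' @return a single number
#' @export
mean_pore_ions <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  mean(seq$states$ion_count)
}

#' Suppress threshold-crossing flicker in a state sequence
#'
#' Replaces every run of identical state labels shorter than `min_frames`
#' with the preceding persistent state. Flicker at a site boundary (an ion
#' jittering across a threshold) inflates transition counts in the graph;
#' this filter is a reporting aid only -- boundary-event detection and
#' mechanism classification always use the raw per-frame assignments, so
#' debouncing never changes conduction counts.
#'
#' @param seq a `state_sequence`
#' @param min_frames minimum dwell, in frames, for a state visit to stand
#' @return a `state_sequence` with smoothed `states` (assignments untouched)
#' @export
debounce_states <- function(seq, min_frames = 2L) {
  stopifnot(inherits(seq, "state_sequence"), min_frames >= 1L)
  st <- copy(seq$states)
  r <- rle(st$label)
  lab <- r$values
  for (k in seq_along(lab)) {
    if (r$lengths[k] < min_frames && k > 1L) lab[k] <- lab[k - 1L]
  }
  st[, label := rep(lab, r$lengths)]
  st[, ion_count := vapply(strsplit(label, ":", fixed = TRUE), function(x) {
    sum(x != "" & x != "K")
  }, integer(1L))]
  out <- seq
  out$states <- st[]
  out
}

#' State-transition graph
#'
#' One node per distinct binding state, weighted by the fraction of frames
#' spent in it; one directed edge per observed frame-to-frame state change,
#' annotated with a boundary flag derived from ion-identity bookkeeping:
#' `influx` (a new ion entered the pore from the intracellular fluid),
#' `efflux` (an ion detached from S0 into the extracellular fluid),
#' `entry_extra` / `exit_intra` (the mirrored crossings used for inward
#' conduction), or `internal` (ions rearranged inside the pore). A
#' transition in which crossings occur on both boundaries within one frame
#' interval is flagged `internal` with a warning (ambiguous ordering).
#'
#' @param seq a `state_sequence`
#' @return a `state_graph`: list with `nodes` (data.table `label`,
#'   `occupancy`, `ion_count`, `group`), `edges` (data.table `from`, `to`,
#'   `flag`, `count`) and the originating `seq`
#' @export
build_state_graph <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  st <- seq$states
  nodes <- st[, .(occupancy = .N / nrow(st),
                  ion_count = ion_count[1L]), by = label]
  setorder(nodes, -occupancy)
  nodes[, group := NA_character_]

  changed <- which(st$label[-1L] != st$label[-nrow(st)])
  if (length(changed) > 0L) {
    steps <- .boundary_steps(seq)
    n_amb <- 0L
    flags <- vapply(changed, function(i) {
      ev <- steps[frame == st$frame[i + 1L]]
      if (nrow(ev) == 0L) return("internal")
      if (nrow(ev) > 1L) {
        n_amb <<- n_amb + 1L
        return("internal")
      }
      switch(ev$kind,
             assoc_intra = "influx", dissoc_extra = "efflux",
             assoc_extra = "entry_extra", dissoc_intra = "exit_intra")
    }, character(1L))
    if (n_amb > 0L) {
      warning(sprintf(
        "%d transition(s) with crossings on both pore boundaries within one frame interval; flagged internal",
        n_amb))
    }
    edges <- data.table(from = st$label[changed],
                        to = st$label[changed + 1L],
                        flag = flags)[, .(count = .N), by = .(from, to, flag)]
  } else {
    edges <- data.table(from = character(), to = character(),
                        flag = character(), count = integer())
  }
  structure(list(nodes = nodes[], edges = edges[], seq = seq),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("<state_graph> %d states, %d edges (%d transitions)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' Group binding states (II, IIIr, IIIe, IV, V)
#'
#' Tags every node with its mechanistic group: two-ion states are `II`,
#' four-ion states `IV`, states with five or more ions `V`. Three-ion
#' states split temporally around the resting state (the modal three-ion
#' state): frames visited between completing a conduction cycle's second
#' boundary crossing and first regaining the resting state vote `IIIe`
#' ("entrance"), all other three-ion frames vote `IIIr` ("resting"); each
#' state takes its majority tag. States with fewer than two ions are tagged
#' `other`. Mechanism counting never uses these tags (it uses event
#' ordering); they describe the graph the way the landscape is usually
#' drawn.
#'
#' @param graph a `state_graph`
#' @return the graph with `nodes$group` filled in
#' @export
group_states <- function(graph) {
  stopifnot(inherits(graph, "state_graph"))
  nodes <- copy(graph$nodes)
  nodes[, group := fifelse(ion_count == 2L, "II",
                   fifelse(ion_count == 4L, "IV",
                   fifelse(ion_count >= 5L, "V",
                   fifelse(ion_count == 3L, "III", "other"))))]

  three <- nodes[group == "III", label]
  if (length(three) > 0L) {
    resting <- nodes[group == "III"][which.max(occupancy), label]
    votes <- .third_group_votes(graph$seq, resting)
    nodes[group == "III",
          group := fifelse(label == resting, "IIIr",
                   fifelse(label %in% votes$e_major, "IIIe", "IIIr"))]
  }
  out <- graph
  out$nodes <- nodes[]
  out
}

# For each maximal run of 3-ion frames, frames before the first visit to the
# resting state vote IIIe when the preceding off-resting excursion contained
# a conduction-advancing pair of boundary crossings (association on one side
# and dissociation on the other); otherwise the whole run votes IIIr.
# Returns the labels whose IIIe votes outnumber their IIIr votes.
.third_group_votes <- function(seq, resting_label) {
  st <- seq$states
  steps <- .boundary_steps(seq)
  cnt3 <- st$ion_count == 3L
  r <- rle(cnt3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  e_votes <- r_votes <- character(0L)
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    is_e_prefix <- FALSE
    if (k > 1L) {
      exc <- starts[k - 1L]:ends[k - 1L]
      ev <- steps[frame %in% st$frame[c(exc, run[1L])]]
      has_assoc_i <- any(ev$kind == "assoc_intra")
      has_assoc_e <- any(ev$kind == "assoc_extra")
      has_dissoc_i <- any(ev$kind == "dissoc_intra")
      has_dissoc_e <- any(ev$kind == "dissoc_extra")
      is_e_prefix <- (has_assoc_i && has_dissoc_e) ||
                     (has_assoc_e && has_dissoc_i)
    }
    hit <- match(resting_label, st$label[run])
    if (is_e_prefix && (is.na(hit) || hit > 1L)) {
      upto <- if (is.na(hit)) length(run) else hit - 1L
      e_votes <- c(e_votes, st$label[run[seq_len(upto)]])
      if (!is.na(hit)) {
        r_votes <- c(r_votes, st$label[run[hit:length(run)]])
      }
    } else {
      r_votes <- c(r_votes, st$label[run])
    }
  }
  e_tab <- table(e_votes)
  r_tab <- table(r_votes)
  labs <- union(names(e_tab), names(r_tab))
  ev <- as.numeric(e_tab[labs]); ev[is.na(ev)] <- 0
  rv <- as.numeric(r_tab[labs]); rv[is.na(rv)] <- 0
  list(e_major = labs[ev > rv])
}

#' Export a state sequence as TSV
#'
#' Columns `frame`, `time_ps`, `label`, `ion_count`.
#'
#' @param seq a `state_sequence`
#' @param path output path
#' @export
write_state_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "state_sequence"))
  fwrite(seq$states, path, sep = "\t")
  invisible(path)
}

#' Convert a state graph to igraph
#'
#' Node attributes: `label` (state), `occupancy`, `ion_count`, `group`;
#' edge attributes: `count`, `flag`. Parallel edges with different flags are
#' kept distinct.
#'
#' @param graph a `state_graph`
#' @return an [igraph::graph] object
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "state_graph"))
  nodes <- graph$nodes
  vertices <- data.frame(name = nodes$label, occupancy = nodes$occupancy,
                         ion_count = nodes$ion_count,
                         group = ifelse(is.na(nodes$group), "", nodes$group))
  edges <- graph$edges
  igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to,
               count = edges$count, flag = edges$flag),
    directed = TRUE, vertices = vertices)
}

#' Write a state graph to GraphML or DOT
#'
#' @param graph a `state_graph`
#' @param path output path
#' @param format `"graphml"` or `"dot"`
#' @export
write_state_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph), path, format = format)
  invisible(path)
}
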