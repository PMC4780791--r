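# Independent oracles. These re-derive expected values by routes that do not
# touch the package's implementation paths: exhaustive enumeration plus a
# linear solve for the hopping chain, and closed forms elsewhere.

# Stationary distribution of a hop_model by master equation: enumerate the
# occupancy configurations reachable from the seeded one, build the rate
# matrix from an independent coding of the rate rules, and solve pi Q = 0.
oracle_stationary <- function(m) {
  cap <- unname(m$capacity)            # S0..S6
  r <- m$repulsion_range
  half <- m$bias / 2
  ok <- function(occ, to, from = NA) {
    if (occ[to] >= cap[to]) return(FALSE)
    if (r > 0L) {
      for (j in max(1L, to - r):min(7L, to + r)) {
        if (j != to && (is.na(from) || j != from) && occ[j] > 0L) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  moves <- function(occ) {
    crowd <- exp(m$crowding * (sum(occ) - m$crowding_ref))
    out <- list()
    for (i in 1:7) {
      if (occ[i] == 0L) next
      esc <- m$k0 * exp(-unname(m$depths)[i])
      if (i > 1L && ok(occ, i - 1L, i)) {
        nxt <- occ; nxt[i] <- nxt[i] - 1L; nxt[i - 1L] <- nxt[i - 1L] + 1L
        out[[length(out) + 1L]] <- list(occ = nxt, rate = esc * exp(half))
      }
      if (i < 7L && ok(occ, i + 1L, i)) {
        nxt <- occ; nxt[i] <- nxt[i] - 1L; nxt[i + 1L] <- nxt[i + 1L] + 1L
        out[[length(out) + 1L]] <- list(occ = nxt, rate = esc * exp(-half))
      }
      if (i == 1L) {
        nxt <- occ; nxt[1L] <- nxt[1L] - 1L
        out[[length(out) + 1L]] <- list(
          occ = nxt,
          rate = m$k_out_extra * exp(-unname(m$depths)[1L]) * exp(half) *
            crowd)
      }
      if (i == 7L) {
        nxt <- occ; nxt[7L] <- nxt[7L] - 1L
        out[[length(out) + 1L]] <- list(
          occ = nxt,
          rate = m$k_out_intra * exp(-unname(m$depths)[7L]) * exp(-half) *
            crowd)
      }
    }
    if (ok(occ, 7L)) {
      nxt <- occ; nxt[7L] <- nxt[7L] + 1L
      out[[length(out) + 1L]] <- list(occ = nxt,
                                      rate = m$k_in_intra * exp(half))
    }
    if (ok(occ, 1L)) {
      nxt <- occ; nxt[1L] <- nxt[1L] + 1L
      out[[length(out) + 1L]] <- list(occ = nxt,
                                      rate = m$k_in_extra * exp(-half))
    }
    out
  }
  key <- function(occ) paste(occ, collapse = "")
  occ0 <- integer(7L)
  for (s in m$init_sites) occ0[s + 1L] <- occ0[s + 1L] + 1L
  # breadth-first closure of the reachable configuration space
  states <- list(occ0)
  names(states) <- key(occ0)
  queue <- list(occ0)
  edges <- list()
  while (length(queue) > 0L) {
    occ <- queue[[1L]]; queue <- queue[-1L]
    for (mv in moves(occ)) {
      k <- key(mv$occ)
      if (is.null(states[[k]])) {
        states[[k]] <- mv$occ
        queue[[length(queue) + 1L]] <- mv$occ
      }
      edges[[length(edges) + 1L]] <- list(from = key(occ), to = k,
                                          rate = mv$rate)
    }
  }
  n <- length(states)
  idx <- stats::setNames(seq_len(n), names(states))
  Q <- matrix(0, n, n)
  for (e in edges) {
    Q[idx[[e$from]], idx[[e$to]]] <- Q[idx[[e$from]], idx[[e$to]]] + e$rate
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q)
  A[n, ] <- 1                               # replace one balance eq by sum=1
  b <- c(rep(0, n - 1L), 1)
  pi <- solve(A, b)
  cfg <- do.call(rbind, unname(states))
  label <- apply(cfg, 1L, function(occ) {
    paste0("K:", paste(rep(0:6, occ), collapse = ":"))
  })
  list(pi = stats::setNames(pi, names(states)),
       configs = cfg,
       label_prob = tapply(pi, label, sum),
       p_site = as.numeric(t(cfg > 0) %*% pi),   # P(site occupied), S0..S6
       mean_ions = sum(rowSums(cfg) * pi))
}

# brute-force scalar projection of points onto a unit axis
oracle_project <- function(p, origin, u) {
  vapply(seq_len(nrow(p)), function(i) {
    sum((as.numeric(p[i, ]) - origin) * u)
  }, numeric(1L))
}

# linear-scan region assignment over half-open intervals
oracle_assign <- function(z, thresholds) {
  regions <- c("INTRA", paste0("S", 6:0), "EXTRA")
  vapply(z, function(zz) {
    k <- 1L
    for (t in thresholds) if (zz >= t) k <- k + 1L else break
    regions[k]
  }, character(1L))
}
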