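# shared fixture builders (all programmatic; no stored data)

# quick sweep from a sample vector
mk_sweep <- function(v, rate = 10, amp = 0, onset = 0, dur = NULL,
                     isi = NA) {
  if (is.null(dur)) dur <- length(v) / rate - onset
  voltage_sweep(v, rate, step_protocol(amp, onset, dur, isi))
}

# analytic passive RC step response: the independent closed-form oracle
rc_sweep <- function(amp_pA, r_MOhm = 140, tau_ms = 22, rmp = -70,
                     rate = 10, onset = 50, dur = 500, pad = 50,
                     noise_sd = 0) {
  n <- round((onset + dur + pad) * rate)
  t <- (seq_len(n) - 1) / rate
  dv <- r_MOhm * amp_pA / 1000  # MOhm * pA -> mV via /1000
  v <- rep(rmp, n)
  on <- t >= onset & t < onset + dur
  v[on] <- rmp + dv * (1 - exp(-(t[on] - onset) / tau_ms))
  off <- t >= onset + dur
  v_end <- rmp + dv * (1 - exp(-dur / tau_ms))
  v[off] <- rmp + (v_end - rmp) * exp(-(t[off] - onset - dur) / tau_ms)
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  mk_sweep(v, rate, amp_pA, onset, dur)
}

# minimal valid trace bundle built from analytic RC responses
mk_bundle <- function(r_MOhm = 140, tau_ms = 22, rmp = -70, rate = 10,
                      rest_s = 1, rs = 10, noise_sd = 0,
                      long_amps = seq(-100, 40, by = 20), cell_id = "c1",
                      meta = NULL) {
  rest <- mk_sweep(rep(rmp, rest_s * 1000 * rate) +
                     if (noise_sd > 0) rnorm(rest_s * 1000 * rate, 0, noise_sd) else 0,
                   rate, 0, 0, rest_s * 1000)
  short <- lapply(seq(10, 30, 10), function(a)
    rc_sweep(a, r_MOhm, tau_ms, rmp, rate, onset = 10, dur = 50, pad = 40,
             noise_sd = noise_sd))
  long <- lapply(long_amps, function(a)
    rc_sweep(a, r_MOhm, tau_ms, rmp, rate, noise_sd = noise_sd))
  trace_bundle(cell_id, rest, short, long, rs, meta = meta)
}

# config accepting the miniature rest traces above
mini_config <- function(...) feature_config(rest_min_duration_s = 1, ...)

# sweep with rectangular +20 mV pulses (1 ms) at given times: a spike-train
# carrier whose 0-mV upward crossings are exactly at the pulse onsets
pulse_sweep <- function(times_ms, rate = 20, total_ms = 700, onset = 100,
                        dur = 500, amp = 200, width_ms = 1) {
  n <- round(total_ms * rate)
  v <- rep(-70, n)
  for (t0 in times_ms) {
    i0 <- round(t0 * rate) + 1L
    i1 <- min(n, i0 + round(width_ms * rate) - 1L)
    v[i0:i1] <- 20
  }
  mk_sweep(v, rate, amp, onset, dur)
}

# node-table helpers for hand-built trees --------------------------------

swc_row <- function(id, type, x, y, z, radius, parent)
  data.frame(id = id, type = type, x = x, y = y, z = z, radius = radius,
             parent = parent)

# soma at origin + single straight basal dendrite of given length along x
straight_tree <- function(length_um = 100, n_inner = 1, type = 3) {
  xs <- seq(0, length_um, length.out = n_inner + 2)[-1]
  rows <- list(swc_row(1, 1, 0, 0, 0, 6, -1))
  for (i in seq_along(xs))
    rows[[i + 1]] <- swc_row(i + 1, type, xs[i], 0, 0, 0.5, i)
  neuron_tree(do.call(rbind, rows))
}

# Y-tree: stem along x to (stem_um, 0), two branches to x = tip_x
y_tree <- function(stem_um = 15, tip_x = 35, spread = 6) {
  neuron_tree(rbind(
    swc_row(1, 1, 0, 0, 0, 6, -1),
    swc_row(2, 3, stem_um, 0, 0, 0.5, 1),
    swc_row(3, 3, tip_x, spread, 0, 0.5, 2),
    swc_row(4, 3, tip_x, -spread, 0, 0.5, 2)))
}

# dense-resampling Sholl oracle (0.1 um steps by default)
sholl_oracle <- function(tree, arbor = "basal", interval = 10,
                         step_um = 0.1, mode = "3d") {
  nodes <- tree$nodes
  codes <- switch(arbor, basal = 3, apical = 4, all = c(3, 4))
  root <- nodes[nodes$parent == -1, ]
  center <- c(root$x, root$y, root$z)
  dims <- if (mode == "2d") 1:2 else 1:3
  pts <- cbind(nodes$x - center[1], nodes$y - center[2],
               nodes$z - center[3])[, dims, drop = FALSE]
  idx_of <- match(nodes$parent, nodes$id)
  edges <- which(nodes$type %in% codes & !is.na(idx_of))
  r_node <- sqrt(rowSums(pts^2))
  r_max <- max(r_node[c(edges, idx_of[edges])])
  n_ring <- max(1L, ceiling(r_max / interval - 1e-9))
  radii <- interval * seq_len(n_ring)
  crossings <- numeric(n_ring)
  shell <- numeric(n_ring)
  for (e in edges) {
    a <- pts[idx_of[e], ]; b <- pts[e, ]
    L <- sqrt(sum((b - a)^2))
    if (L < 1e-12) next
    m <- max(2L, ceiling(L / step_um) + 1L)
    tt <- seq(0, 1, length.out = m)
    d <- sqrt(colSums((outer(a, rep(1, m)) + outer(b - a, tt))^2))
    for (k in seq_len(n_ring)) {
      s <- d - radii[k]
      crossings[k] <- crossings[k] +
        sum(s[-1] * s[-m] < 0) + sum(s[-1] == 0)
    }
    mid <- (d[-1] + d[-m]) / 2
    bin <- pmin(n_ring, floor(mid / interval) + 1L)
    piece <- L / (m - 1)
    for (k in unique(bin)) shell[k] <- shell[k] + piece * sum(bin == k)
  }
  list(ring_radii_um = radii, intersections = crossings,
       length_per_shell_um = shell)
}
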