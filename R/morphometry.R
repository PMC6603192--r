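# SWC structure-type codes for arbor selection
arbor_codes <- function(arbor = c("basal", "apical", "all", "axon")) {
  switch(match.arg(arbor), basal = 3, apical = 4, axon = 2, all = c(3, 4))
}

# Segment decomposition of one arbor under centrifugal ordering.
#
# A segment is a maximal unbranched chain of arbor nodes; segments leaving
# the soma have order 1 and the order increments by one at every branch
# point moving tipward.  The edge connecting a stem to its soma parent is
# part of the stem segment, so segment lengths sum to the arbor total.
arbor_segments <- function(tree, arbor = "basal") {
  nodes <- tree$nodes
  codes <- arbor_codes(arbor)
  in_arbor <- nodes$type %in% codes
  if (!any(in_arbor)) return(NULL)
  idx_of <- match(nodes$parent, nodes$id)       # row index of parent
  children <- vector("list", nrow(nodes))
  for (i in which(in_arbor)) {
    p <- idx_of[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  n_children <- lengths(children)
  edge_len <- function(i) {
    p <- idx_of[i]
    sqrt((nodes$x[i] - nodes$x[p])^2 + (nodes$y[i] - nodes$y[p])^2 +
           (nodes$z[i] - nodes$z[p])^2)
  }
  # heads: arbor nodes whose parent is outside the arbor (stem) or is a
  # branch point within the arbor
  is_soma_parent <- !is.na(idx_of) & !(nodes$type[idx_of] %in% codes)
  heads <- which(in_arbor & (is_soma_parent | is.na(idx_of) |
                               (!is_soma_parent & n_children[idx_of] >= 2)))
  segs <- lapply(heads, function(h) {
    len <- if (!is.na(idx_of[h])) edge_len(h) else 0
    i <- h
    while (n_children[i] == 1L) {
      i <- children[[i]][1]
      len <- len + edge_len(i)
    }
    list(head = nodes$id[h], tail = nodes$id[i], head_row = h, tail_row = i,
         length_um = len, terminal = n_children[i] == 0L)
  })
  # centrifugal order by walking from stems outward
  order_of <- setNames(rep(NA_real_, length(segs)),
                       vapply(segs, function(s) s$head, numeric(1)))
  head_rows <- vapply(segs, function(s) s$head_row, numeric(1))
  tail_rows <- vapply(segs, function(s) s$tail_row, numeric(1))
  stem <- vapply(segs, function(s)
    is.na(idx_of[s$head_row]) || !(nodes$type[idx_of[s$head_row]] %in% codes),
    logical(1))
  ord <- rep(NA_integer_, length(segs))
  ord[stem] <- 1L
  repeat {
    todo <- which(is.na(ord))
    if (!length(todo)) break
    progressed <- FALSE
    for (k in todo) {
      parent_seg <- which(tail_rows == idx_of[head_rows[k]])
      if (length(parent_seg) == 1L && !is.na(ord[parent_seg])) {
        ord[k] <- ord[parent_seg] + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("disconnected arbor segments", call. = FALSE)
  }
  data.frame(head = vapply(segs, `[[`, numeric(1), "head"),
             tail = vapply(segs, `[[`, numeric(1), "tail"),
             order = ord,
             length_um = vapply(segs, `[[`, numeric(1), "length_um"),
             terminal = vapply(segs, `[[`, logical(1), "terminal"),
             stem = stem)
}

#' Centrifugal branch orders
#'
#' Decomposes an arbor into unbranched segments and assigns centrifugal
#' orders: segments leaving the soma are order 1 and the order increments
#' by one at every branch point moving tipward.
#'
#' @param tree a [neuron_tree()]
#' @param arbor `"basal"`, `"apical"`, `"axon"` or `"all"`
#' @return data frame with one row per segment: `head`/`tail` node ids,
#'   `order`, `length_um`, `terminal`, `stem`
#' @export
branch_orders <- function(tree, arbor = "basal") {
  stopifnot(inherits(tree, "neuron_tree"))
  segs <- arbor_segments(tree, arbor)
  if (is.null(segs)) stop("arbor '", arbor, "' is empty", call. = FALSE)
  segs
}

#' Arbor summary statistics
#'
#' Counts of primary dendrites (stems leaving the soma), branch points and
#' terminal tips, total dendritic length (sum of all branch lengths, each
#' the sum of Euclidean distances between consecutive nodes) and mean
#' length (total divided by the number of primary dendrites).
#'
#' @param tree a [neuron_tree()]
#' @param arbor arbor selector, see [branch_orders()]
#' @return list of class `arbor_summary` with `n_primary`, `n_nodes`,
#'   `n_ends`, `total_length_um`, `mean_length_um`, `terminal_orders`
#' @export
arbor_summary <- function(tree, arbor = "basal") {
  segs <- branch_orders(tree, arbor)
  n_primary <- sum(segs$stem)
  n_ends <- sum(segs$terminal)
  structure(list(
    n_primary = n_primary,
    n_nodes = sum(!segs$terminal),  # every non-terminal segment ends in a branch point
    n_ends = n_ends,
    total_length_um = sum(segs$length_um),
    mean_length_um = sum(segs$length_um) / n_primary,
    terminal_orders = segs$order[segs$terminal]),
    class = "arbor_summary")
}

#' Dendritic complexity index
#'
#' `(sum of terminal orders + number of terminals) *
#' (total dendritic length / number of primary dendrites)` -- a
#' dimensionless index combining topological depth with arbor size,
#' homogeneous of degree one in length.
#'
#' @param tree a [neuron_tree()]
#' @param arbor arbor selector
#' @return complexity index
#' @export
complexity <- function(tree, arbor = "basal") {
  s <- arbor_summary(tree, arbor)
  if (s$n_primary == 0)
    stop("complexity undefined: no primary dendrites", call. = FALSE)
  (sum(s$terminal_orders) + s$n_ends) * (s$total_length_um / s$n_primary)
}

#' Soma area
#'
#' Shoelace polygon area of the traced 2D soma contour when present;
#' otherwise falls back to `pi * r^2` of the root soma radius, flagged via
#' the `"provenance"` attribute (`"contour"` or `"radius"`).
#'
#' @param tree a [neuron_tree()]
#' @return area in square micrometres
#' @export
soma_area <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  ct <- tree$soma_contour
  if (!is.null(ct) && nrow(ct) >= 3) {
    x <- ct$x; y <- ct$y
    j <- c(seq_len(nrow(ct))[-1], 1L)
    a <- abs(sum(x * y[j] - x[j] * y)) / 2
    return(structure(a, provenance = "contour"))
  }
  root <- tree$nodes[tree$nodes$parent == -1, ]
  structure(pi * root$radius^2, provenance = "radius")
}

#' Sholl analysis
#'
#' Exact segment--sphere Sholl profile around the soma: for concentric
#' spheres (or circles in 2D mode) at `interval_um` increments out to the
#' maximal tip radius, counts the exact number of dendrite crossings of
#' each sphere and accumulates dendritic length into the radial shells
#' bounded by consecutive spheres.  Crossing points along every straight
#' edge are found from the quadratic radial parametrization, so re-entrant
#' dendrites count once per crossing and shell lengths sum exactly to the
#' arbor total length.
#'
#' @param tree a [neuron_tree()]
#' @param arbor arbor selector, see [branch_orders()]
#' @param interval_um ring spacing, default 10
#' @param center sphere center; default the root soma node position
#' @param mode `"3d"` (spheres, default) or `"2d"` (circles on the x-y
#'   projection)
#' @return list of class `sholl_profile` with `ring_radii_um`,
#'   `intersections` (per ring), `length_per_shell_um` (shell with outer
#'   radius `ring_radii_um[i]`), `interval_um`
#' @export
sholl <- function(tree, arbor = "basal", interval_um = 10, center = NULL,
                  mode = c("3d", "2d")) {
  stopifnot(inherits(tree, "neuron_tree"))
  mode <- match.arg(mode)
  nodes <- tree$nodes
  codes <- arbor_codes(arbor)
  if (is.null(center)) {
    root <- nodes[nodes$parent == -1, ]
    center <- c(root$x, root$y, root$z)
  }
  dims <- if (mode == "2d") 1:2 else 1:3
  pts <- cbind(nodes$x - center[1], nodes$y - center[2],
               nodes$z - center[3])[, dims, drop = FALSE]
  idx_of <- match(nodes$parent, nodes$id)
  edges <- which(nodes$type %in% codes & !is.na(idx_of))
  if (!length(edges)) stop("arbor '", arbor, "' is empty", call. = FALSE)

  r_node <- sqrt(rowSums(pts^2))
  r_max <- max(r_node[edges], r_node[idx_of[edges]])
  n_ring <- max(1L, ceiling(r_max / interval_um - 1e-9))
  radii <- interval_um * seq_len(n_ring)

  crossings <- numeric(n_ring)
  shell_len <- numeric(n_ring)
  for (e in edges) {
    a <- pts[idx_of[e], ]
    b <- pts[e, ]
    v <- b - a
    vv <- sum(v * v)
    L <- sqrt(vv)
    av <- sum(a * v)
    aa <- sum(a * a)
    if (L < 1e-12) next
    # crossing parameters for every ring radius
    ts <- c(0, 1)
    for (k in seq_len(n_ring)) {
      disc <- av^2 - vv * (aa - radii[k]^2)
      if (disc <= 0) next
      sq <- sqrt(disc)
      for (t in c((-av - sq) / vv, (-av + sq) / vv)) {
        if (t > 1e-12 && t <= 1 + 1e-12) {
          crossings[k] <- crossings[k] + 1
          if (t < 1 - 1e-12) ts <- c(ts, t)
        }
      }
    }
    ts <- sort(unique(ts))
    for (j in seq_len(length(ts) - 1)) {
      tm <- (ts[j] + ts[j + 1]) / 2
      d_mid <- sqrt(aa + 2 * tm * av + tm^2 * vv)
      bin <- min(n_ring, floor(d_mid / interval_um) + 1L)
      shell_len[bin] <- shell_len[bin] + L * (ts[j + 1] - ts[j])
    }
  }
  structure(list(ring_radii_um = radii, intersections = crossings,
                 length_per_shell_um = shell_len, interval_um = interval_um,
                 mode = mode),
            class = "sholl_profile")
}
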