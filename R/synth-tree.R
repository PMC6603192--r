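# random unit vector; when parent_dir given, drawn within a cone around it
random_direction <- function(parent_dir = NULL, spread = 0.6) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  if (is.null(parent_dir)) return(u)
  d <- parent_dir + spread * u
  d / sqrt(sum(d^2))
}

#' Generate a random dendritic arbor with bookkept ground truth
#'
#' Stochastic centrifugal growth: `n_primary` stems leave the soma, each
#' segment draws its length from a normal distribution (truncated at
#' `min_segment_um`) and is laid out as a chain of short internodes with
#' small directional jitter; at a segment end the dendrite bifurcates with
#' probability `branch_prob` while the centrifugal order is below
#' `max_order`, otherwise it terminates.  The exact total length, branch
#' and terminal counts and terminal orders realized during growth are
#' recorded in the `"ground_truth"` attribute, giving an independent
#' cross-check for [arbor_summary()].
#'
#' @param n_primary number of stems leaving the soma (>= 1)
#' @param branch_prob bifurcation probability at a segment end, in `[0, 1]`
#' @param mean_segment_um,sd_segment_um segment-length distribution
#' @param max_order maximal centrifugal order
#' @param type `"basal"` or `"apical"` (SWC codes 3 / 4)
#' @param internode_um nominal spacing of nodes along a segment
#' @param min_segment_um lower truncation of segment lengths
#' @param soma_radius_um radius of the single soma root node
#' @param seed optional seed (`NULL` leaves the RNG stream alone)
#' @return a [neuron_tree()] with attribute `"ground_truth"` (list with
#'   `total_length_um`, `n_primary`, `n_nodes`, `n_ends`,
#'   `terminal_orders`)
#' @export
generate_tree <- function(n_primary = 4, branch_prob = 0.35,
                          mean_segment_um = 45, sd_segment_um = 15,
                          max_order = 5, type = c("basal", "apical"),
                          internode_um = 8, min_segment_um = 5,
                          soma_radius_um = 6, seed = NULL) {
  type <- match.arg(type)
  if (n_primary < 1) stop("empty arbor: n_primary must be >= 1", call. = FALSE)
  stopifnot(branch_prob >= 0, branch_prob <= 1, max_order >= 1)
  if (!is.null(seed)) set.seed(seed)
  code <- if (type == "basal") 3 else 4

  nodes <- list(c(1, 1, 0, 0, 0, soma_radius_um, -1))  # soma root
  gt <- list(total = 0, n_nodes = 0, n_ends = 0, term_orders = numeric(0))
  next_id <- 2

  grow <- function(parent_id, origin, dir, order) {
    len <- max(min_segment_um, rnorm(1, mean_segment_um, sd_segment_um))
    n_piece <- max(1L, round(len / internode_um))
    pos <- origin
    pid <- parent_id
    for (k in seq_len(n_piece)) {
      dir <- random_direction(dir, spread = 0.15)
      step <- len / n_piece
      new_pos <- pos + step * dir
      gt$total <<- gt$total + step
      nodes[[length(nodes) + 1L]] <<-
        c(next_id, code, new_pos, 0.5, pid)
      pid <- next_id
      next_id <<- next_id + 1
      pos <- new_pos
    }
    if (order < max_order && runif(1) < branch_prob) {
      gt$n_nodes <<- gt$n_nodes + 1
      for (b in 1:2) grow(pid, pos, random_direction(dir, 1.2), order + 1)
    } else {
      gt$n_ends <<- gt$n_ends + 1
      gt$term_orders <<- c(gt$term_orders, order)
    }
  }
  for (s in seq_len(n_primary))
    grow(1, c(0, 0, 0), random_direction(), 1)

  df <- as.data.frame(do.call(rbind, nodes))
  names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")
  tree <- neuron_tree(df)
  attr(tree, "ground_truth") <- list(
    total_length_um = gt$total, n_primary = n_primary,
    n_nodes = gt$n_nodes, n_ends = gt$n_ends,
    terminal_orders = gt$term_orders)
  tree
}

#' Generate a two-arbor neuron (basal + apical) with a soma contour
#'
#' Convenience wrapper building one reconstruction with both dendrite
#' classes and a circular-ish soma contour polygon, as downstream code
#' expects from real tracings.  Ground truth for each arbor is stored in
#' the `"ground_truth"` attribute under `$basal` and `$apical`.
#'
#' @param basal,apical argument lists passed to [generate_tree()]
#' @param soma_radius_um soma size; also drives the contour
#' @param contour_points number of polygon vertices for the soma contour
#' @param seed optional seed
#' @return a [neuron_tree()]
#' @export
generate_neuron <- function(basal = list(n_primary = 4),
                            apical = list(n_primary = 1, max_order = 6),
                            soma_radius_um = 6, contour_points = 64,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- do.call(generate_tree, c(basal, list(type = "basal",
                                             soma_radius_um = soma_radius_um)))
  ta <- do.call(generate_tree, c(apical, list(type = "apical",
                                              soma_radius_um = soma_radius_um)))
  nb <- tb$nodes
  na_ <- ta$nodes[-1, , drop = FALSE]  # drop duplicate soma root
  offset <- max(nb$id)
  na_$id <- na_$id + offset
  na_$parent <- ifelse(na_$parent == 1, 1, na_$parent + offset)
  th <- seq(0, 2 * pi, length.out = contour_points + 1)[-1]
  r <- soma_radius_um * (1 + 0.05 * sin(3 * th))
  tree <- neuron_tree(rbind(nb, na_),
                      soma_contour = data.frame(x = r * cos(th),
                                                y = r * sin(th)))
  attr(tree, "ground_truth") <- list(basal = attr(tb, "ground_truth"),
                                     apical = attr(ta, "ground_truth"))
  tree
}
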