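#' Neuronal reconstruction tree
#'
#' Wraps a node table in the standard SWC layout: `id`, `type` (SWC codes:
#' 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite), `x`, `y`, `z`
#' (micrometres), `radius` (micrometres), `parent` (`-1` for the root).
#' Exactly one root is required, every parent must precede its child (which
#' also guarantees acyclicity), and ids must be unique.
#'
#' @param nodes data frame with the seven SWC columns
#' @param soma_contour optional data frame with columns `x`, `y`: ordered
#'   2D polygon tracing the soma boundary (micrometres)
#' @return object of class `neuron_tree`
#' @export
neuron_tree <- function(nodes, soma_contour = NULL) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes)))
    stop("nodes must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  nodes <- nodes[, req]
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L)
    stop("tree must have exactly one root (parent -1); found ",
         length(roots), call. = FALSE)
  pos <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1 & (is.na(pos) | pos >= seq_len(nrow(nodes))))
  if (length(bad))
    stop("orphan or forward-referencing parents at node id(s) ",
         paste(nodes$id[bad], collapse = ", "),
         " (every parent must be defined before its child)", call. = FALSE)
  if (!all(nodes$type %in% 0:7))
    stop("structure types must be SWC standard codes 0-7", call. = FALSE)
  if (!is.null(soma_contour)) {
    stopifnot(is.data.frame(soma_contour),
              all(c("x", "y") %in% names(soma_contour)))
  }
  structure(list(nodes = nodes, soma_contour = soma_contour),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = 1:4,
                      labels = c("soma", "axon", "basal", "apical")))
  cat("<neuron_tree>", nrow(x$nodes), "nodes (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  invisible(x)
}

#' Read an SWC reconstruction
#'
#' Parses the standard whitespace-separated 7-column SWC text format,
#' reporting structural violations (wrong column counts, duplicate ids,
#' orphan or forward-referencing parents) with the offending line numbers.
#' An optional soma-contour sidecar CSV (columns `x`, `y`) can be attached.
#'
#' @param path SWC file
#' @param contour_path optional CSV with the 2D soma contour
#' @return a [neuron_tree()]
#' @export
read_swc <- function(path, contour_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("SWC parse error: no data lines", call. = FALSE)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("SWC parse error: expected 7 columns at line(s) ",
         paste(keep[nf != 7L], collapse = ", "), call. = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  bad <- keep[rowSums(is.na(m)) > 0]
  if (length(bad))
    stop("SWC parse error: non-numeric fields at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  tree <- tryCatch(neuron_tree(nodes), error = function(e)
    stop("SWC structure error in ", basename(path), ": ",
         conditionMessage(e), call. = FALSE))
  if (!is.null(contour_path))
    tree$soma_contour <- read.csv(contour_path)[, c("x", "y")]
  tree
}

#' Write an SWC reconstruction
#'
#' @param tree a [neuron_tree()]
#' @param path output file
#' @param contour_path optional CSV path for the soma contour sidecar
#' @return `path`, invisibly
#' @export
write_swc <- function(tree, path, contour_path = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  lines <- sprintf("%d %d %s %s %s %s %d", as.integer(n$id),
                   as.integer(n$type), fmt17(n$x), fmt17(n$y), fmt17(n$z),
                   fmt17(n$radius), as.integer(n$parent))
  writeLines(c("# SWC written by patchmorph", lines), path)
  if (!is.null(contour_path) && !is.null(tree$soma_contour))
    write.csv(tree$soma_contour, contour_path, row.names = FALSE)
  invisible(path)
}
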