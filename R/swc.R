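#' Neuron morphology objects
#'
#' A `neuron_morphology` is a rooted tree of typed nodes with 3D coordinates.
#' Node types are `soma`, `basal` and `apical` (SWC structure codes 1, 3 and
#' 4). One named coordinate axis increases with cortical depth and the pial
#' surface is at depth 0; by default this is the `y` axis.
#'
#' @param nodes data frame with columns `id` (integer, unique), `parent`
#'   (integer; -1 for the root), `type` (one of `"soma"`, `"basal"`,
#'   `"apical"`), `x`, `y`, `z` (um) and `radius` (um). Every parent must be
#'   declared on an earlier row than its children.
#' @param depth_axis which coordinate axis increases with cortical depth;
#'   one of `"x"`, `"y"`, `"z"`.
#' @return an object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes, depth_axis = "y") {
  depth_axis <- match.arg(depth_axis, c("x", "y", "z"))
  req <- c("id", "parent", "type", "x", "y", "z", "radius")
  if (!all(req %in% names(nodes)))
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes)[req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id))
    stop("duplicated node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(nodes$type %in% c("soma", "basal", "apical")))
    stop("unknown node type(s): ",
         paste(setdiff(unique(nodes$type), c("soma", "basal", "apical")),
               collapse = ", "))
  root <- which(nodes$parent == -1L)
  if (length(root) != 1L)
    stop("morphology must have exactly one root node (parent = -1), found ",
         length(root))
  if (nodes$type[root] != "soma")
    stop("root node must be of type 'soma'")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z", "radius")]))))
    stop("node coordinates must be finite")
  ## parent must precede child (guarantees connectivity and no cycles)
  pos <- match(nodes$parent, nodes$id)
  nonroot <- seq_len(nrow(nodes))[-root]
  bad <- nonroot[is.na(pos[nonroot])]
  if (length(bad))
    stop("node(s) ", paste(nodes$id[bad], collapse = ", "),
         " reference undeclared parent(s)")
  late <- nonroot[pos[nonroot] >= nonroot]
  if (length(late))
    stop("parent of node ", nodes$id[late[1]], " is declared after it")
  structure(list(nodes = nodes, depth_axis = depth_axis),
            class = "neuron_morphology")
}

#' Cortical depth of each node
#' @param morph a [neuron_morphology()].
#' @return numeric vector of depths (um) in node order.
#' @export
node_depths <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  morph$nodes[[morph$depth_axis]]
}

#' Soma depth of a morphology
#' @param morph a [neuron_morphology()].
#' @return depth (um) of the root node.
#' @export
soma_depth <- function(morph) {
  node_depths(morph)[morph$nodes$parent == -1L]
}

## internal: one row per non-root node, with parent/child coordinates,
## Euclidean edge length and the child's type
morph_edges <- function(morph) {
  n <- morph$nodes
  pos <- match(n$parent, n$id)
  keep <- !is.na(pos)
  child <- n[keep, , drop = FALSE]
  par <- n[pos[keep], , drop = FALSE]
  len <- sqrt((child$x - par$x)^2 + (child$y - par$y)^2 + (child$z - par$z)^2)
  data.frame(child_id = child$id, type = child$type,
             d0 = par[[morph$depth_axis]], d1 = child[[morph$depth_axis]],
             x0 = par$x, y0 = par$y, z0 = par$z,
             x1 = child$x, y1 = child$y, z1 = child$z,
             length = len, stringsAsFactors = FALSE)
}

## internal: number of children per node (in node order)
n_children <- function(morph) {
  n <- morph$nodes
  tab <- table(factor(n$parent, levels = n$id))
  as.integer(tab)
}

#' Read a neuron reconstruction in SWC format
#'
#' Standard 7-column SWC: `id type x y z radius parent`, 1-based ids, parent
#' -1 for the root, `#` comment lines. Structure codes 1, 3, 4 map to soma,
#' basal and apical dendrite; any other code is an error.
#'
#' @param path file path.
#' @param depth_axis coordinate axis increasing with cortical depth.
#' @return a [neuron_morphology()].
#' @export
read_swc <- function(path, depth_axis = "y") {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no SWC records in ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("malformed SWC line ", keep[which(nf != 7L)[1]],
         ": expected 7 fields")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("malformed SWC line ", keep[which(rowSums(is.na(m)) > 0)[1]],
         ": non-numeric field")
  code <- as.integer(m[, 2])
  bad <- which(!code %in% c(1L, 3L, 4L))
  if (length(bad))
    stop("unsupported SWC structure code ", code[bad[1]], " on line ",
         keep[bad[1]])
  type <- c("soma", "basal", "apical")[match(code, c(1L, 3L, 4L))]
  nodes <- data.frame(id = as.integer(m[, 1]), parent = as.integer(m[, 7]),
                      type = type, x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], stringsAsFactors = FALSE)
  neuron_morphology(nodes, depth_axis = depth_axis)
}

#' Write a neuron morphology to SWC
#'
#' @param morph a [neuron_morphology()].
#' @param path output file path.
#' @return `path`, invisibly. `read_swc(write_swc(m, f))` reproduces `m` up
#'   to floating-point formatting.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "neuron_morphology"))
  n <- morph$nodes
  code <- c(soma = 1L, basal = 3L, apical = 4L)[n$type]
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   n$id, code, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC export (id type x y z radius parent)", lines), path)
  invisible(path)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  ed <- morph_edges(x)
  cat("Neuron morphology: ", nrow(x$nodes), " nodes, ",
      sprintf("%.0f", sum(ed$length[ed$type != "soma"])),
      " um dendritic length, soma depth ",
      sprintf("%.0f", soma_depth(x)), " um\n", sep = "")
  invisible(x)
}
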