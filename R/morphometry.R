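#' Laminar profile of a dendritic morphology
#'
#' Apportions dendritic path length, branch points and complexity to
#' cortical layers. Each edge's Euclidean length is split among layers in
#' proportion to the fraction of its (linearly interpolated) depth interval
#' falling inside each layer band. A branch point is any non-soma node with
#' at least two children, assigned to the layer containing its depth.
#' Per-layer complexity is path length times the number of branch points.
#'
#' Nodes above the pia (negative depth) are clipped to depth 0 with a
#' warning; depths beyond the deepest layer boundary are pooled into the
#' deepest layer.
#'
#' @param morph a [neuron_morphology()], registered so that pia = depth 0.
#' @param layers a [layer_scheme()].
#' @return an object of class `laminar_profile`: a data frame with columns
#'   `layer`, `path_length` (um), `branch_points`, `complexity`
#'   (um x count), with the total dendritic length as attribute
#'   `total_length`.
#' @export
laminar_profile <- function(morph, layers = layer_scheme()) {
  stopifnot(inherits(morph, "neuron_morphology"),
            inherits(layers, "layer_scheme"))
  ed <- morph_edges(morph)
  ed <- ed[ed$type != "soma", , drop = FALSE]
  if (any(c(ed$d0, ed$d1) < 0)) {
    warning("node(s) above the pia (negative depth); clipped to 0")
    ed$d0 <- pmax(ed$d0, 0)
    ed$d1 <- pmax(ed$d1, 0)
  }
  dmin <- pmin(ed$d0, ed$d1)
  dmax <- pmax(ed$d0, ed$d1)
  span <- dmax - dmin
  len <- numeric(nrow(layers))
  for (k in seq_len(nrow(layers))) {
    lo <- layers$lo[k]
    hi <- if (k == nrow(layers)) Inf else layers$hi[k]
    ov <- pmin(dmax, hi) - pmax(dmin, lo)
    frac <- ifelse(span > 0, pmax(ov, 0) / span,
                   as.numeric(dmin >= lo & dmin < hi))
    len[k] <- sum(frac * ed$length)
  }
  nc <- n_children(morph)
  is_bp <- nc >= 2L & morph$nodes$type != "soma"
  bp_layer <- layer_of(node_depths(morph)[is_bp], layers)
  bp <- as.integer(table(factor(bp_layer, levels = layers$layer)))
  out <- data.frame(layer = layers$layer, path_length = len,
                    branch_points = bp, complexity = len * bp,
                    stringsAsFactors = FALSE)
  attr(out, "total_length") <- sum(ed$length)
  class(out) <- c("laminar_profile", "data.frame")
  out
}

#' Names of the default dendritic feature set
#'
#' The 21-dimensional feature space: soma depth; total/basal/apical path
#' length; total/basal/apical branch points; per-layer (L1, L2/3, L4, L5A,
#' L5B) path length and branch points; maximal horizontal tuft extent;
#' apical trunk length to the main bifurcation; number of primary basal
#' stems; maximal branch order. Lengths and depths are in um.
#'
#' @return character vector of length 21.
#' @export
dendritic_feature_names <- function() {
  lay <- c("L1", "L2/3", "L4", "L5A", "L5B")
  c("soma_depth", "total_length", "basal_length", "apical_length",
    "total_bp", "basal_bp", "apical_bp",
    paste0("length_", lay), paste0("bp_", lay),
    "tuft_extent", "trunk_length", "n_basal_stems", "max_branch_order")
}

#' Dendritic feature vector of a morphology
#'
#' Computes the default 21-feature morphometric vector (see
#' [dendritic_feature_names()]). The registry is pluggable: `features`
#' selects and orders any subset.
#'
#' @param morph a [neuron_morphology()].
#' @param layers a [layer_scheme()]; must contain layers L1, L2/3, L4, L5A
#'   and L5B for the per-layer features.
#' @param features character vector of feature names to return.
#' @return named numeric vector of class `dendritic_features`.
#' @export
feature_vector <- function(morph, layers = layer_scheme(),
                           features = dendritic_feature_names()) {
  stopifnot(inherits(morph, "neuron_morphology"))
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  if (!all(lay5 %in% layers$layer))
    stop("layer scheme must contain layers ", paste(lay5, collapse = ", "))
  ed <- morph_edges(morph)
  ed <- ed[ed$type != "soma", , drop = FALSE]
  nodes <- morph$nodes
  nc <- n_children(morph)
  root <- which(nodes$parent == -1L)
  is_bp <- nc >= 2L & nodes$type != "soma"
  depths <- node_depths(morph)

  has_apical <- any(nodes$type == "apical")
  if (!has_apical)
    warning("morphology has no apical subtree; apical features set to 0")

  prof <- suppressWarnings(laminar_profile(morph, layers))
  prof5 <- prof[match(lay5, prof$layer), ]

  type_len <- function(tp) sum(ed$length[ed$type == tp])
  type_bp <- function(tp) sum(is_bp & nodes$type == tp)

  ## cumulative path length from the soma to each node
  pos <- match(nodes$parent, nodes$id)
  elen <- numeric(nrow(nodes))
  elen[-root] <- sqrt((nodes$x[-root] - nodes$x[pos[-root]])^2 +
                      (nodes$y[-root] - nodes$y[pos[-root]])^2 +
                      (nodes$z[-root] - nodes$z[pos[-root]])^2)
  dist_root <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))[-root])
    dist_root[i] <- dist_root[pos[i]] + elen[i]

  ## branch order: 1 + number of non-soma branch points strictly between
  ## the soma and the node
  ord <- integer(nrow(nodes))
  ord[root] <- 0L
  for (i in seq_len(nrow(nodes))[-root])
    ord[i] <- ord[pos[i]] + as.integer(is_bp[pos[i]])
  max_order <- if (nrow(nodes) > 1L) max(ord[-root]) + 1L else 0L

  ## maximal horizontal tuft extent: largest pairwise horizontal distance
  ## among apical nodes within L1
  l1_hi <- layers$hi[layers$layer == "L1"]
  tuft <- which(nodes$type == "apical" & depths < l1_hi)
  horiz <- setdiff(c("x", "y", "z"), morph$depth_axis)
  tuft_extent <- 0
  if (length(tuft) >= 2L) {
    h <- as.matrix(nodes[tuft, horiz])
    tuft_extent <- max(stats::dist(h))
  }

  ## apical trunk length: path distance from soma to the first apical branch
  ## point (or to the farthest apical node if the apical tree is unbranched)
  apical_bp_nodes <- which(is_bp & nodes$type == "apical")
  trunk_length <- if (length(apical_bp_nodes)) {
    min(dist_root[apical_bp_nodes])
  } else if (has_apical) {
    max(dist_root[nodes$type == "apical"])
  } else 0

  vals <- c(
    soma_depth = depths[root],
    total_length = sum(ed$length),
    basal_length = type_len("basal"),
    apical_length = type_len("apical"),
    total_bp = sum(is_bp),
    basal_bp = type_bp("basal"),
    apical_bp = type_bp("apical"),
    stats::setNames(prof5$path_length, paste0("length_", lay5)),
    stats::setNames(as.numeric(prof5$branch_points), paste0("bp_", lay5)),
    tuft_extent = tuft_extent,
    trunk_length = trunk_length,
    n_basal_stems = sum(nodes$parent == nodes$id[root] &
                        nodes$type == "basal"),
    max_branch_order = as.numeric(max_order)
  )
  missing <- setdiff(features, names(vals))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  structure(vals[features], class = "dendritic_features")
}

#' Principal component analysis of dendritic feature matrices
#'
#' Features are z-scored column-wise before the decomposition; constant
#' (zero-variance) columns are dropped with a warning. The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' results are reproducible up to feature order.
#'
#' @param x numeric matrix or data frame, cells in rows, features in
#'   columns.
#' @return an object of class `feature_pca`: list with `scores`, `loadings`
#'   (orthonormal columns), `explained_variance` (proportions), `center`,
#'   `scale` and `dropped` (names of constant columns).
#' @export
pca_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 cells for PCA")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop))
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  if (all(drop)) {
    ## fully degenerate input (e.g. identical cells): all scores are zero
    return(structure(list(scores = matrix(0, nrow(x), 1,
                                          dimnames = list(NULL, "PC1")),
                          loadings = matrix(0, 0, 1,
                                            dimnames = list(NULL, "PC1")),
                          explained_variance = NA_real_,
                          center = numeric(0), scale = numeric(0),
                          dropped = colnames(x)),
                     class = "feature_pca"))
  }
  z <- scale(x[, !drop, drop = FALSE], center = ctr[!drop],
             scale = sds[!drop])
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x, loadings = pr$rotation,
                 explained_variance = pr$sdev^2 / sum(pr$sdev^2),
                 center = ctr[!drop], scale = sds[!drop],
                 dropped = colnames(x)[drop]),
            class = "feature_pca")
}

#' @export
print.feature_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat("Feature PCA: ", ncol(x$loadings), " components; PC1/PC2 explain ",
      sprintf("%.1f%%/%.1f%%", 100 * ev[1], 100 * ev[min(2, length(ev))]),
      " of variance\n", sep = "")
  invisible(x)
}
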