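#' Default cluster merge map
#'
#' The classifier operates on three clusters: POm, Sp5C and a merged
#' SC/Pons cluster, because SC- and Pons-projecting cells share depth,
#' spiking and similarity characteristics.
#'
#' @return named character vector mapping labels to cluster names.
#' @export
default_merge_map <- function() {
  c(POm = "POm", Sp5C = "Sp5C", SC = "SC/Pons", Pons = "SC/Pons")
}

## internal: invert a covariance matrix on the correlation scale, which
## keeps mixed-unit feature spaces (um alongside Hz and dimensionless
## indices) well conditioned
inv_cov <- function(C, label = "?") {
  s <- sqrt(diag(C))
  if (any(s <= 0)) stop("singular covariance for cluster '", label, "'")
  Rm <- C / outer(s, s)
  Rinv <- tryCatch(solve(Rm), error = function(e)
    stop("singular covariance for cluster '", label, "' despite ridge: ",
         conditionMessage(e)))
  Rinv / outer(s, s)
}

## internal: map raw labels through a merge map (labels absent from the
## map are kept as-is)
merge_labels <- function(labels, merge_map) {
  out <- merge_map[labels]
  out[is.na(out)] <- labels[is.na(out)]
  unname(out)
}

#' Fit per-cluster Gaussian models
#'
#' For each (merged) cluster, computes the sample mean and sample
#' covariance (denominator `n - 1`) of the feature matrix, with a small
#' proportional ridge (`ridge` times each feature's variance) added to the
#' covariance diagonal so the model stays invertible for small clusters
#' without breaking the affine invariance of the Mahalanobis distance.
#' The degrees of freedom of every cluster equal the shared feature
#' dimension.
#'
#' @param x numeric matrix, cells in rows, features in columns.
#' @param labels character vector of target labels per cell.
#' @param merge_map named character vector mapping labels to cluster names
#'   (see [default_merge_map()]); use `NULL` for no merging.
#' @param ridge relative ridge added to the covariance diagonal.
#' @param standardize if `TRUE`, features are z-scored (global mean/SD)
#'   before fitting; the scaling is stored and applied at classification.
#' @param quiet suppress small-sample warnings.
#' @return an object of class `cluster_model`.
#' @export
fit_clusters <- function(x, labels, merge_map = default_merge_map(),
                         ridge = 1e-6, standardize = FALSE, quiet = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels))
    stop("labels must match the rows of x")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = ctr, scale = scl)
  }
  cl_labels <- if (is.null(merge_map)) labels else
    merge_labels(labels, merge_map)
  d <- ncol(x)
  clusters <- list()
  for (g in sort(unique(cl_labels))) {
    xi <- x[cl_labels == g, , drop = FALSE]
    if (nrow(xi) < 2L)
      stop("cluster '", g, "' has fewer than 2 cells")
    if (nrow(xi) < d + 1L && !quiet)
      warning("cluster '", g, "' has ", nrow(xi), " cells for ", d,
              " features; covariance is ridge-regularized only")
    C <- stats::cov(xi)
    ## per-axis proportional ridge: keeps the model invertible for small
    ## clusters while preserving exact invariance under affine rescaling
    ## of individual features
    dg <- diag(C)
    base <- if (any(dg > 0)) ifelse(dg > 0, dg, mean(dg[dg > 0]))
            else rep(1, d)
    C <- C + diag(ridge * base, nrow = d)
    inv <- inv_cov(C, g)
    clusters[[g]] <- list(label = g, mean = colMeans(xi), cov = C,
                          cov_inv = inv, n = nrow(xi))
  }
  structure(list(clusters = clusters, dof = d,
                 features = colnames(x), merge_map = merge_map,
                 ridge = ridge, standardize = standardize,
                 center = ctr, scale = scl),
            class = "cluster_model")
}

#' Mahalanobis distances to each cluster
#'
#' Distance of each cell to each cluster centre in units of the cluster's
#' covariance-defined standard deviation:
#' `d = sqrt((x - mu)' C^-1 (x - mu))`.
#'
#' @param model a [fit_clusters()] model.
#' @param x numeric matrix (cells x features) or a single feature vector.
#' @return matrix of distances, cells in rows, clusters in columns.
#' @export
cluster_distances <- function(model, x) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$dof)
    stop("x has ", ncol(x), " features; model expects ", model$dof)
  if (model$standardize)
    x <- scale(x, center = model$center, scale = model$scale)
  d2 <- sapply(model$clusters, function(cl)
    stats::mahalanobis(x, cl$mean, cl$cov_inv, inverted = TRUE))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1,
                                     dimnames = list(NULL, names(model$clusters)))
  sqrt(pmax(d2, 0))
}

#' Classify cells with chi-squared assignment confidences
#'
#' Each cell is assigned to the cluster with the minimum Mahalanobis
#' distance. The confidence of assignment to cluster `k` is
#' `P(k) = p_k / sum_i p_i` with `p_i = 1 - F(d_i^2, DOF)`, where `F` is
#' the chi-squared cumulative distribution function and DOF is the feature
#' dimension: `p_i` is the probability of finding a single cell at distance
#' `d_i` or farther from cluster `i`. If every `p_i` underflows to zero,
#' the assigned cluster receives confidence 1 and the cell is flagged.
#'
#' @param model a [fit_clusters()] model.
#' @param x feature matrix or single feature vector.
#' @return an object of class `classification_result`: list with
#'   `assigned` (cluster labels), `confidence` (P of the assigned cluster),
#'   `distance`, `p` and `posterior` matrices, and logical flags
#'   `tie` and `underflow`.
#' @export
classify_cells <- function(model, x) {
  dist <- cluster_distances(model, x)
  d2 <- dist^2
  p <- matrix(stats::pchisq(d2, df = model$dof, lower.tail = FALSE),
              nrow = nrow(d2), dimnames = dimnames(d2))
  assigned_idx <- apply(dist, 1, which.min)
  tie <- apply(dist, 1, function(r) sum(r == min(r)) > 1L)
  tot <- rowSums(p)
  underflow <- tot == 0
  post <- p / ifelse(tot > 0, tot, 1)
  for (i in which(underflow)) post[i, ] <- 0
  post[cbind(which(underflow), assigned_idx[underflow])] <- 1
  labels <- colnames(dist)
  structure(list(assigned = labels[assigned_idx],
                 confidence = post[cbind(seq_len(nrow(post)), assigned_idx)],
                 distance = dist, p = p, posterior = post,
                 tie = tie, underflow = underflow),
            class = "classification_result")
}

#' Leave-one-out or resubstitution evaluation of a labeled cohort
#'
#' Fits the cluster model and classifies every cell, either with the full
#' model (resubstitution) or refitting the model with the cell held out
#' (leave-one-out). Returns the per-cell table, the confusion matrix and
#' summary accuracy/confidence statistics.
#'
#' @param x feature matrix, cells in rows.
#' @param labels true target labels per cell.
#' @param merge_map cluster merge map (see [default_merge_map()]).
#' @param loo if `TRUE`, leave-one-out evaluation.
#' @param cell_ids optional cell identifiers for the result table.
#' @param ... passed to [fit_clusters()].
#' @return list with `table` (data frame: cell, true label, merged true
#'   label, assigned cluster, correct, confidence), `confusion`,
#'   `accuracy`, `mean_confidence` (over all cells) and
#'   `mean_confidence_correct` (over correctly assigned cells).
#' @export
evaluate_cohort <- function(x, labels, merge_map = default_merge_map(),
                            loo = FALSE, cell_ids = NULL, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  truth <- merge_labels(labels, if (is.null(merge_map))
    stats::setNames(unique(labels), unique(labels)) else merge_map)
  if (loo) {
    assigned <- character(n)
    confidence <- numeric(n)
    for (i in seq_len(n)) {
      m <- fit_clusters(x[-i, , drop = FALSE], labels[-i], merge_map,
                        quiet = TRUE, ...)
      r <- classify_cells(m, x[i, ])
      assigned[i] <- r$assigned
      confidence[i] <- r$confidence
    }
  } else {
    m <- fit_clusters(x, labels, merge_map, quiet = TRUE, ...)
    r <- classify_cells(m, x)
    assigned <- r$assigned
    confidence <- r$confidence
  }
  correct <- assigned == truth
  tab <- data.frame(cell = if (is.null(cell_ids)) seq_len(n) else cell_ids,
                    true = labels, true_cluster = truth,
                    assigned = assigned, correct = correct,
                    confidence = confidence, stringsAsFactors = FALSE)
  list(table = tab,
       confusion = table(true = truth, assigned = assigned),
       accuracy = mean(correct),
       mean_confidence = mean(confidence),
       mean_confidence_correct = if (any(correct))
         mean(confidence[correct]) else NA_real_)
}

#' Serialize / restore a cluster model as JSON
#'
#' @param model a [fit_clusters()] model.
#' @param path output (input) file path.
#' @return `write_cluster_model` returns `path` invisibly;
#'   `read_cluster_model` returns the restored `cluster_model`.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  payload <- list(
    features = model$features, dof = model$dof, ridge = model$ridge,
    standardize = model$standardize, center = model$center,
    scale = model$scale, merge_map = as.list(model$merge_map),
    clusters = lapply(model$clusters, function(cl)
      list(label = cl$label, n = cl$n, mean = cl$mean,
           cov = cl$cov))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- lapply(p$clusters, function(cl) {
    C <- as.matrix(cl$cov)
    dimnames(C) <- list(p$features, p$features)
    list(label = cl$label, mean = stats::setNames(unlist(cl$mean),
                                                  p$features),
         cov = C, cov_inv = inv_cov(C, cl$label), n = cl$n)
  })
  structure(list(clusters = clusters, dof = p$dof, features = p$features,
                 merge_map = unlist(p$merge_map), ridge = p$ridge,
                 standardize = isTRUE(p$standardize),
                 center = unlist(p$center), scale = unlist(p$scale)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model: ", length(x$clusters), " clusters (",
      paste(names(x$clusters), collapse = ", "), "), ", x$dof,
      " features\n", sep = "")
  invisible(x)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Classification of ", length(x$assigned), " cell(s): ",
      paste(sprintf("%s (%.0f%%)", x$assigned, 100 * x$confidence),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
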