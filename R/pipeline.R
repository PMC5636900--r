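#' Spiking metrics of every cell in a cohort
#'
#' @param cohort a [generate_cohort()] cohort (with spike trains).
#' @return data frame, one row per cell, with identifiers, soma depth and
#'   all [activity_metrics()] columns.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  do.call(rbind, lapply(cohort, function(cell) {
    if (is.null(cell$trains)) stop("cohort has no spike trains")
    cbind(data.frame(cell_id = cell$cell_id, group = cell$group,
                     dual = cell$dual, soma_depth = cell$soma_depth,
                     stringsAsFactors = FALSE),
          activity_metrics(cell$trains))
  }))
}

#' Dendritic feature matrix of a cohort
#'
#' @param cohort a cohort with morphologies.
#' @param layers a [layer_scheme()].
#' @return list with `features` (cells x 21 matrix), `complexity`
#'   (cells x 5 per-layer complexity matrix), `labels`, `cell_ids`,
#'   `dual`.
#' @export
cohort_features <- function(cohort, layers = layer_scheme()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  feats <- t(vapply(cohort, function(cell) {
    if (is.null(cell$morphology)) stop("cohort has no morphologies")
    as.numeric(feature_vector(cell$morphology, layers))
  }, numeric(21)))
  colnames(feats) <- dendritic_feature_names()
  comp <- t(vapply(cohort, function(cell) {
    pr <- laminar_profile(cell$morphology, layers)
    pr$complexity[match(lay5, pr$layer)]
  }, numeric(5)))
  colnames(comp) <- lay5
  list(features = feats, complexity = comp,
       labels = vapply(cohort, `[[`, character(1), "group"),
       cell_ids = vapply(cohort, `[[`, character(1), "cell_id"),
       dual = vapply(cohort, `[[`, logical(1), "dual"))
}

#' PSTH similarity indices of every cell in a cohort
#'
#' Builds the four group templates from the single-labeled cells'
#' trial-averaged PSTHs and scores every cell (including dual-labeled
#' ones) against them.
#'
#' @param cohort a cohort with spike trains.
#' @param bin_width PSTH bin width (ms).
#' @return list with `table` (data frame: cell_id, the four similarity
#'   sums, SI1, SI2) and `templates`.
#' @export
cohort_similarity <- function(cohort, bin_width = 5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  psths <- lapply(cohort, function(cell) compute_psth(cell$trains,
                                                      bin_width))
  ong <- vapply(cohort, function(cell) ongoing_rate(cell$trains),
                numeric(1))
  labels <- vapply(cohort, `[[`, character(1), "group")
  dual <- vapply(cohort, `[[`, logical(1), "dual")
  groups <- unique(labels[!dual])
  templates <- build_templates(psths[!dual], ong[!dual], labels[!dual],
                               groups = groups)
  rows <- lapply(seq_along(cohort), function(i) {
    si <- similarity_indices(normalize_evoked(psths[[i]], ong[i]),
                             templates)
    data.frame(cell_id = cohort[[i]]$cell_id,
               sim_POm = si$similarity[["POm"]],
               sim_SC = si$similarity[["SC"]],
               sim_Pons = si$similarity[["Pons"]],
               sim_Sp5C = si$similarity[["Sp5C"]],
               SI1 = si$SI1, SI2 = si$SI2, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), templates = templates)
}

#' Assemble a classification feature matrix for a cohort
#'
#' The feature spaces mirror the classifier analyses: soma depth alone,
#' ongoing rate alone, a dendritic scalar alone (the first principal
#' component of the per-layer complexity 5-vector across the cohort),
#' the combined 3-feature space, the combined space augmented with the
#' two PSTH similarity indices, or the full per-layer complexity
#' 5-vector.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param space one of `"depth"`, `"rate"`, `"dendrite"`,
#'   `"dendrite_laminar"`, `"combined"`, `"combined_si"`.
#' @param layers a [layer_scheme()].
#' @param si optional precomputed [cohort_similarity()] table (computed on
#'   demand for the `combined_si` space).
#' @param feats optional precomputed [cohort_features()] result.
#' @return list with `x` (feature matrix), `labels` (primary targets),
#'   `cell_ids`, `dual`.
#' @export
target_feature_matrix <- function(cohort, space = "combined",
                                  layers = layer_scheme(), si = NULL,
                                  feats = NULL) {
  space <- match.arg(space, c("depth", "rate", "dendrite",
                              "dendrite_laminar", "combined",
                              "combined_si"))
  needs_morph <- space %in% c("dendrite", "dendrite_laminar", "combined",
                              "combined_si")
  labels <- vapply(cohort, `[[`, character(1), "group")
  cell_ids <- vapply(cohort, `[[`, character(1), "cell_id")
  dual <- vapply(cohort, `[[`, logical(1), "dual")
  depth <- vapply(cohort, `[[`, numeric(1), "soma_depth")
  cols <- list()
  if (space %in% c("depth", "combined", "combined_si"))
    cols$soma_depth <- depth
  if (space %in% c("rate", "combined", "combined_si"))
    cols$ongoing_rate <- vapply(cohort, function(cell)
      ongoing_rate(cell$trains), numeric(1))
  if (needs_morph) {
    if (is.null(feats)) feats <- cohort_features(cohort, layers)
    if (space == "dendrite_laminar") {
      for (nm in colnames(feats$complexity))
        cols[[paste0("complexity_", nm)]] <- feats$complexity[, nm]
    } else {
      pca <- pca_features(feats$complexity)
      cols$dendrite_scalar <- pca$scores[, 1]
    }
  }
  if (space == "combined_si") {
    if (is.null(si)) si <- cohort_similarity(cohort)$table
    cols$SI1 <- si$SI1
    cols$SI2 <- si$SI2
  }
  x <- do.call(cbind, cols)
  rownames(x) <- cell_ids
  list(x = x, labels = labels, cell_ids = cell_ids, dual = dual)
}

#' Classify a cohort in a feature space, holding dual-labeled cells out
#'
#' Single-labeled cells are evaluated by leave-one-out (or
#' resubstitution); dual-labeled cells never enter the cluster fit and
#' are classified as held-out queries, counted correct when assigned to
#' the cluster of either of their targets.
#'
#' @param fm a [target_feature_matrix()] result.
#' @param cohort the cohort (for dual cells' second labels).
#' @param merge_map cluster merge map.
#' @param loo leave-one-out evaluation of the single-labeled cells?
#' @return list with `table`, `confusion`, `accuracy`,
#'   `mean_confidence`, `mean_confidence_correct` (single-labeled cells)
#'   and `duals` (per-cell table for dual-labeled cells, or NULL).
#' @export
classify_cohort <- function(fm, cohort, merge_map = default_merge_map(),
                            loo = TRUE) {
  singles <- !fm$dual
  ev <- evaluate_cohort(fm$x[singles, , drop = FALSE],
                        fm$labels[singles], merge_map, loo = loo,
                        cell_ids = fm$cell_ids[singles])
  duals <- NULL
  if (any(fm$dual)) {
    model <- fit_clusters(fm$x[singles, , drop = FALSE],
                          fm$labels[singles], merge_map, quiet = TRUE)
    r <- classify_cells(model, fm$x[fm$dual, , drop = FALSE])
    targets <- lapply(cohort[fm$dual], `[[`, "true_targets")
    ok <- mapply(function(assigned, tt)
      assigned %in% merge_labels(tt, merge_map), r$assigned, targets)
    duals <- data.frame(cell = fm$cell_ids[fm$dual],
                        true = vapply(targets, paste, character(1),
                                      collapse = "+"),
                        assigned = r$assigned, correct = as.logical(ok),
                        confidence = r$confidence,
                        stringsAsFactors = FALSE)
  }
  c(ev, list(duals = duals))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, computes per-cell spiking metrics, dendritic
#' features, PSTH similarity indices, classifies the cohort in the
#' configured feature spaces and writes a reproducible report bundle
#' (CSV/JSON; reruns with the same config are byte-identical).
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param layers a [layer_scheme()].
#' @param spaces feature spaces to classify in.
#' @param loo leave-one-out classification?
#' @param bin_width PSTH bin width (ms).
#' @return (invisibly) list with `cohort`, `metrics`, `features`,
#'   `similarity`, `classification` (per space) and `group_summary`.
#' @export
run_pipeline <- function(config = default_cohort_config(), out_dir = NULL,
                         layers = layer_scheme(),
                         spaces = c("depth", "rate", "dendrite",
                                    "combined", "combined_si"),
                         loo = TRUE, bin_width = 5) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_trials < 1) stop("configuration has no stimulation trials")
  if (all(vapply(config$groups, `[[`, integer(1), "n_cells") == 0))
    stop("configuration has no cells")
  cohort <- generate_cohort(config)
  metrics <- cohort_metrics(cohort)
  feats <- cohort_features(cohort, layers)
  sim <- cohort_similarity(cohort, bin_width)
  classification <- list()
  for (sp in spaces) {
    fm <- target_feature_matrix(cohort, sp, layers, si = sim$table,
                                feats = feats)
    classification[[sp]] <- classify_cohort(fm, cohort, loo = loo)
  }
  group_summary <- make_group_summary(config, metrics, feats)
  out <- list(cohort = cohort, metrics = metrics, features = feats,
              similarity = sim$table, classification = classification,
              group_summary = group_summary, config = config)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  invisible(out)
}

## internal: per-group empirical summary + calibration constants, with a
## TOTAL row carrying the per-column and %-of-NeuN sums
make_group_summary <- function(config, metrics, feats) {
  singles <- !metrics$dual
  glabels <- names(config$groups)
  total_len <- feats$features[, "total_length"]
  rows <- lapply(glabels, function(g) {
    i <- singles & metrics$group == g
    gp <- config$groups[[g]]
    data.frame(group = g, n = sum(i),
               depth_um = mean(metrics$soma_depth[i]),
               ongoing_hz = mean(metrics$ongoing_rate[i]),
               burst100_pct = mean(metrics$burst100_pct[i]),
               burst200_pct = mean(metrics$burst200_pct[i]),
               onset_hz = mean(metrics$onset_rate[i]),
               onset_prob = mean(metrics$onset_prob[i]),
               sustained_hz = mean(metrics$sustained_rate[i]),
               total_length_mm = mean(total_len[i]) / 1000,
               cells_per_column = gp$cells_per_column,
               pct_neun = gp$pct_neun, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(group = "TOTAL", n = sum(out$n),
                      depth_um = mean(metrics$soma_depth[singles]),
                      ongoing_hz = mean(metrics$ongoing_rate[singles]),
                      burst100_pct = mean(metrics$burst100_pct[singles]),
                      burst200_pct = mean(metrics$burst200_pct[singles]),
                      onset_hz = mean(metrics$onset_rate[singles]),
                      onset_prob = mean(metrics$onset_prob[singles]),
                      sustained_hz = mean(metrics$sustained_rate[singles]),
                      total_length_mm = mean(total_len[singles]) / 1000,
                      cells_per_column = sum(out$cells_per_column),
                      pct_neun = sum(out$pct_neun),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

## internal: write the report bundle (no timestamps, so reruns are
## byte-identical)
write_report_bundle <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  manifest <- do.call(rbind, lapply(out$cohort, function(cell)
    data.frame(cell_id = cell$cell_id, group = cell$group,
               targets = paste(cell$true_targets, collapse = "+"),
               dual = cell$dual, soma_depth = cell$soma_depth,
               ongoing_rate = cell$params$ongoing_rate,
               onset_rate = cell$params$onset_rate,
               onset_prob = cell$params$onset_prob,
               sustained_rate = cell$params$sustained_rate,
               stringsAsFactors = FALSE)))
  wcsv(manifest, "cohort_manifest.csv")
  wcsv(out$metrics, "metrics.csv")
  fdf <- data.frame(cell_id = out$features$cell_ids,
                    out$features$features, check.names = FALSE,
                    stringsAsFactors = FALSE)
  wcsv(fdf, "features.csv")
  wcsv(out$similarity, "similarity.csv")
  cls <- do.call(rbind, lapply(names(out$classification), function(sp) {
    r <- out$classification[[sp]]
    tab <- rbind(r$table[, c("cell", "true", "assigned", "correct",
                             "confidence")],
                 if (!is.null(r$duals))
                   r$duals[, c("cell", "true", "assigned", "correct",
                               "confidence")])
    cbind(space = sp, tab, stringsAsFactors = FALSE)
  }))
  wcsv(cls, "classification.csv")
  wcsv(out$group_summary, "group_summary.csv")
  summary <- lapply(out$classification, function(r)
    list(accuracy = r$accuracy, mean_confidence = r$mean_confidence,
         mean_confidence_correct = r$mean_confidence_correct,
         confusion = as.data.frame(r$confusion)))
  jsonlite::write_json(list(seed = out$config$seed,
                            n_cells = length(out$cohort),
                            spaces = summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(paste("ptarget version:",
                     as.character(utils::packageVersion("ptarget"))),
               paste("R version:", R.version.string),
               paste("seed:", out$config$seed)),
             file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
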