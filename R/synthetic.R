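#' Parameters of one projection-target group
#'
#' Describes the generative statistics of one group of pyramidal tract
#' neurons sharing a subcortical target: soma depth distribution, ongoing
#' and evoked spiking statistics, burst fractions, the qualitative shape of
#' the sustained response envelope, laminar dendrite targets, and the
#' per-column abundance calibration used by the soma-density stage.
#'
#' Rates are per-cell means and SDs in Hz; onset and sustained rates are
#' *elevations* above the ongoing rate. Burst fractions are fractions of
#' ongoing action potentials (0-1). Laminar targets are per-layer dendritic
#' path lengths (um) and branch-point counts for layers L1, L2/3, L4, L5A
#' and L5B.
#'
#' @param target_label one of `"POm"`, `"SC"`, `"Pons"`, `"Sp5C"`.
#' @param n_cells number of cells to generate for this group.
#' @param depth_mean,depth_sd soma depth distribution (um).
#' @param ongoing_rate_mean,ongoing_rate_sd ongoing rate distribution (Hz).
#' @param burst100_frac,burst200_frac mean fraction of ongoing spikes in
#'   100 Hz / 200 Hz bursts (burst200 is a subset of burst100).
#' @param onset_rate_mean,onset_rate_sd onset elevation (Hz) in 0-100 ms.
#' @param onset_prob,onset_prob_sd per-trial onset response probability.
#' @param sustained_rate_mean,sustained_rate_sd sustained elevation (Hz)
#'   in 100-700 ms.
#' @param sustained_shape one of `"flat_at_baseline"`,
#'   `"constant_elevated"`, `"decaying"`, `"late_ramp"`.
#' @param laminar_length_targets,laminar_bp_targets named numeric vectors
#'   (L1, L2/3, L4, L5A, L5B) of per-layer path length (um) and branch
#'   points.
#' @param morph_rel_sd relative SD of the per-cell morphology size factor.
#' @param cells_per_column calibration constant: labeled cells per average
#'   barrel column.
#' @param pct_neun calibration constant: labeled cells as % of all neurons
#'   in L5.
#' @return an object of class `group_params`.
#' @export
group_params <- function(target_label, n_cells,
                         depth_mean, depth_sd,
                         ongoing_rate_mean, ongoing_rate_sd,
                         burst100_frac, burst200_frac,
                         onset_rate_mean, onset_rate_sd,
                         onset_prob, onset_prob_sd,
                         sustained_rate_mean, sustained_rate_sd,
                         sustained_shape,
                         laminar_length_targets, laminar_bp_targets,
                         morph_rel_sd = 0.2,
                         cells_per_column = NA_real_,
                         pct_neun = NA_real_) {
  sustained_shape <- match.arg(sustained_shape,
                               c("flat_at_baseline", "constant_elevated",
                                 "decaying", "late_ramp"))
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  if (!identical(names(laminar_length_targets), lay5) ||
      !identical(names(laminar_bp_targets), lay5))
    stop("laminar targets must be named ", paste(lay5, collapse = ", "))
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (any(c(ongoing_rate_mean, onset_rate_mean, sustained_rate_mean,
            depth_mean) < 0))
    stop("mean rates and depth must be >= 0")
  if (onset_prob < 0 || onset_prob > 1)
    stop("onset_prob must be in [0, 1]")
  if (burst200_frac > burst100_frac)
    stop("burst200_frac must not exceed burst100_frac")
  if (any(laminar_length_targets < 0) || any(laminar_bp_targets < 0))
    stop("laminar targets must be nonnegative")
  structure(list(target_label = target_label, n_cells = as.integer(n_cells),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 ongoing_rate_mean = ongoing_rate_mean,
                 ongoing_rate_sd = ongoing_rate_sd,
                 burst100_frac = burst100_frac,
                 burst200_frac = burst200_frac,
                 onset_rate_mean = onset_rate_mean,
                 onset_rate_sd = onset_rate_sd,
                 onset_prob = onset_prob, onset_prob_sd = onset_prob_sd,
                 sustained_rate_mean = sustained_rate_mean,
                 sustained_rate_sd = sustained_rate_sd,
                 sustained_shape = sustained_shape,
                 laminar_length_targets = laminar_length_targets,
                 laminar_bp_targets = laminar_bp_targets,
                 morph_rel_sd = morph_rel_sd,
                 cells_per_column = cells_per_column,
                 pct_neun = pct_neun),
            class = "group_params")
}

#' Cohort configuration
#'
#' @param groups list of [group_params()] objects.
#' @param dual_fraction population-level fraction of PTs innervating two of
#'   the injected targets (reporting calibration; the recorded-sample
#'   layout uses `n_dual` explicit dual-labeled cells).
#' @param n_dual number of extra dual-labeled cells appended to the cohort.
#'   Dual cells inherit all generative parameters from their primary group;
#'   the second label is annotation only, and POm/Sp5C pairings are
#'   excluded.
#' @param n_trials trials per cell (typical range 20-30).
#' @param window recording window in ms, default `c(-200, 1100)`.
#' @param stimulus_duration stimulus duration in ms (onset at 0).
#' @param seed integer seed making the generated cohort reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(groups, dual_fraction = 0.25, n_dual = 0,
                          n_trials = 25, window = c(-200, 1100),
                          stimulus_duration = 700, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "group_params")))
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (dual_fraction < 0 || dual_fraction > 1)
    stop("dual_fraction must be in [0, 1]")
  if (window[1] > 0 || window[2] < stimulus_duration)
    stop("recording window must contain the stimulus")
  names(groups) <- vapply(groups, `[[`, character(1), "target_label")
  structure(list(groups = groups, dual_fraction = dual_fraction,
                 n_dual = as.integer(n_dual), n_trials = as.integer(n_trials),
                 window = window, stimulus_duration = stimulus_duration,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort configuration
#'
#' The calibration used throughout the package: four target groups (POm,
#' SC, Pons, Sp5C) with soma depths, ongoing rates, burst fractions, onset
#' and sustained responses, sustained envelope shapes, per-layer dendrite
#' targets and per-column abundances matching the published group
#' statistics of identified PT neurons in rat barrel cortex. Per-cell SDs
#' for the functional parameters are derived from the published standard
#' errors of group means (SD = SE * sqrt(5), group size 5); soma depth SDs
#' are published directly.
#'
#' Group sizes default to the reconstructed sample (5/5/5/4) plus 3
#' dual-labeled cells; 25 stimulation trials per cell.
#'
#' @param n_cells integer vector of length 4: cells per group
#'   (POm, SC, Pons, Sp5C).
#' @param n_dual number of extra dual-labeled cells.
#' @param n_trials trials per cell.
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @examples
#' cfg <- default_cohort_config()
#' cfg$groups$POm$ongoing_rate_mean # 7.2 Hz
#' @export
default_cohort_config <- function(n_cells = c(5, 5, 5, 4), n_dual = 3,
                                  n_trials = 25, seed = 1) {
  stopifnot(length(n_cells) == 4)
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  lt <- function(x) stats::setNames(x, lay5)
  groups <- list(
    group_params("POm", n_cells[1], 1042, 105,
                 7.2, 1.6 * sqrt(5), 0.052, 0.021,
                 5.1, 1.7 * sqrt(5), 0.66, 0.09 * sqrt(5),
                 0.8, 1.4 * sqrt(5), "flat_at_baseline",
                 lt(c(1200, 2500, 1500, 1000, 6500)),
                 lt(c(8, 10, 6, 4, 38)),
                 morph_rel_sd = 1.2 / 12.7,
                 cells_per_column = 256, pct_neun = 7),
    group_params("SC", n_cells[2], 1055, 97,
                 1.3, 0.6 * sqrt(5), 0.135, 0.062,
                 1.7, 1.2 * sqrt(5), 0.23, 0.12 * sqrt(5),
                 2.3, 1.1 * sqrt(5), "constant_elevated",
                 lt(c(1300, 2700, 1700, 3500, 4000)),
                 lt(c(9, 11, 7, 28, 22)),
                 morph_rel_sd = 3.9 / 13.2,
                 cells_per_column = 174, pct_neun = 5),
    group_params("Pons", n_cells[3], 1131, 110,
                 1.8, 1.1 * sqrt(5), 0.052, 0.004,
                 4.5, 2.9 * sqrt(5), 0.38, 0.20 * sqrt(5),
                 3.3, 2.1 * sqrt(5), "decaying",
                 lt(c(2800, 3200, 2000, 2600, 6200)),
                 lt(c(24, 14, 8, 16, 36)),
                 morph_rel_sd = 4.7 / 16.8,
                 cells_per_column = 421, pct_neun = 12),
    group_params("Sp5C", n_cells[4], 1154, 98,
                 4.3, 1.0 * sqrt(5), 0.046, 0.015,
                 6.9, 3.1 * sqrt(5), 0.64, 0.11 * sqrt(5),
                 3.3, 1.6 * sqrt(5), "late_ramp",
                 lt(c(1500, 3000, 800, 2300, 6200)),
                 lt(c(12, 14, 2, 20, 42)),
                 morph_rel_sd = 3.8 / 13.8,
                 cells_per_column = 284, pct_neun = 9)
  )
  cohort_config(groups, dual_fraction = 0.25, n_dual = n_dual,
                n_trials = n_trials, seed = seed)
}

## internal: Gaussian truncated below (resample until above `lower`)
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- x < lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("truncated-normal sampling failed to converge")
}

## internal: sustained envelope multiplier at normalized time u in [0, 1)
sustained_shape_fn <- function(shape) {
  switch(shape,
         flat_at_baseline = function(u) rep(1, length(u)),
         constant_elevated = function(u) rep(1, length(u)),
         decaying = function(u) 2 * (1 - u),
         late_ramp = function(u) ifelse(u < 2 / 3, 0, 3),
         stop("unknown sustained shape: ", shape))
}

#' Simulate spike trains of one cell
#'
#' Inhomogeneous Poisson process with intensity `r(t)` equal to the
#' ongoing rate before stimulus onset and after the post-stimulus return;
#' ongoing + onset elevation during the onset window (0-100 ms); ongoing +
#' a shaped sustained envelope with the configured mean elevation during
#' 100-700 ms; and a linear return to the ongoing rate over 700-800 ms.
#' Negative instantaneous intensities are floored at zero.
#'
#' Bursting is modelled by doublet injection: each ongoing-period spike is
#' followed, with a probability tuned to the target burst fractions, by a
#' second spike at an inter-spike interval of at most 5 ms (200 Hz bursts)
#' or 5-10 ms (100 Hz bursts); the base ongoing intensity is rescaled so
#' the total ongoing rate is preserved.
#'
#' The per-trial onset-response probability is calibrated to
#' `onset_prob`: when the Poisson expectation of observing at least one
#' onset spike exceeds the target, a trial's onset-window spikes are
#' deleted with probability `1 - onset_prob / p_expected`; when it falls
#' short, a single uniformly timed onset spike is injected into spikeless
#' trials with probability `(onset_prob - p_expected) / (1 - p_expected)`,
#' so the realized probability matches the target in expectation from both
#' sides.
#'
#' @param params list with `ongoing_rate` (Hz), `onset_rate` (elevation,
#'   Hz), `sustained_rate` (elevation, Hz), `sustained_shape`, optional
#'   `onset_prob` (`NULL` to disable the calibration) and optional
#'   `burst100_frac`, `burst200_frac` (fractions, default 0).
#' @param n_trials number of trials.
#' @param window recording window (ms), must contain the stimulus.
#' @param seed optional integer seed.
#' @param stimulus_duration stimulus duration (ms).
#' @return a [spike_train_set()].
#' @export
generate_spike_trains <- function(params, n_trials, window = c(-200, 1100),
                                  seed = NULL, stimulus_duration = 700) {
  if (!is.null(seed)) set.seed(seed)
  ong <- params$ongoing_rate
  oe <- if (is.null(params$onset_rate)) 0 else params$onset_rate
  se <- if (is.null(params$sustained_rate)) 0 else params$sustained_rate
  shape <- if (is.null(params$sustained_shape)) "constant_elevated" else
    params$sustained_shape
  b100 <- if (is.null(params$burst100_frac)) 0 else params$burst100_frac
  b200 <- if (is.null(params$burst200_frac)) 0 else params$burst200_frac
  op <- params$onset_prob
  if (ong < 0) stop("ongoing rate must be >= 0")
  if (window[1] > 0 || window[2] < stimulus_duration)
    stop("recording window must contain the stimulus")
  if (b200 > b100) stop("burst200_frac must not exceed burst100_frac")

  ## doublet-injection probability q preserving the total ongoing rate:
  ## burst fraction ~ 2q / (1 + q)  =>  q = b / (2 - b)
  q <- if (b100 > 0) b100 / (2 - b100) else 0
  w200 <- if (b100 > 0) b200 / b100 else 0
  base_ong <- ong / (1 + q)

  sf <- sustained_shape_fn(shape)
  onset_abs <- max(0, ong + oe)
  end_elev <- se * sf(1 - 1e-9)
  sus_end <- stimulus_duration
  ret_end <- stimulus_duration + 100
  rate_at <- function(t) {
    r <- numeric(length(t))
    pre <- t < 0
    r[pre] <- base_ong
    i <- t >= 0 & t < 100
    r[i] <- onset_abs
    i <- t >= 100 & t < sus_end
    u <- (t[i] - 100) / (sus_end - 100)
    r[i] <- pmax(0, ong + se * sf(u))
    i <- t >= sus_end & t < ret_end
    r[i] <- pmax(0, ong + end_elev * (1 - (t[i] - sus_end) / 100))
    r[t >= ret_end] <- ong
    r
  }
  shape_peak <- switch(shape, flat_at_baseline = se,
                       constant_elevated = se,
                       decaying = max(2 * se, 0), late_ramp = max(3 * se, 0))
  rmax <- max(base_ong, onset_abs, ong + max(shape_peak, 0),
              ong + max(end_elev, 0), ong)
  p_exp <- 1 - exp(-onset_abs * 0.1)

  span <- diff(window) / 1000
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    t <- numeric(0)
    if (rmax > 0) {
      n_cand <- stats::rpois(1, rmax * span)
      cand <- sort(stats::runif(n_cand, window[1], window[2]))
      t <- cand[stats::runif(n_cand) < rate_at(cand) / rmax]
    }
    if (!is.null(op)) {
      if (p_exp > op) {
        if (stats::runif(1) < 1 - op / p_exp)
          t <- t[t < 0 | t >= 100]
      } else if (p_exp < op && !any(t >= 0 & t < 100)) {
        if (stats::runif(1) < (op - p_exp) / (1 - p_exp))
          t <- sort(c(t, stats::runif(1, 0, 100)))
      }
    }
    if (q > 0) {
      ong_spikes <- t[t < 0]
      inject <- ong_spikes[stats::runif(length(ong_spikes)) < q]
      if (length(inject)) {
        isi <- ifelse(stats::runif(length(inject)) < w200,
                      stats::runif(length(inject), 1, 5),
                      stats::runif(length(inject), 5, 10))
        doublets <- inject + isi
        t <- sort(c(t, doublets[doublets < 0]))
      }
    }
    trials[[k]] <- unique(t)
  }
  spike_train_set(trials, window, stimulus_duration)
}

#' Construct a synthetic dendritic morphology with laminar targets
#'
#' Builds a rooted tree (soma, basal subtree around the soma, apical trunk
#' ascending through the layers with side branches and an L1 tuft) whose
#' per-layer dendritic path lengths match the requested targets and whose
#' per-layer branch-point counts match them exactly. Straight segments and
#' bifurcations are placed inside each layer band: the trunk contributes
#' its vertical span, side branches placed at bifurcation nodes contribute
#' the remainder, and layers without bifurcations absorb the remainder in
#' an unbranched horizontal detour. Layers below the soma are reached by a
#' descending basal cable.
#'
#' When called with a [group_params()] object, per-cell variability is
#' introduced by a multiplicative size factor applied to both length and
#' branch-point targets (Gaussian, mean 1, SD `morph_rel_sd`, truncated at
#' 0.2); length and branch-point totals therefore covary, as they do in
#' real reconstructions. Set `length_jitter_sd = 0` to reproduce the group
#' targets exactly.
#'
#' @param group a [group_params()] object, or a list with elements
#'   `laminar_length_targets` and `laminar_bp_targets` (named L1, L2/3,
#'   L4, L5A, L5B).
#' @param soma_depth soma depth (um), > 0.
#' @param seed optional integer seed.
#' @param layers a [layer_scheme()].
#' @param length_jitter_sd relative SD of the per-cell size factor;
#'   defaults to the group's `morph_rel_sd` (0 for plain target lists).
#' @param n_basal_stems number of primary basal stems.
#' @return a [neuron_morphology()] with attribute `realized_targets` (the
#'   jittered per-cell targets the tree was built to).
#' @export
generate_morphology <- function(group, soma_depth, seed = NULL,
                                layers = layer_scheme(),
                                length_jitter_sd = NULL,
                                n_basal_stems = 4) {
  if (!is.null(seed)) set.seed(seed)
  if (soma_depth <= 0) stop("soma_depth must be > 0")
  len_t <- group$laminar_length_targets
  bp_t <- group$laminar_bp_targets
  if (is.null(length_jitter_sd))
    length_jitter_sd <- if (inherits(group, "group_params"))
      group$morph_rel_sd else 0
  ## the size factor is floored at 0.45 so the jittered layer targets stay
  ## above the trunk spans the construction needs to traverse each layer
  f <- if (length_jitter_sd > 0)
    rtrunc_norm(1, 1, length_jitter_sd, lower = 0.45) else 1
  len_t <- len_t * f
  bp_t <- pmax(round(bp_t * f), 0)
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  if (!identical(names(len_t), lay5) || !identical(names(bp_t), lay5))
    stop("laminar targets must be named ", paste(lay5, collapse = ", "))
  if (any(bp_t > 0 & len_t <= 0))
    stop("a layer with branch points must have nonzero length")
  li <- layers[match(lay5, layers$layer), ]
  if (anyNA(li$lo))
    stop("layer scheme must contain layers ", paste(lay5, collapse = ", "))

  ## node accumulator
  nid <- 0L
  nd <- list(id = integer(), parent = integer(), type = character(),
             x = numeric(), y = numeric(), z = numeric(),
             radius = numeric())
  add <- function(parent, type, x, y, z, radius = 0.5) {
    nid <<- nid + 1L
    nd$id[nid] <<- nid; nd$parent[nid] <<- parent
    nd$type[nid] <<- type
    nd$x[nid] <<- x; nd$y[nid] <<- y; nd$z[nid] <<- z
    nd$radius[nid] <<- radius
    nid
  }
  azimuth <- 0
  twig <- function(parent, type, x0, depth, z0, len) {
    azimuth <<- azimuth + 2.399963
    add(parent, type, x0 + len * cos(azimuth), depth,
        z0 + len * sin(azimuth))
  }
  soma_id <- add(-1L, "soma", 0, soma_depth, 0, radius = 5)

  above <- which(li$hi <= soma_depth)    # layers entirely above the soma
  below <- which(li$lo >= soma_depth)    # layers entirely below the soma
  s_idx <- setdiff(seq_len(5L), c(above, below))
  if (!length(s_idx)) s_idx <- NA_integer_  # soma below L5B

  ## builds a vertical trunk from the soma through `idx` layers (ordered
  ## from the soma outward), placing bifurcation twigs and detours so each
  ## layer meets its length/branch-point target
  build_trunk <- function(idx, type, upward) {
    if (!length(idx)) return(invisible(NULL))
    active <- idx[seq_len(max(c(which(len_t[idx] > 0 | bp_t[idx] > 0), 0)))]
    if (!length(active)) return(invisible(NULL))
    last <- active[length(active)]
    ## end depth: just past the outermost attachment point of the last
    ## traversed layer
    b_last <- bp_t[last]
    frac <- if (b_last > 0) (b_last + 0.5) / (b_last + 1) else 0.6
    end_depth <- if (upward) li$hi[last] - frac * (li$hi[last] - li$lo[last])
                 else li$lo[last] + frac * (li$hi[last] - li$lo[last])
    ## per-layer trunk spans (including the traversed part of the soma's
    ## own layer) and remainders
    trunk_iv <- sort(c(end_depth, soma_depth))
    span <- pmax(0, pmin(trunk_iv[2], li$hi) - pmax(trunk_iv[1], li$lo))
    rem <- len_t - span
    if (any(rem[active] < -1e-6))
      stop("unreachable laminar targets: trunk span exceeds the length ",
           "target in layer ", lay5[active[which(rem[active] < -1e-6)[1]]])
    ## chain events ordered from the soma outward
    ev_depth <- numeric(0); ev_kind <- character(0); ev_len <- numeric(0)
    for (k in active) {
      B <- bp_t[k]
      if (B > 0) {
        at <- li$lo[k] + (li$hi[k] - li$lo[k]) * (seq_len(B) / (B + 1))
        ev_depth <- c(ev_depth, at)
        ev_kind <- c(ev_kind, rep("attach", B))
        ev_len <- c(ev_len, rep(max(rem[k], 0) / B, B))
      } else if (rem[k] > 1e-9) {
        mid <- (li$lo[k] + li$hi[k]) / 2
        ev_depth <- c(ev_depth, mid)
        ev_kind <- c(ev_kind, "detour")
        ev_len <- c(ev_len, rem[k])
      }
    }
    ord <- order(if (upward) -ev_depth else ev_depth)
    ev_depth <- ev_depth[ord]; ev_kind <- ev_kind[ord]; ev_len <- ev_len[ord]
    ## clip events to lie between soma and trunk end
    keep <- if (upward) ev_depth < soma_depth & ev_depth > end_depth
            else ev_depth > soma_depth & ev_depth < end_depth
    ord2 <- if (upward) order(-ev_depth[keep]) else order(ev_depth[keep])
    prev <- soma_id
    evs <- which(keep)[ord2]
    for (j in evs) {
      node <- add(prev, type, 0, ev_depth[j], 0)
      if (ev_kind[j] == "attach") {
        twig(node, type, 0, ev_depth[j], 0, ev_len[j])
      } else {
        out <- add(node, type, ev_len[j] / 2, ev_depth[j], 0)
        node <- add(out, type, 0, ev_depth[j], 0)
      }
      prev <- node
    }
    add(prev, type, 0, end_depth, 0)
    span
  }

  up_span <- build_trunk(rev(above), "apical", upward = TRUE)
  dn_span <- build_trunk(below, "basal", upward = FALSE)
  if (is.null(up_span)) up_span <- numeric(5)
  if (is.null(dn_span)) dn_span <- numeric(5)

  ## soma layer: basal stems around the soma
  if (!is.na(s_idx)) {
    rem_s <- len_t[s_idx] - up_span[s_idx] - dn_span[s_idx]
    if (rem_s < -1e-6)
      stop("unreachable laminar targets: trunk spans exceed the length ",
           "target in the soma layer ", lay5[s_idx])
    B <- bp_t[s_idx]
    if (rem_s > 1e-9 || B > 0) {
      stems <- max(1L, min(n_basal_stems, ceiling(rem_s / 200)))
      b_stem <- diff(round(seq(0, B, length.out = stems + 1L)))
      share <- rep(rem_s / stems, stems)
      for (s in seq_len(stems)) {
        azimuth <- azimuth + 2.399963
        dx <- cos(azimuth); dz <- sin(azimuth)
        b <- b_stem[s]
        if (b == 0L) {
          add(soma_id, "basal", share[s] * dx, soma_depth, share[s] * dz)
        } else {
          seg <- share[s] / (2 * b + 1)
          prev <- soma_id
          for (i in seq_len(b)) {
            node <- add(prev, "basal", i * seg * dx, soma_depth,
                        i * seg * dz)
            twig(node, "basal", i * seg * dx, soma_depth, i * seg * dz, seg)
            prev <- node
          }
          add(prev, "basal", (b + 1) * seg * dx, soma_depth,
              (b + 1) * seg * dz)
        }
      }
    }
  }

  nodes <- data.frame(id = nd$id, parent = nd$parent, type = nd$type,
                      x = nd$x, y = nd$y, z = nd$z, radius = nd$radius,
                      stringsAsFactors = FALSE)
  out <- neuron_morphology(nodes, depth_axis = "y")
  attr(out, "realized_targets") <- list(length = len_t, bp = bp_t,
                                        size_factor = f)
  out
}

## internal: allowed second targets for a dual-labeled cell (POm and Sp5C
## essentially never overlap)
dual_partners <- function(primary, groups) {
  excl <- switch(primary, POm = "Sp5C", Sp5C = "POm", character(0))
  setdiff(groups, c(primary, excl))
}

#' Generate a synthetic PT cohort
#'
#' Draws per-cell soma depths, ongoing rates, evoked-response parameters
#' and burst fractions from the group calibration (depths and ongoing
#' rates from Gaussians truncated at zero; onset/sustained elevations
#' Gaussian; probabilities clipped to `[0, 1]`), then delegates to
#' [generate_morphology()] and [generate_spike_trains()]. Dual-labeled
#' cells are appended as extra cells inheriting all parameters from their
#' primary group. Output is reproducible for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @param morphology generate dendritic morphologies? (Disable for
#'   physiology-only studies; much faster.)
#' @param trains generate spike trains?
#' @return an object of class `synthetic_cohort`: a list of cells, each
#'   with `cell_id`, `group` (primary target), `true_targets`, `dual`,
#'   `soma_depth`, `params` (realized per-cell rates), `morphology` and
#'   `trains`.
#' @export
generate_cohort <- function(config, morphology = TRUE, trains = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  glabels <- names(config$groups)
  ## phase 1: draw all per-cell parameters and sub-seeds up front
  plan <- list()
  for (g in glabels) {
    gp <- config$groups[[g]]
    for (i in seq_len(gp$n_cells))
      plan[[length(plan) + 1L]] <- list(group = g, dual = FALSE,
                                        second = NA_character_)
  }
  if (config$n_dual > 0) {
    wts <- vapply(config$groups, `[[`, integer(1), "n_cells")
    if (sum(wts) == 0) wts <- rep(1, length(wts))
    for (i in seq_len(config$n_dual)) {
      g <- sample(glabels, 1, prob = wts)
      plan[[length(plan) + 1L]] <-
        list(group = g, dual = TRUE,
             second = sample(dual_partners(g, glabels), 1))
    }
  }
  counts <- integer(length(glabels)); names(counts) <- glabels
  n_dual_seen <- 0L
  for (j in seq_along(plan)) {
    p <- plan[[j]]
    gp <- config$groups[[p$group]]
    params <- list(
      ongoing_rate = rtrunc_norm(1, gp$ongoing_rate_mean,
                                 gp$ongoing_rate_sd),
      onset_rate = stats::rnorm(1, gp$onset_rate_mean, gp$onset_rate_sd),
      sustained_rate = stats::rnorm(1, gp$sustained_rate_mean,
                                    gp$sustained_rate_sd),
      onset_prob = min(1, max(0, stats::rnorm(1, gp$onset_prob,
                                              gp$onset_prob_sd))),
      sustained_shape = gp$sustained_shape,
      burst100_frac = rtrunc_norm(1, gp$burst100_frac,
                                  0.5 * gp$burst100_frac),
      burst200_frac = rtrunc_norm(1, gp$burst200_frac,
                                  0.5 * gp$burst200_frac))
    params$burst200_frac <- min(params$burst200_frac, params$burst100_frac)
    depth <- rtrunc_norm(1, gp$depth_mean, gp$depth_sd)
    seeds <- sample.int(.Machine$integer.max - 1L, 2)
    if (p$dual) {
      n_dual_seen <- n_dual_seen + 1L
      id <- sprintf("dual_%02d", n_dual_seen)
    } else {
      counts[p$group] <- counts[p$group] + 1L
      id <- sprintf("%s_%02d", p$group, counts[p$group])
    }
    plan[[j]] <- c(p, list(cell_id = id, soma_depth = depth,
                           params = params, seeds = seeds))
  }
  ## phase 2: build morphologies and spike trains with the frozen seeds
  cells <- lapply(plan, function(p) {
    gp <- config$groups[[p$group]]
    structure(list(
      cell_id = p$cell_id, group = p$group,
      true_targets = if (p$dual) c(p$group, p$second) else p$group,
      dual = p$dual, soma_depth = p$soma_depth, params = p$params,
      morphology = if (morphology)
        generate_morphology(gp, p$soma_depth, seed = p$seeds[1]) else NULL,
      trains = if (trains)
        generate_spike_trains(p$params, config$n_trials, config$window,
                              seed = p$seeds[2],
                              config$stimulus_duration) else NULL),
      class = "synthetic_cell")
  })
  structure(cells, config = config, class = "synthetic_cohort")
}

#' Generate a synthetic multi-slice soma field with a NeuN reference
#'
#' Emulates serial 50 um slices through the barrel cortex after retrograde
#' labeling: all-neuron (NeuN) somata are drawn from the reference depth
#' profile (which has its peak in L4), labeled somata per target group
#' from the group depth Gaussians, and each slice carries an integer-bin
#' vertical jitter and a per-slice volume factor. The configured
#' per-column group abundances are recorded as ground truth so the
#' soma-density pipeline can be validated against them.
#'
#' @param config a [cohort_config()] supplying the group depth statistics
#'   and `cells_per_column` calibration.
#' @param seed optional integer seed.
#' @param n_slices number of slices.
#' @param volume_factor mean fraction of an average column's somata
#'   contained in one slice.
#' @param jitter_bins maximal vertical slice jitter in bins (bin width
#'   from the reference profile).
#' @param include_labeled generate labeled channels? `FALSE` yields a
#'   NeuN-only field.
#' @param reference a [density_profile()] of all neurons per average
#'   column.
#' @return an object of class `soma_field`: list with `slices` (data
#'   frames with `depth`, `channel`), `truth` (ground-truth per-column
#'   counts per group), `factors`, `shifts` and `reference`.
#' @export
generate_soma_field <- function(config, seed = NULL, n_slices = 10,
                                volume_factor = 0.5, jitter_bins = 2,
                                include_labeled = TRUE,
                                reference = reference_neun_profile()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  bw <- reference$bin_width
  grid_max <- reference$edges[length(reference$edges)]
  f <- volume_factor * stats::runif(n_slices, 0.85, 1.15)
  shifts <- sample(seq(-jitter_bins, jitter_bins), n_slices,
                   replace = TRUE)
  glabels <- if (include_labeled) names(config$groups) else character(0)
  clamp <- function(d) pmin(pmax(d, 0), grid_max - 1e-3)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    nb <- stats::rpois(length(reference$counts), f[k] * reference$counts)
    lo <- reference$edges[-length(reference$edges)]
    neun_d <- stats::runif(sum(nb), rep(lo, nb), rep(lo + bw, nb))
    depth <- clamp(neun_d + shifts[k] * bw)
    channel <- rep("NeuN", length(depth))
    for (g in glabels) {
      gp <- config$groups[[g]]
      m <- stats::rpois(1, f[k] * gp$cells_per_column)
      d <- clamp(rtrunc_norm(m, gp$depth_mean, gp$depth_sd) +
                 shifts[k] * bw)
      depth <- c(depth, d)
      channel <- c(channel, rep(g, m))
    }
    slices[[k]] <- data.frame(depth = depth, channel = channel,
                              stringsAsFactors = FALSE)
  }
  truth <- if (include_labeled)
    vapply(config$groups, `[[`, numeric(1), "cells_per_column") else
    numeric(0)
  structure(list(slices = slices, truth = truth, factors = f,
                 shifts = shifts, reference = reference),
            class = "soma_field")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  dual <- vapply(x, `[[`, logical(1), "dual")
  cat("Synthetic PT cohort: ", length(x), " cells (",
      paste(sprintf("%s: %d", names(table(groups)), table(groups)),
            collapse = ", "), "; ", sum(dual), " dual-labeled)\n",
      sep = "")
  invisible(x)
}

#' @export
print.soma_field <- function(x, ...) {
  cat("Synthetic soma field: ", length(x$slices), " slices, channels: ",
      paste(unique(x$slices[[1]]$channel), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
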