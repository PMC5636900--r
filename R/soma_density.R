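#' 1D soma density profile
#'
#' Bins soma depths into 50 um intervals along the vertical cortical axis.
#' Bins are half-open `[k * bw, (k + 1) * bw)` starting at depth 0.
#'
#' @param depths numeric vector of soma depths (um), all `>= 0`.
#' @param bin_width bin width in um (default 50).
#' @param max_depth depth extent of the profile grid (um); all profiles
#'   built on the same grid are directly comparable.
#' @return an object of class `density_profile`: list with `counts`,
#'   `bin_width` and `edges`.
#' @export
bin_profile <- function(depths, bin_width = 50, max_depth = 2000) {
  if (length(depths) && any(depths < 0))
    stop("soma depths must be >= 0")
  if (length(depths) && any(depths >= max_depth))
    stop("soma depth beyond the profile grid (", max_depth, " um)")
  edges <- seq(0, max_depth, by = bin_width)
  counts <- if (length(depths)) {
    graphics::hist(depths, breaks = edges, right = FALSE,
                   include.lowest = TRUE, plot = FALSE)$counts
  } else integer(length(edges) - 1L)
  density_profile(counts, bin_width)
}

#' @rdname bin_profile
#' @param counts integer vector of per-bin soma counts.
#' @export
density_profile <- function(counts, bin_width = 50) {
  if (any(counts < 0)) stop("profile counts must be >= 0")
  structure(list(counts = as.numeric(counts), bin_width = bin_width,
                 edges = seq(0, by = bin_width,
                             length.out = length(counts) + 1L)),
            class = "density_profile")
}

## internal: translate a profile by an integer number of bins (zero fill)
shift_profile <- function(profile, shift) {
  n <- length(profile$counts)
  out <- numeric(n)
  src <- seq_len(n) - shift
  ok <- src >= 1L & src <= n
  out[ok] <- profile$counts[src[ok]]
  profile$counts <- out
  profile
}

## internal: peak bin within a depth range; ties broken toward the
## shallowest bin
peak_bin <- function(profile, range) {
  lo <- profile$edges[-length(profile$edges)]
  in_range <- lo >= range[1] & lo < range[2]
  idx <- which(in_range)
  idx[which.max(profile$counts[idx])]
}

#' Align slice profiles by the L4 peak of the NeuN profile
#'
#' Each slice's profiles (the NeuN profile and any companion labeled-channel
#' profiles) are shifted by an integer number of bins so that the L4 peaks of
#' the NeuN profiles coincide with the median peak bin across slices. A
#' slice whose NeuN profile does not attain its maximum inside the L4 depth
#' range is excluded with a warning. Equal-height peaks resolve to the
#' shallowest bin.
#'
#' @param neun_profiles list of [density_profile()] objects, one per slice.
#' @param companions optional list (parallel to `neun_profiles`) of named
#'   lists of companion profiles to shift along with each slice.
#' @param l4_range depth range of L4 in um, default `c(600, 900)`.
#' @return list with `neun` (aligned NeuN profiles), `companions` (aligned
#'   companions), `shifts` (bins, per retained slice), `target_bin` and
#'   `excluded` (indices of excluded slices).
#' @export
align_by_l4_peak <- function(neun_profiles, companions = NULL,
                             l4_range = c(600, 900)) {
  stopifnot(is.list(neun_profiles), length(neun_profiles) >= 1L)
  peaks <- integer(length(neun_profiles))
  ok <- logical(length(neun_profiles))
  for (i in seq_along(neun_profiles)) {
    p <- neun_profiles[[i]]
    pk <- peak_bin(p, l4_range)
    ## the profile's global maximum must lie within L4
    ok[i] <- length(pk) == 1L && p$counts[pk] > 0 &&
      p$counts[pk] == max(p$counts)
    peaks[i] <- if (ok[i]) pk else NA_integer_
  }
  if (!any(ok))
    stop("no slice has its NeuN maximum within the L4 range")
  if (any(!ok))
    warning("excluding ", sum(!ok),
            " slice(s) without an L4 NeuN maximum")
  target <- as.integer(round(stats::median(peaks[ok])))
  shifts <- target - peaks[ok]
  keep <- which(ok)
  neun <- Map(shift_profile, neun_profiles[keep], shifts)
  comp <- NULL
  if (!is.null(companions)) {
    comp <- Map(function(slice, s) lapply(slice, shift_profile, shift = s),
                companions[keep], shifts)
  }
  list(neun = neun, companions = comp, shifts = shifts,
       target_bin = target, excluded = which(!ok))
}

#' Average profiles across slices
#'
#' @param profiles list of [density_profile()] objects on the same grid.
#' @return a [density_profile()] of mean per-bin counts.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  counts <- rowMeans(sapply(profiles, function(p) p$counts))
  density_profile(counts, profiles[[1]]$bin_width)
}

#' Amplitude scaling of a NeuN profile to a reference
#'
#' Finds the scale `s` minimizing the squared error
#' `sum((s * p - ref)^2)`, whose closed form is
#' `s = sum(p * ref) / sum(p^2)`. The fit is searched over a grid of
#' integer alignment shifts and the best shift is kept and reported.
#'
#' @param profile [density_profile()] to scale (e.g. the slice-average NeuN
#'   profile).
#' @param reference [density_profile()] in target units (e.g. neurons per
#'   average barrel column).
#' @param max_shift largest integer bin shift searched in both directions.
#' @return list of class `profile_fit` with `scale`, `shift`, `sse`.
#' @export
fit_scale <- function(profile, reference, max_shift = 4) {
  stopifnot(inherits(profile, "density_profile"),
            inherits(reference, "density_profile"))
  if (length(profile$counts) != length(reference$counts))
    stop("profile and reference must share the same grid")
  if (all(profile$counts == 0)) stop("cannot scale an all-zero profile")
  best <- NULL
  for (k in -max_shift:max_shift) {
    p <- shift_profile(profile, k)$counts
    den <- sum(p^2)
    if (den == 0) next
    s <- sum(p * reference$counts) / den
    sse <- sum((s * p - reference$counts)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(scale = s, shift = k, sse = sse)
  }
  class(best) <- "profile_fit"
  best
}

#' Labeled somata per average barrel column
#'
#' Scales a labeled-channel profile by the amplitude factor obtained from
#' the NeuN fit and sums it, giving the estimated number of labeled neurons
#' per average barrel column (the units of the reference profile).
#'
#' @param labeled_profile [density_profile()] of labeled somata (slice
#'   average).
#' @param fit a [fit_scale()] result from the same slice set's NeuN profile.
#' @return estimated count per average column.
#' @export
per_column_estimate <- function(labeled_profile, fit) {
  stopifnot(inherits(labeled_profile, "density_profile"),
            inherits(fit, "profile_fit"))
  fit$scale * sum(labeled_profile$counts)
}

#' Full soma-density pipeline on a multi-slice soma field
#'
#' Bins per-slice soma depths per channel, aligns slices by the L4 NeuN
#' peak, averages the aligned profiles, scales the average NeuN profile to
#' the reference by least squares and returns per-column estimates for each
#' labeled channel. Somata marked in several channels contribute to each of
#' their channels' profiles.
#'
#' @param slices list of data frames with columns `depth` (um) and
#'   `channel`; the NeuN channel must be present in each slice.
#' @param reference [density_profile()] of all neurons per average column.
#' @param neun_channel name of the all-neuron channel (default `"NeuN"`).
#' @param l4_range L4 depth range for alignment (um).
#' @param max_shift shift search radius for [fit_scale()].
#' @return list with `estimates` (named, per labeled channel), `fit`,
#'   `shifts`, `neun_avg` and `labeled_avg`.
#' @export
estimate_per_column <- function(slices, reference, neun_channel = "NeuN",
                                l4_range = c(600, 900), max_shift = 4) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  grid_max <- reference$edges[length(reference$edges)]
  bw <- reference$bin_width
  channels <- setdiff(unique(unlist(lapply(slices, function(s)
    unique(s$channel)))), neun_channel)
  neun <- list()
  comp <- list()
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!any(s$channel == neun_channel))
      stop("slice ", i, " has no '", neun_channel, "' somata")
    neun[[i]] <- bin_profile(s$depth[s$channel == neun_channel], bw,
                             grid_max)
    comp[[i]] <- lapply(stats::setNames(channels, channels), function(ch)
      bin_profile(s$depth[s$channel == ch], bw, grid_max))
  }
  al <- align_by_l4_peak(neun, comp, l4_range)
  neun_avg <- average_profiles(al$neun)
  fit <- fit_scale(neun_avg, reference, max_shift)
  labeled_avg <- lapply(stats::setNames(channels, channels), function(ch)
    average_profiles(lapply(al$companions, `[[`, ch)))
  estimates <- vapply(labeled_avg, per_column_estimate, numeric(1),
                      fit = fit)
  list(estimates = estimates, fit = fit, shifts = al$shifts,
       neun_avg = neun_avg, labeled_avg = labeled_avg)
}

#' Packaged synthetic reference NeuN profile
#'
#' A smooth, layered all-neuron depth profile for an average barrel column
#' (50 um bins, L4 peak), shipped as a plain-text fixture. It is a
#' synthetic stand-in constructed for self-contained runs and recovery
#' tests; users analysing real data should supply their own reference.
#'
#' @return a [density_profile()] in neurons per average column.
#' @export
reference_neun_profile <- function() {
  path <- system.file("extdata", "reference_neun_synthetic.csv",
                      package = "ptarget", mustWork = TRUE)
  ref <- utils::read.csv(path)
  density_profile(ref$neurons_per_column,
                  bin_width = ref$depth_hi[1] - ref$depth_lo[1])
}

#' @export
print.density_profile <- function(x, ...) {
  cat("Soma density profile: ", length(x$counts), " bins of ",
      x$bin_width, " um, total ", sprintf("%.0f", sum(x$counts)),
      " somata\n", sep = "")
  invisible(x)
}
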