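#' Normalized sensory-evoked PSTH
#'
#' Subtracts the ongoing rate from every bin, sets negative bins to zero,
#' then normalizes to the bin with the maximal rate. An all-zero PSTH stays
#' all-zero. The result lives in `[0, 1]` per bin and is the input to the
#' PSTH similarity measure.
#'
#' @param psth a [compute_psth()] object at the standard binning.
#' @param ongoing_rate ongoing rate in Hz to subtract from each bin.
#' @return an object of class `normalized_psth`: list with `values`
#'   (per-bin, in `[0, 1]`), `bin_width`, `window` and `ongoing_rate`.
#' @export
normalize_evoked <- function(psth, ongoing_rate) {
  stopifnot(inherits(psth, "psth"), is.numeric(ongoing_rate),
            length(ongoing_rate) == 1L)
  v <- pmax(psth$rate - ongoing_rate, 0)
  m <- max(v)
  if (m > 0) v <- v / m
  structure(list(values = v, bin_width = psth$bin_width,
                 window = psth$window, ongoing_rate = ongoing_rate),
            class = "normalized_psth")
}

## internal: check two normalized PSTHs share a binning
check_same_binning <- function(a, b) {
  if (!identical(length(a$values), length(b$values)) ||
      any(a$window != b$window) || a$bin_width != b$bin_width)
    stop("PSTHs have different windows or binnings")
}

#' PSTH similarity (bin-wise absolute difference sum)
#'
#' The bin-wise absolute difference between two normalized evoked PSTHs,
#' summed across the entire recording period. Smaller values mean more
#' similar PSTHs; 0 means identical. This is an L1 metric on the normalized
#' PSTH space.
#'
#' @param a,b [normalize_evoked()] objects on the same binning.
#' @return nonnegative dissimilarity sum.
#' @export
psth_similarity <- function(a, b) {
  stopifnot(inherits(a, "normalized_psth"), inherits(b, "normalized_psth"))
  check_same_binning(a, b)
  sum(abs(a$values - b$values))
}

#' Group-average PSTH templates
#'
#' Builds one normalized evoked PSTH per target group by averaging the raw
#' PSTHs of all cells with that label, subtracting the group-mean ongoing
#' rate, clamping negative bins and normalizing to the maximal bin.
#'
#' @param psths list of [compute_psth()] objects, one per cell.
#' @param ongoing_rates numeric vector of per-cell ongoing rates (Hz).
#' @param labels character vector of group labels per cell.
#' @param groups group names required to be present; defaults to the four
#'   subcortical targets.
#' @return named list of [normalize_evoked()] templates, one per group, of
#'   class `group_templates`.
#' @export
build_templates <- function(psths, ongoing_rates, labels,
                            groups = c("POm", "SC", "Pons", "Sp5C")) {
  stopifnot(length(psths) == length(labels),
            length(ongoing_rates) == length(labels))
  out <- vector("list", length(groups))
  names(out) <- groups
  for (g in groups) {
    idx <- which(labels == g)
    if (!length(idx))
      stop("no cells with label '", g, "' to build a template from")
    rates <- sapply(psths[idx], function(p) p$rate)
    avg <- psths[[idx[1]]]
    avg$rate <- rowMeans(rates)
    out[[g]] <- normalize_evoked(avg, mean(ongoing_rates[idx]))
  }
  class(out) <- "group_templates"
  out
}

#' Similarity indices of a cell against the group templates
#'
#' Computes the four dissimilarity sums of a cell's normalized evoked PSTH
#' to the group templates and combines them into two similarity indices:
#' `SI1 = (sim_Pons - sim_SC) / (sim_SC + sim_Pons)` and
#' `SI2 = (sim_Sp5C - sim_POm) / (sim_POm + sim_Sp5C)`. Both lie in
#' `[-1, 1]`; a zero denominator yields an index of 0 (neutral).
#'
#' @param cell a [normalize_evoked()] object.
#' @param templates a [build_templates()] object with templates `POm`,
#'   `SC`, `Pons` and `Sp5C`.
#' @return list with `similarity` (named numeric of the four sums), `SI1`
#'   and `SI2`, of class `similarity_indices`.
#' @export
similarity_indices <- function(cell, templates) {
  stopifnot(inherits(cell, "normalized_psth"),
            inherits(templates, "group_templates"))
  need <- c("POm", "SC", "Pons", "Sp5C")
  if (!all(need %in% names(templates)))
    stop("templates must contain groups ", paste(need, collapse = ", "))
  sim <- vapply(templates[need], function(tm) psth_similarity(cell, tm),
                numeric(1))
  ratio <- function(num, den) if (den == 0) 0 else num / den
  structure(list(similarity = sim,
                 SI1 = ratio(sim[["Pons"]] - sim[["SC"]],
                             sim[["SC"]] + sim[["Pons"]]),
                 SI2 = ratio(sim[["Sp5C"]] - sim[["POm"]],
                             sim[["POm"]] + sim[["Sp5C"]])),
            class = "similarity_indices")
}

#' @export
print.similarity_indices <- function(x, ...) {
  cat("PSTH similarity: ",
      paste(sprintf("%s=%.2f", names(x$similarity), x$similarity),
            collapse = ", "),
      sprintf("; SI1 = %.3f, SI2 = %.3f\n", x$SI1, x$SI2), sep = "")
  invisible(x)
}
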