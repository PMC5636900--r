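#' Cortical layer scheme
#'
#' Defines the vertical partition of the cortex into named layers. Depth is
#' measured in micrometres along the vertical cortical axis, with the pial
#' surface at 0. Layer intervals are half-open `[lo, hi)`, contiguous from 0.
#'
#' The default boundaries place the L5A/L5B border at 1050 um, the convention
#' used throughout the package to split layer 5 into its upper and lower
#' sublayers. All other boundaries are generic values for rat vibrissal
#' cortex and can be overridden.
#'
#' @param boundaries named numeric vector of upper layer boundaries (um),
#'   strictly increasing. Names are the layer names; the lower boundary of the
#'   first layer is 0.
#' @return an object of class `layer_scheme`: a data frame with columns
#'   `layer`, `lo`, `hi`.
#' @examples
#' layer_scheme()
#' @export
layer_scheme <- function(boundaries = c("L1" = 100, "L2/3" = 600, "L4" = 900,
                                        "L5A" = 1050, "L5B" = 1400,
                                        "L6" = 1850)) {
  if (is.null(names(boundaries)) || any(!nzchar(names(boundaries))))
    stop("layer boundaries must be named")
  if (any(!is.finite(boundaries)) || any(diff(c(0, boundaries)) <= 0))
    stop("layer boundaries must be finite and strictly increasing from 0")
  out <- data.frame(layer = names(boundaries),
                    lo = c(0, boundaries[-length(boundaries)]),
                    hi = unname(boundaries),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("layer_scheme", "data.frame")
  out
}

#' Layer membership of depths
#'
#' @param depth numeric vector of cortical depths (um). Negative depths are
#'   clipped to 0 (i.e. assigned to the most superficial layer); depths at or
#'   below the deepest boundary are assigned to the deepest layer.
#' @param layers a [layer_scheme()].
#' @return character vector of layer names.
#' @export
layer_of <- function(depth, layers = layer_scheme()) {
  stopifnot(inherits(layers, "layer_scheme"))
  d <- pmax(depth, 0)
  idx <- findInterval(d, c(layers$lo, layers$hi[nrow(layers)]),
                      rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(layers))
  layers$layer[idx]
}

#' @export
print.layer_scheme <- function(x, ...) {
  cat("Cortical layer scheme (depths in um, pia = 0):\n")
  print.data.frame(x, ...)
  invisible(x)
}
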