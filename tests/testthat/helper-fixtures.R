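# shared fixtures built in code (no stored data)

# a psth object with given per-bin rates (for unit tests of the
# similarity stage that need exact bin values)
make_psth <- function(rates, bin_width = 5, t0 = 0) {
  edges <- seq(t0, by = bin_width, length.out = length(rates) + 1L)
  structure(list(rate = rates, edges = edges, bin_width = bin_width,
                 n_trials = 1L, window = c(t0, edges[length(edges)]),
                 total_count = NA_integer_),
            class = "psth")
}

make_npsth <- function(values, bin_width = 5, t0 = 0) {
  normalize_evoked(make_psth(values / max(max(values), 1), bin_width, t0),
                   ongoing_rate = 0)
}

# hand-built morphology: soma plus a list of (parent, type, x, y, z) rows
make_morph <- function(rows, soma = c(0, 0, 0)) {
  df <- data.frame(id = 1L, parent = -1L, type = "soma",
                   x = soma[1], y = soma[2], z = soma[3], radius = 5,
                   stringsAsFactors = FALSE)
  for (r in rows) {
    df <- rbind(df, data.frame(id = nrow(df) + 1L,
                               parent = as.integer(r[[1]]), type = r[[2]],
                               x = r[[3]], y = r[[4]], z = r[[5]],
                               radius = 0.5, stringsAsFactors = FALSE))
  }
  neuron_morphology(df)
}

# independent oracle for laminar path length: sample every edge densely
# (0.1 um steps) and assign each step's length to the layer of its
# midpoint depth
dense_laminar_lengths <- function(morph, layers = layer_scheme(),
                                  step = 0.1) {
  n <- morph$nodes
  pos <- match(n$parent, n$id)
  out <- numeric(nrow(layers))
  names(out) <- layers$layer
  for (i in seq_len(nrow(n))[n$parent != -1L]) {
    if (n$type[i] == "soma") next
    p <- pos[i]
    len <- sqrt((n$x[i] - n$x[p])^2 + (n$y[i] - n$y[p])^2 +
                (n$z[i] - n$z[p])^2)
    if (len == 0) next
    k <- max(2L, ceiling(len / step))
    f <- (seq_len(k) - 0.5) / k
    d <- n[[morph$depth_axis]][p] + f * (n[[morph$depth_axis]][i] -
                                         n[[morph$depth_axis]][p])
    lay <- layer_of(d, layers)
    tab <- table(factor(lay, levels = layers$layer))
    out <- out + as.numeric(tab) * len / k
  }
  out
}

# upper regularized incomplete gamma Q(a, x) via pracma, the independent
# oracle for the chi-squared tail probability p = Q(df/2, d2/2)
chisq_tail_oracle <- function(d2, df) {
  vapply(d2, function(x) {
    g <- pracma::gammainc(x / 2, df / 2)
    unname(g["uppinc"] / gamma(df / 2))
  }, numeric(1))
}
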