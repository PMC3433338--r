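# Independent oracles and fixture builders used across the suite.

# Brute-force incorporation model: consume the read one base at a time,
# independent of the package's run-length implementation.
oracle_walk <- function(read, order) {
  rb <- strsplit(read, "")[[1]]
  ob <- strsplit(order, "")[[1]]
  out <- integer(length(ob))
  for (i in seq_along(ob)) {
    while (length(rb) > 0 && rb[1] == ob[i]) {
      out[i] <- out[i] + 1L
      rb <- rb[-1]
    }
  }
  out
}

# Brute-force 1-D mixture-fraction estimate by grid search.
oracle_grid_fit <- function(h, wt, mut, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  sse <- vapply(grid, function(f)
    sum((h - ((1 - f) * wt + f * mut))^2), numeric(1))
  grid[which.min(sse)]
}

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# Noiseless mixture pyrogram at a given instrument scale.
noiseless_pyrogram <- function(assay, variant = NULL, fraction = 0,
                               scale = 100) {
  synth_pyrogram(assay, variant = variant, fraction = fraction, scale = scale,
                 noise_sd = 0, nonspecific = c(0, 0))
}
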