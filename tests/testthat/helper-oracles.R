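# Independent brute-force oracles (per-cell loops, no shared code with the
# package internals) and small fixture builders.

bf_majority <- function(values, classes, f) {
  nr <- nrow(values) %/% f
  nc <- ncol(values) %/% f
  k <- length(classes)
  assign <- matrix(NA_integer_, nr, nc)
  fractions <- array(NA_real_, c(nr, nc, k))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      block <- values[((r - 1) * f + 1):(r * f), ((c - 1) * f + 1):(c * f)]
      block <- block[!is.na(block)]
      if (!length(block)) next
      counts <- sapply(seq_len(k), function(cls) sum(block == cls))
      fractions[r, c, ] <- counts / length(block)
      assign[r, c] <- which(counts == max(counts))[1]
    }
  }
  list(assign = assign, fractions = fractions)
}

bf_agreement <- function(mats) {
  out <- matrix(NA_integer_, nrow(mats[[1]]), ncol(mats[[1]]))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      votes <- sapply(mats, function(m) m[r, c])
      if (!anyNA(votes)) out[r, c] <- max(table(votes))
    }
  }
  out
}

bf_diversity <- function(mats) {
  out <- matrix(NA_integer_, nrow(mats[[1]]), ncol(mats[[1]]))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      votes <- sapply(mats, function(m) m[r, c])
      if (!anyNA(votes)) out[r, c] <- length(unique(votes))
    }
  }
  out
}

bf_transitions <- function(mats) {
  out <- matrix(NA_integer_, nrow(mats[[1]]), ncol(mats[[1]]))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      votes <- sapply(mats, function(m) m[r, c])
      if (!anyNA(votes)) out[r, c] <- sum(diff(votes) != 0)
    }
  }
  out
}

random_cat_raster <- function(nr, nc, k, na_frac = 0) {
  v <- sample.int(k, nr * nc, replace = TRUE)
  if (na_frac > 0) v[runif(nr * nc) < na_frac] <- NA_integer_
  categorical_raster(matrix(v, nr, nc), paste0("C", seq_len(k)))
}

# a small perfectly separable landscape: 4 disjoint boxes on MAT x MAP
separable_landscape <- function(nr = 30, nc = 30, seed = 11,
                                label_noise = 0) {
  specs <- list(
    variable_spec("MAT", 2, grad_row = 3, noise_amplitude = 0.05,
                  correlation_length = 4),
    variable_spec("MAP", 1000, grad_col = 800, noise_amplitude = 20,
                  correlation_length = 4, lower = 1)
  )
  rules <- list(
    niche_rule("A", list(MAT = c(-Inf, 2), MAP = c(-Inf, 1000)), 1),
    niche_rule("B", list(MAT = c(-Inf, 2), MAP = c(1000, Inf)), 2),
    niche_rule("C", list(MAT = c(2, Inf), MAP = c(-Inf, 1000)), 3),
    niche_rule("D", list(MAT = c(2, Inf), MAP = c(1000, Inf)), 4)
  )
  surface <- generate_climate_baseline(nr, nc, specs, seed = seed)
  veg <- generate_vegetation(surface, rules, fine_factor = 1,
                             label_noise = label_noise, seed = seed + 1)
  list(surface = surface, veg = veg$map, truth = veg$truth, rules = rules)
}

# uniform likelihood map from a matrix of per-cell vectors (rows = cells in
# row-major order)
lik_from_rows <- function(rows, nr, nc, classes) {
  likelihood_map(rows, nr, nc, classes)
}
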