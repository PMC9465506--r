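# Independent latent-state enumeration oracle for the CJS likelihood.
# The probability of a detection history, conditional on first detection at
# occasion f, is obtained by summing over the last occasion d at which the
# population was alive: survival over intervals f..d-1, death in interval d
# (unless it survived to T), and Bernoulli detection at alive occasions after
# f.  `p[j]` is detection at occasion j + 1 (length T - 1).
seq2 <- function(a, b) if (a > b) integer(0) else a:b

oracle_history_prob <- function(y, phi, p) {
  T <- length(y)
  f <- which(y == 1)[1]
  l <- max(which(y == 1))
  prob <- 0
  for (d in seq2(max(f, l), T)) {
    surv <- prod(phi[seq2(f, d - 1)]) * (if (d < T) 1 - phi[d] else 1)
    det <- 1
    for (j in seq2(f + 1, d)) {
      det <- det * (if (y[j] == 1) p[j - 1] else 1 - p[j - 1])
    }
    prob <- prob + surv * det
  }
  prob
}

# all suffix histories of length T with first detection at occasion f
all_suffix_histories <- function(T, f) {
  n_free <- T - f
  grid <- as.matrix(expand.grid(rep(list(0:1), n_free)))
  y <- matrix(0L, nrow(grid), T)
  y[, f] <- 1L
  if (n_free > 0) y[, (f + 1):T] <- grid
  y
}

# small record-table builder used across tests
make_records <- function(species, locality, country = "AT", year) {
  tibble::tibble(species = species, locality = locality,
                 country = country, year = as.integer(year))
}
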