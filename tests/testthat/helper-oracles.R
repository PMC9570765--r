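# Independent oracles and fixture builders used across the suite.

# brute-force Burden matrix: double loop over all atom pairs
oracle_burden <- function(mol, diag_vals) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$i[k]] <- deg[mol$bonds$i[k]] + 1L
    deg[mol$bonds$j[k]] <- deg[mol$bonds$j[k]] + 1L
  }
  B <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { B[i, j] <- diag_vals[i]; next }
    hit <- which((mol$bonds$i == i & mol$bonds$j == j) |
                 (mol$bonds$i == j & mol$bonds$j == i))
    if (length(hit)) {
      o <- if (isTRUE(mol$bonds$aromatic[hit[1]])) 1.5 else mol$bonds$order[hit[1]]
      B[i, j] <- 0.1 * o + if (deg[i] == 1L || deg[j] == 1L) 0.01 else 0
    } else {
      B[i, j] <- 0.001
    }
  }
  B
}

# eigen-summary oracle independent of eigen(): shift to positive definite,
# take singular values, shift back, interpolate at fractional ranks by hand
oracle_bcut_summary <- function(B) {
  n <- nrow(B)
  shift <- sum(abs(B)) + 1
  ev <- sort(svd(B + diag(shift, n))$d - shift)
  interp <- function(rank) {
    lo <- floor(rank); hi <- ceiling(rank)
    ev[lo] + (rank - lo) * (ev[hi] - ev[lo])
  }
  c(ev[1], interp(1 + (n - 1) / 3), interp(1 + 2 * (n - 1) / 3), ev[n])
}

# explicit-sum implementations of the evaluation statistics
oracle_pearson <- function(y, p) {
  N <- length(y)
  yb <- sum(y) / N; pb <- sum(p) / N
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_len(N)) {
    num <- num + (y[i] - yb) * (p[i] - pb)
    d1 <- d1 + (y[i] - yb)^2
    d2 <- d2 + (p[i] - pb)^2
  }
  num / sqrt(d1 * d2)
}
oracle_r2 <- function(y, p) {
  N <- length(y); yb <- sum(y) / N
  rss <- 0; tss <- 0
  for (i in seq_len(N)) {
    rss <- rss + (y[i] - p[i])^2
    tss <- tss + (y[i] - yb)^2
  }
  1 - rss / tss
}
oracle_rmse <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - p[i])^2
  sqrt(s / length(y))
}

# two well-separated Gaussian blobs (offset along every coordinate so the
# separation survives per-column standardization); matrix plus true labels
make_blobs <- function(n_per = 50, d = 8, sep = 12, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * d), ncol = d) - sep / 2,
    matrix(rnorm(n_per * d), ncol = d) + sep / 2
  )
  list(X = X, labels = rep(1:2, each = n_per))
}

# permute the atoms of a mol_graph (with bond reindexing)
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, ]
  bonds <- mol$bonds
  bonds$i <- inv[bonds$i]
  bonds$j <- inv[bonds$j]
  mol_graph(atoms[, c("element", "charge", "h_count")], bonds)
}

# tiny natural-alphabet encoded dataset with linear potency, for model tests
make_toy_encoded <- function(n = 60, seed = 3, noise_sd = 0,
                             beta = c(nt1_BCUT_SMR_3 = 1,
                                      nt2_BCUT_SLOGP_0 = -0.8)) {
  tab <- natural_descriptor_table()
  rec <- generate_sequences(n, L = 5L, alphabet = tab$NT, seed = seed)
  rec <- generate_potencies(rec, tab, beta = beta, noise_sd = noise_sd,
                            seed = seed + 1L)
  encode_dataset(rec, tab)
}
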