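# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Bray-Curtis over samples-in-rows matrix
bc_brute <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    out[i, j] <- num / den
  }
  out
}

# naive O(n^3) agglomeration under the Ward.D2 Lance-Williams update;
# returns the merge heights in order
ward_brute <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        a <- active[ii]; b <- active[jj]
        if (dm[a, b] < bd) { bd <- dm[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bd)
    na <- sizes[a]; nb <- sizes[b]
    for (k in active) {
      if (k == a || k == b) next
      nk <- sizes[k]
      dm[a, k] <- dm[k, a] <- sqrt(((na + nk) * dm[a, k]^2 +
                                    (nb + nk) * dm[b, k]^2 -
                                    nk * dm[a, b]^2) / (na + nb + nk))
    }
    sizes[a] <- na + nb
    active <- setdiff(active, b)
  }
  heights
}

# topological overlap from an adjacency matrix (diagonal 1), triple loop
tom_brute <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  out <- matrix(1, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive scan over occurrence pairs for the minimal gene-gap distance
gap_brute <- function(genome, famA, famB) {
  best <- NA_integer_
  for (rep_id in unique(genome$genes$replicon_id)) {
    sub <- genome$genes[genome$genes$replicon_id == rep_id, ]
    m <- nrow(sub)
    pa <- sub$rank[sub$family_id == famA]
    pb <- sub$rank[sub$family_id == famB]
    for (p in pa) for (q in pb) {
      d <- abs(p - q)
      if (genome$topology[[rep_id]] == "circular") d <- min(d, m - d)
      if (is.na(best) || d < best) best <- d
    }
  }
  best
}

# per-row / per-column filter survivors, by explicit counting
filter_samples_brute <- function(values, min_families) {
  keep <- character(0)
  for (s in colnames(values)) {
    n_det <- 0
    for (g in rownames(values)) if (values[g, s] > 0) n_det <- n_det + 1
    if (n_det > min_families) keep <- c(keep, s)
  }
  keep
}

filter_genes_brute <- function(values, min_cov, min_samples) {
  keep <- character(0)
  for (g in rownames(values)) {
    n_ok <- 0
    for (s in colnames(values)) if (values[g, s] > min_cov) n_ok <- n_ok + 1
    if (n_ok >= min_samples) keep <- c(keep, g)
  }
  keep
}
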