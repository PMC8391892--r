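# Shared fixtures and independent oracles used across the test files.

# a random piecewise-linear spectrum on a descending grid
random_spectrum <- function(n = 50, id = "s", seed = 1) {
  set.seed(seed)
  wn <- sort(runif(n, 700, 3900), decreasing = TRUE)
  spectrum(id, wn, runif(n, 0, 1))
}

# random uniform-grid spectrum (for Savitzky-Golay tests)
uniform_spectrum <- function(n = 101, id = "u", seed = 1, step = 2) {
  set.seed(seed)
  wn <- seq(3000, by = -step, length.out = n)
  spectrum(id, wn, rnorm(n))
}

# noiseless two-component calibration series at the study's 8 levels:
# X rows are mixtures of two fixed profiles, y the % v/v levels
two_component_set <- function(p = 12, seed = 1) {
  set.seed(seed)
  a <- runif(p); b <- runif(p)
  y <- c(0, 2, 4, 8, 16, 32, 64, 100)
  X <- t(vapply(y, function(l) (1 - l / 100) * a + (l / 100) * b, numeric(p)))
  list(X = X, y = y)
}

# ordinary least squares on centered data: the normal-equations oracle that
# full-rank PLSR/PCR must match
ols_oracle <- function(X, y) {
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  drop(solve(crossprod(Xc), crossprod(Xc, yc)))
}

# brute-force Ward agglomeration: at every step recompute, from scratch, the
# increase in total within-cluster sum of squares for every candidate pair
# and merge the cheapest (ties by smallest index pair). Heights are reported
# on the Euclidean scale, sqrt(2 * delta SS), matching ward.D2.
ward_bruteforce <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  active <- seq_len(n)   # id of each active cluster; leaves 1..n
  members <- clusters
  merges <- list()
  next_id <- n
  ss <- function(idx) {
    if (length(idx) == 1L) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2L, ctr)^2)
  }
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      d <- ss(c(members[[i]], members[[j]])) - ss(members[[i]]) - ss(members[[j]])
      if (is.null(best) || d < best$d - 1e-12) best <- list(i = i, j = j, d = d)
    }
    next_id <- next_id + 1L
    merges[[length(merges) + 1L]] <-
      list(ids = sort(c(active[best$i], active[best$j])),
           height = sqrt(2 * best$d))
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    active[best$i] <- next_id
    members[best$j] <- NULL
    active <- active[-best$j]
  }
  merges
}

# convert an ftir_dendrogram merge table to the same (leaf/cluster id) form
# as ward_bruteforce: leaves 1..n, internal nodes n+1, n+2, ...
dendrogram_merge_ids <- function(d) {
  n <- length(d$leaf_ids)
  lapply(seq_len(nrow(d$merges)), function(i) {
    conv <- function(j) if (j < 0) -j else n + j
    list(ids = sort(c(conv(d$merges$a[i]), conv(d$merges$b[i]))),
         height = d$merges$height[i])
  })
}
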