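# Shared fixtures and independent brute-force oracles.

# the 13 unique 3D offsets used by the texture matrices
oracle_dirs <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  # canonical sign: first non-zero component positive, then dedupe
  for (i in seq_len(nrow(d))) {
    nz <- which(d[i, ] != 0)[1]
    if (d[i, nz] < 0) d[i, ] <- -d[i, ]
  }
  unique(d)
}

# brute-force direction-averaged symmetric GLCM (normalised)
oracle_glcm <- function(levels) {
  dm <- dim(levels)
  ng <- max(levels)
  dirs <- oracle_dirs()
  p <- matrix(0, ng, ng)
  nd <- 0
  for (r in seq_len(nrow(dirs))) {
    cnt <- matrix(0, ng, ng)
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      a <- levels[i, j, k]
      if (a <= 0) next
      ii <- i + dirs[r, 1]; jj <- j + dirs[r, 2]; kk <- k + dirs[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > dm[1] || jj > dm[2] || kk > dm[3]) next
      b <- levels[ii, jj, kk]
      if (b <= 0) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) > 0) {
      p <- p + cnt / sum(cnt)
      nd <- nd + 1
    }
  }
  p / nd
}

# brute-force run-length matrices, one per direction
oracle_glrlm <- function(levels) {
  dm <- dim(levels)
  ng <- max(levels)
  maxlen <- max(dm)
  dirs <- oracle_dirs()
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > dm[1] || j > dm[2] || k > dm[3]) return(0L)
    levels[i, j, k]
  }
  lapply(seq_len(nrow(dirs)), function(r) {
    d <- dirs[r, ]
    R <- matrix(0, ng, maxlen)
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      a <- at(i, j, k)
      if (a <= 0) next
      if (at(i - d[1], j - d[2], k - d[3]) == a) next
      len <- 1
      while (at(i + len * d[1], j + len * d[2], k + len * d[3]) == a) {
        len <- len + 1
      }
      R[a, len] <- R[a, len] + 1
    }
    R
  })
}

# exhaustive-pair Harrell C
oracle_concordance <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    # i must be the earlier observed event
    if (event[i] != 1) next
    if (!(time[i] < time[j] || (time[i] == time[j] && event[j] == 0))) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# exhaustive-pair cumulative/dynamic AUC with marker low = case
oracle_time_auc <- function(marker, time, event, horizon) {
  case <- which(time <= horizon & event == 1)
  ctrl <- which(time > horizon)
  num <- 0
  for (i in case) for (j in ctrl) {
    if (marker[i] < marker[j]) num <- num + 1
    else if (marker[i] == marker[j]) num <- num + 0.5
  }
  num / (length(case) * length(ctrl))
}

# small deterministic phantom pair used across tests
small_sphere_phantom <- function(seed = 11) {
  generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                semi_axes_mm = c(8, 8, 8),
                                texture_corr_mm = 2, seed = seed))
}

# quick PH survival data for evaluation tests
simulate_ph <- function(n, beta, k = 1.4, lam = 15, cmax = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(beta)), n)
    eta <- drop(x %*% beta)
    tt <- lam * (-log(runif(n)) / exp(eta))^(1 / k)
    cc <- runif(n, 0, cmax)
    list(x = x, eta = eta, time = pmin(tt, cc),
         event = as.integer(tt <= cc))
  })
}
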