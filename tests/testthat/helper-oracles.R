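# Naive brute-force oracles, deliberately independent of the package's
# vectorized implementations: explicit per-voxel loops everywhere.

# random quantized VOI on a dims grid (random smooth-ish intensities,
# random blobby mask with at least a few voxels)
random_voi <- function(dims = c(6, 6, 3), G = 8, p_mask = 0.7) {
  vox <- array(stats::rnorm(prod(dims), sd = 10), dims)
  repeat {
    m <- array(stats::runif(prod(dims)) < p_mask, dims)
    if (sum(m) >= 4) break
  }
  quantize(vox, voi_mask(m), G = G)
}

glcm_offsets <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                     "135" = c(-1, -1))

# brute-force symmetric co-occurrence counts via triple loop
oracle_glcm_counts <- function(q, direction, distance = 1) {
  off <- glcm_offsets[[as.character(direction)]] * distance
  L <- q$levels
  dims <- dim(L)
  C <- matrix(0, q$G, q$G)
  for (k in seq_len(dims[3])) {
    for (i in seq_len(dims[1])) {
      for (j in seq_len(dims[2])) {
        a <- L[i, j, k]
        if (is.na(a)) next
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2]) next
        b <- L[i2, j2, k]
        if (is.na(b)) next
        C[a, b] <- C[a, b] + 1
        C[b, a] <- C[b, a] + 1
      }
    }
  }
  C
}

# naive GLCM features from a counts matrix, scalar loops
oracle_glcm_features <- function(C) {
  G <- nrow(C)
  tot <- sum(C)
  if (tot == 0) {
    return(c(energy = 1, contrast = 0, correlation = 1, entropy = 0,
             homogeneity = 1, dissimilarity = 0, sum_entropy = 0,
             cluster_shade = 0, cluster_prominence = 0))
  }
  P <- C / tot
  mu <- 0
  for (i in 1:G) for (j in 1:G) mu <- mu + i * P[i, j]
  s2 <- 0
  for (i in 1:G) for (j in 1:G) s2 <- s2 + (i - mu)^2 * P[i, j]
  en <- ct <- ey <- hm <- ds <- cs <- cp <- cr <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    en <- en + p^2
    ct <- ct + (i - j)^2 * p
    if (p > 0) ey <- ey - p * log2(p)
    hm <- hm + p / (1 + (i - j)^2)
    ds <- ds + abs(i - j) * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cr <- cr + (i - mu) * (j - mu) * p
  }
  cr <- if (s2 > 0) cr / s2 else 1
  se <- 0
  for (s in 2:(2 * G)) {
    ps <- 0
    for (i in 1:G) {
      j <- s - i
      if (j >= 1 && j <= G) ps <- ps + P[i, j]
    }
    if (ps > 0) se <- se - ps * log2(ps)
  }
  c(energy = en, contrast = ct, correlation = cr, entropy = ey,
    homogeneity = hm, dissimilarity = ds, sum_entropy = se,
    cluster_shade = cs, cluster_prominence = cp)
}

# enumerate maximal runs by walking each voxel: a run starts where the
# backward neighbor is absent/different, then is walked forward
oracle_runs <- function(q, direction) {
  off <- glcm_offsets[[as.character(direction)]]
  L <- q$levels
  dims <- dim(L)
  at <- function(i, j, k) {
    if (i < 1 || i > dims[1] || j < 1 || j > dims[2]) return(NA_integer_)
    L[i, j, k]
  }
  runs <- list()
  for (k in seq_len(dims[3])) {
    for (i in seq_len(dims[1])) {
      for (j in seq_len(dims[2])) {
        a <- L[i, j, k]
        if (is.na(a)) next
        prev <- at(i - off[1], j - off[2], k)
        if (!is.na(prev) && prev == a) next  # not a run start
        len <- 1
        i2 <- i + off[1]; j2 <- j + off[2]
        while (!is.na(at(i2, j2, k)) && at(i2, j2, k) == a) {
          len <- len + 1
          i2 <- i2 + off[1]; j2 <- j2 + off[2]
        }
        runs[[length(runs) + 1]] <- c(level = a, length = len)
      }
    }
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(runs, n_voxels) {
  Nr <- nrow(runs)
  g <- runs[, "level"]; l <- runs[, "length"]
  lev_counts <- table(g)
  len_counts <- table(l)
  c(short_run_emphasis = sum(1 / l^2) / Nr,
    long_run_emphasis = sum(l^2) / Nr,
    gray_level_nonuniformity = sum(as.numeric(lev_counts)^2) / Nr,
    run_length_nonuniformity = sum(as.numeric(len_counts)^2) / Nr,
    run_percentage = Nr / n_voxels,
    low_gray_run_emphasis = sum(1 / g^2) / Nr,
    high_gray_run_emphasis = sum(g^2) / Nr,
    short_run_low_gray_emphasis = sum(1 / (g^2 * l^2)) / Nr,
    short_run_high_gray_emphasis = sum(g^2 / l^2) / Nr,
    long_run_low_gray_emphasis = sum(l^2 / g^2) / Nr,
    long_run_high_gray_emphasis = sum(g^2 * l^2) / Nr)
}

# flood-fill connected components (26-connectivity) over equal levels
oracle_zones <- function(q) {
  L <- q$levels
  dims <- dim(L)
  seen <- array(FALSE, dims)
  zones <- list()
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (v in which(!is.na(L))) {
    if (seen[v]) next
    idx <- arrayInd(v, dims)
    lev <- L[v]
    stack <- list(idx)
    seen[v] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(nbrs))) {
        nb <- cur + nbrs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        val <- L[nb[1], nb[2], nb[3]]
        if (is.na(val) || val != lev) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1]] <- nb
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  do.call(rbind, zones)
}

oracle_glzsm_features <- function(zones) {
  Nz <- nrow(zones)
  g <- zones[, "level"]; s <- zones[, "size"]
  c(high_intensity_emphasis = sum(g^2) / Nz,
    high_intensity_large_area_emphasis = sum(g^2 * s^2) / Nz,
    low_intensity_emphasis = sum(1 / g^2) / Nz,
    low_intensity_large_area_emphasis = sum(s^2 / g^2) / Nz)
}

oracle_first_order <- function(q) {
  x <- q$raw
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lv <- q$levels[!is.na(q$levels)]
  p <- as.numeric(table(factor(lv, levels = 1:q$G))) / n
  pp <- p[p > 0]
  c(mean = mu, median = stats::median(x), minimum = min(x),
    maximum = max(x), range = max(x) - min(x), variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    energy = sum(p^2),
    entropy = -sum(pp * log2(pp)),
    uniformity = sum(p^2),
    mean_absolute_deviation = sum(abs(x - mu)) / n)
}

# dense projected-gradient solver for the soft-margin dual:
# min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0
oracle_qp_svm <- function(K, y, C, iters = 50000) {
  m <- length(y)
  Q <- (y %o% y) * K
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values))
  eta <- 1 / max(L, 1e-8)
  project <- function(a0) {
    # bisection on the multiplier of y'a = 0 over clip(a0 - lam*y, 0, C)
    f <- function(lam) sum(y * pmin(pmax(a0 - lam * y, 0), C))
    lo <- -1e6; hi <- 1e6
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a0 - (lo + hi) / 2 * y, 0), C)
  }
  a <- project(rep(0, m))
  for (it in seq_len(iters)) {
    g <- Q %*% a - 1
    a_new <- project(a - eta * g)
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  g <- as.vector(K %*% (a * y))
  free <- a > 1e-6 & a < C - 1e-6
  bias <- if (any(free)) mean(y[free] - g[free]) else {
    # midpoint of the feasible bias interval
    up <- (y > 0 & a < C - 1e-6) | (y < 0 & a > 1e-6)
    lo <- (y > 0 & a > 1e-6) | (y < 0 & a < C - 1e-6)
    ((max(y[up] - g[up])) + (min(y[lo] - g[lo]))) / 2
  }
  obj <- sum(a) - 0.5 * drop(crossprod(a, Q %*% a))
  list(alpha = as.vector(a), bias = bias, objective = obj)
}

# tie-halved concordant-pair AUC (rank-sum oracle)
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small in-memory voi_stack with four identical (or supplied) phase volumes
make_stack <- function(dims = c(8, 8, 4), intensities = NULL, mask = NULL,
                       recist = "PR", case_id = "t1", spacing = c(1, 1, 1)) {
  if (is.null(mask)) {
    mask <- array(FALSE, dims)
    mask[2:(dims[1] - 1), 2:(dims[2] - 1), ] <- TRUE
  }
  vols <- lapply(tace_phases, function(p) {
    v <- if (is.null(intensities)) {
      array(stats::rnorm(prod(dims), 100, 10), dims)
    } else if (is.list(intensities)) intensities[[p]] else intensities
    phase_volume(v, spacing = spacing, phase_id = p)
  })
  names(vols) <- tace_phases
  voi_stack(vols, voi_mask(mask), recist = recist, case_id = case_id)
}
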