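# straight-line reimplementation of one filter iteration, written
# independently with naive loops; used as the oracle for enhance()
oracle_one_iteration <- function(v, sigma = 1, rho = 1) {
  d <- dim(v)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  gauss1 <- function(arr, s) {
    r <- max(1, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    out <- arr
    for (axis in 1:3) {
      src <- out
      out <- array(0, d)
      for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
        acc <- 0
        for (o in -r:r) {
          i <- c(x, y, z); i[axis] <- reflect(i[axis] + o, d[axis])
          acc <- acc + k[o + r + 1] * src[i[1], i[2], i[3]]
        }
        out[x, y, z] <- acc
      }
    }
    out
  }
  at <- function(a, x, y, z) {  # replicate boundary
    a[min(max(x, 1), d[1]), min(max(y, 1), d[2]), min(max(z, 1), d[3])]
  }
  vh <- gauss1(v, sigma)
  grad <- function(a) {
    g <- array(0, c(d, 3))
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      g[x, y, z, 1] <- (at(a, x + 1, y, z) - at(a, x - 1, y, z)) / 2
      g[x, y, z, 2] <- (at(a, x, y + 1, z) - at(a, x, y - 1, z)) / 2
      g[x, y, z, 3] <- (at(a, x, y, z + 1) - at(a, x, y, z - 1)) / 2
    }
    g
  }
  g <- grad(vh)
  nvox <- prod(d)
  lam <- matrix(0, nvox, 3)
  vec <- matrix(0, nvox, 9)
  for (l in seq_len(nvox)) {
    idx <- arrayInd(l, d)
    gv <- g[idx[1], idx[2], idx[3], ]
    S <- outer(gv, gv)
    e <- eigen(S, symmetric = TRUE)
    lam[l, ] <- e$values
    vec[l, ] <- c(e$vectors[, 1], e$vectors[, 2], e$vectors[, 3])
  }
  intensity <- rowSums(lam)
  deg <- if (max(intensity) == 0) rep(TRUE, nvox) else
    intensity < 1e-12 * max(intensity)
  rng <- ifelse(deg, 0, (lam[, 1] - lam[, 3]) / pmax(intensity, 1e-300))
  sc <- quantile(intensity, 0.90, names = FALSE)
  inorm <- if (sc > 0) pmin(intensity / sc, 1) else intensity
  W <- abs((abs(rng - 0.5) + 0.5) - inorm)
  W[deg] <- 0
  alpha <- 0.001 * max(W)
  cap <- if (max(W) > 0.45) 0.45 / max(W) else 1
  W <- W * cap; alpha <- alpha * cap
  Dc <- lapply(1:6, function(j) array(0, d))
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (l in seq_len(nvox)) {
    e1 <- vec[l, 1:3]; e2 <- vec[l, 4:6]; e3 <- vec[l, 7:9]
    D <- alpha * outer(e1, e1) + W[l] * (outer(e2, e2) + outer(e3, e3))
    idx <- arrayInd(l, d)
    for (j in 1:6) Dc[[j]][idx[1], idx[2], idx[3]] <- D[pairs[j, 1], pairs[j, 2]]
  }
  Dc <- lapply(Dc, gauss1, s = rho)
  # flux from the smoothed-image gradient, divergence with anti-reflected ghosts
  f <- array(0, c(d, 3))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    gv <- g[x, y, z, ]
    D <- matrix(c(Dc[[1]][x, y, z], Dc[[4]][x, y, z], Dc[[5]][x, y, z],
                  Dc[[4]][x, y, z], Dc[[2]][x, y, z], Dc[[6]][x, y, z],
                  Dc[[5]][x, y, z], Dc[[6]][x, y, z], Dc[[3]][x, y, z]), 3)
    f[x, y, z, ] <- D %*% gv
  }
  fat <- function(x, y, z, c3) {  # anti-reflected ghost fluxes
    if (x < 1) return(-f[1, y, z, c3]); if (x > d[1]) return(-f[d[1], y, z, c3])
    if (y < 1) return(-f[x, 1, z, c3]); if (y > d[2]) return(-f[x, d[2], z, c3])
    if (z < 1) return(-f[x, y, 1, c3]); if (z > d[3]) return(-f[x, y, d[3], c3])
    f[x, y, z, c3]
  }
  out <- v
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    div <- (fat(x + 1, y, z, 1) - fat(x - 1, y, z, 1)) / 2 +
      (fat(x, y + 1, z, 2) - fat(x, y - 1, z, 2)) / 2 +
      (fat(x, y, z + 1, 3) - fat(x, y, z - 1, 3)) / 2
    out[x, y, z] <- v[x, y, z] + div
  }
  out
}

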