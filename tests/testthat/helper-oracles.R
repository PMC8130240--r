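# Independent brute-force oracles used by the unit and acceptance suites.

# explicit-loop oracle for one weighted LK iteration from a zero field
lk_oracle_once <- function(ref, flt, r, sigma, eig_factor, clip) {
  d <- dim(ref$data)
  g <- spatial_gradients(flt)
  gt <- flt$data - ref$data
  w1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  thresh <- eig_factor * sum(w1)^3
  disp <- array(0, c(d, 3))
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    S <- matrix(0, 3, 3); B <- numeric(3)
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      w <- w1[dz + r + 1] * w1[dy + r + 1] * w1[dx + r + 1]
      gv <- c(g$gz[zz, yy, xx], g$gy[zz, yy, xx], g$gx[zz, yy, xx])
      S <- S + w * gv %o% gv
      B <- B + w * gv * gt[zz, yy, xx]
    }
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > thresh
    v <- rep(0, 3)
    if (any(keep)) {
      inv <- e$vectors[, keep, drop = FALSE] %*%
        diag(1 / e$values[keep], sum(keep)) %*%
        t(e$vectors[, keep, drop = FALSE])
      v <- as.numeric(inv %*% (-B))
    }
    disp[z, y, x, ] <- pmin(pmax(v, -clip), clip)
  }
  disp
}

# exhaustive brute-force gamma over the same search grid
gamma_oracle <- function(ref, ev, mask, sy, sx, p) {
  bil <- function(m, y, x) {
    ny <- nrow(m); nx <- ncol(m)
    y <- min(max(y, 0), ny - 1); x <- min(max(x, 0), nx - 1)
    y0 <- min(floor(y), ny - 2); x0 <- min(floor(x), nx - 2)
    fy <- y - y0; fx <- x - x0
    m[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) + m[y0 + 2, x0 + 1] * fy * (1 - fx) +
      m[y0 + 1, x0 + 2] * (1 - fy) * fx + m[y0 + 2, x0 + 2] * fy * fx
  }
  n <- floor(p$search_radius_mm / p$search_step_mm + 1e-9)
  offs <- expand.grid(dy = (-n:n) * p$search_step_mm, dx = (-n:n) * p$search_step_mm)
  offs <- offs[offs$dy^2 + offs$dx^2 <= p$search_radius_mm^2 + 1e-12, ]
  out <- matrix(NA_real_, nrow(ref), ncol(ref))
  for (i in seq_len(nrow(ref))) for (j in seq_len(ncol(ref))) {
    if (!mask[i, j]) next
    rv <- ref[i, j]
    if (abs(rv) < p$low_cut) next
    denom <- p$dose_crit_pct / 100 * max(abs(rv), p$local_floor)
    best <- Inf
    for (k in seq_len(nrow(offs))) {
      evv <- bil(ev, i - 1 + offs$dy[k] / sy, j - 1 + offs$dx[k] / sx)
      g <- (offs$dy[k]^2 + offs$dx[k]^2) / p$dist_crit_mm^2 + ((evv - rv) / denom)^2
      best <- min(best, g)
    }
    out[i, j] <- sqrt(best)
  }
  out
}
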