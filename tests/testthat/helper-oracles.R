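# Independent brute-force oracles used across the suite. These are kept
# deliberately naive and separate from the package's implementations.

# Mann-Whitney: U from direct pair counting, two-sided p by enumerating
# every group assignment of the pooled values.
mw_oracle <- function(x, y) {
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  vals <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(vals), n1)
  u_obs <- ustat(x, y)
  mu <- n1 * length(y) / 2
  u_all <- apply(idx, 2, function(ii) ustat(vals[ii], vals[-ii]))
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Spearman: permutation p via cor(..., method = "spearman") on every
# permutation of y (n small).
all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  out
}

spearman_oracle <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  P <- all_perms(seq_along(y))
  rho_all <- apply(P, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# 26-connected component via plain per-voxel queue, independent of the
# package's padded-offset flood fill
flood_oracle <- function(thr, seed_lin) {
  d <- dim(thr)
  out <- array(FALSE, d)
  queue <- list(arrayInd(seed_lin, d)[1, ])
  out[seed_lin] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      w <- v + c(di, dj, dk)
      if (any(w < 1) || any(w > d)) next
      if (thr[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
  }
  out
}

# fine-grid trapezoid quadrature of a function on [0, t_end] minutes
trapz_quad <- function(f, t_end, dt = 1 / 600) {
  t <- seq(0, t_end, by = dt)
  y <- f(t)
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(t)))
}

# frame-average a fine-grid curve (independent re-implementation)
frame_avg_oracle <- function(y, t_s, schedule) {
  sapply(seq_along(schedule$starts_s), function(i) {
    a <- schedule$starts_s[i]; b <- a + schedule$durations_s[i]
    sel <- t_s >= a - 1e-9 & t_s <= b + 1e-9
    ys <- y[sel]; ts <- t_s[sel]
    sum((ys[-1] + ys[-length(ys)]) / 2 * diff(ts)) / (ts[length(ts)] - ts[1])
  })
}

# small random SUV-like image + mask pair for metric oracles
random_suv_phantom <- function(shape = c(8L, 9L, 7L), seed = 1) {
  set.seed(seed)
  vol <- image_volume(array(runif(prod(shape), 0.1, 5), shape),
                      spacing = c(0.4, 0.4, 0.4), units = "SUV")
  m <- array(runif(prod(shape)) < 0.4, shape)
  if (!any(m)) m[1, 1, 1] <- TRUE
  list(vol = vol, mask = voi_mask(m, spacing = vol$spacing))
}
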