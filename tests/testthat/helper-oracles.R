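# Independent oracles used by the tests. These deliberately re-implement
# the quantities they check through different algorithms / code paths.

# ---- scalar acoustic PSTD solver (base R fft), split-field PML -------------
# first-order pressure-velocity system on the same staggered grid; used as
# the reference for the fluid (mu = 0) limit of the elastic solver.
acou_deriv_sym <- function(n, dx, shift) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[1:n]
  k <- 2 * pi * f / (n * dx)
  1i * k * exp(1i * shift * k * dx / 2)
}

acoustic_oracle_run <- function(p0, rho, c0, grid, nt, dt, pml, sensors) {
  n1 <- grid$shape[1]; n2 <- grid$shape[2]
  dx <- grid$spacing
  mx_p <- acou_deriv_sym(n1, dx[1], +1); mx_m <- acou_deriv_sym(n1, dx[1], -1)
  my_p <- acou_deriv_sym(n2, dx[2], +1); my_m <- acou_deriv_sym(n2, dx[2], -1)
  Dx <- function(f, m) Re(mvfft(mvfft(f) * m, inverse = TRUE)) / n1
  Dy <- function(f, m) t(Re(mvfft(mvfft(t(f)) * m, inverse = TRUE)) / n2)
  lam <- rho * c0^2
  bx <- 2 / (rho + rho[c(2:n1, 1), ])
  by <- 2 / (rho + rho[, c(2:n2, 1)])
  pd <- depact:::.decay_vectors(grid, pml, dt, sqrt(max(c0^2)))
  A1i <- matrix(pd$i[[1]], n1, n2); A1h <- matrix(pd$h[[1]], n1, n2)
  A2i <- matrix(pd$i[[2]], n1, n2, byrow = TRUE)
  A2h <- matrix(pd$h[[2]], n1, n2, byrow = TRUE)
  iw <- depact:::.interp_weights(grid, sensors$positions)
  px <- p0 / 2; py <- p0 / 2
  vx <- matrix(0, n1, n2); vy <- matrix(0, n1, n2)
  trace <- matrix(0, nrow(iw$idx), nt)
  for (t in seq_len(nt)) {
    dtv <- if (t == 1) dt / 2 else dt
    p <- px + py
    vx <- A1h * (A1h * vx - dtv * bx * Dx(p, mx_p))
    vy <- A2h * (A2h * vy - dtv * by * Dy(p, my_p))
    px <- A1i * (A1i * px - dt * lam * Dx(vx, mx_m))
    py <- A2i * (A2i * py - dt * lam * Dy(vy, my_m))
    p <- px + py
    trace[, t] <- rowSums(matrix(p[iw$idx], nrow(iw$idx)) * iw$w)
  }
  trace
}

# ---- exact 1-D total variation proximal map (taut string / Condat) ---------
# direct O(n) algorithm; the reference for the iterative dual TV solver
tv1d_exact <- function(y, lambda) {
  n <- length(y)
  if (n == 1 || lambda <= 0) return(y)
  x <- numeric(n)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lambda; vmax <- y[1] + lambda
  umin <- lambda; umax <- -lambda
  repeat {
    if (k == n) {
      x[k0:n] <- vmin + umin
      break
    }
    if (y[k + 1] + umin < vmin - lambda) {
      x[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]; vmax <- y[k] + 2 * lambda
      umin <- lambda; umax <- -lambda
    } else if (y[k + 1] + umax > vmax + lambda) {
      x[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lambda; vmax <- y[k]
      umin <- lambda; umax <- -lambda
    } else {
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lambda) {
        vmin <- vmin + (umin - lambda) / (k - k0 + 1)
        umin <- lambda
        km <- k
      }
      if (umax <= -lambda) {
        vmax <- vmax + (umax + lambda) / (k - k0 + 1)
        umax <- -lambda
        kp <- k
      }
    }
    if (k == n) {
      if (umin < 0) {
        x[k0:km] <- vmin
        k <- k0 <- km <- km + 1L
        vmin <- y[k]
        umin <- lambda
        umax <- y[k] + lambda - vmax
      } else if (umax > 0) {
        x[k0:kp] <- vmax
        k <- k0 <- kp <- kp + 1L
        vmax <- y[k]
        umax <- -lambda
        umin <- y[k] - lambda - vmin
      } else {
        x[k0:n] <- vmin + umin / (k - k0 + 1)
        break
      }
    }
  }
  x
}

# sub-sample peak time (quadratic interpolation) of a trace, in samples
peak_time <- function(tr) {
  i <- which.max(abs(tr))
  if (i < 2 || i > length(tr) - 1) return(i)
  y1 <- abs(tr[i - 1]); y2 <- abs(tr[i]); y3 <- abs(tr[i + 1])
  i + 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
}

# relative dot-product discrepancy of an operator pair on random vectors
dot_test <- function(op, shape, seed = 1) {
  set.seed(seed)
  x <- array(stats::runif(prod(shape)), shape)
  y <- matrix(stats::rnorm(op$n_channels * op$nt), op$n_channels, op$nt)
  Ax <- op$apply(x)
  Aty <- op$adjoint(y)
  abs(sum(Ax * y) - sum(x * Aty)) / (sqrt(sum(Ax^2)) * sqrt(sum(y^2)))
}
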