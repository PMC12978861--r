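# Brute-force oracle for the latent-chain likelihood and conditional
# occupancy: explicit enumeration over all 2^T latent sequences, written
# independently of the package's forward-backward code.

oracle_site <- function(psi1, gamma, epsilon, p_mat, y_mat) {
  T <- nrow(p_mat)
  seqs <- as.matrix(expand.grid(rep(list(0:1), T)))
  pr <- apply(seqs, 1, function(z) {
    w <- if (z[1] == 1) psi1 else 1 - psi1
    if (T >= 2) {
      for (t in 2:T) {
        w <- w * if (z[t - 1] == 1) {
          if (z[t] == 1) 1 - epsilon[t - 1] else epsilon[t - 1]
        } else {
          if (z[t] == 1) gamma[t - 1] else 1 - gamma[t - 1]
        }
      }
    }
    for (t in seq_len(T)) {
      for (j in seq_len(ncol(y_mat))) {
        yv <- y_mat[t, j]
        if (!is.na(yv)) {
          w <- w * if (z[t] == 1) {
            if (yv == 1) p_mat[t, j] else 1 - p_mat[t, j]
          } else {
            if (yv == 1) 0 else 1
          }
        }
      }
    }
    w
  })
  lik <- sum(pr)
  cond <- vapply(seq_len(T), function(t) sum(pr[seqs[, t] == 1]) / lik,
                 numeric(1))
  list(lik = lik, cond_occ = cond)
}

oracle_study <- function(psi1, gamma, epsilon, p, y) {
  n <- dim(y)[1]; T <- dim(y)[2]
  per_site <- lapply(seq_len(n), function(i) {
    oracle_site(psi1[i],
                if (T >= 2) gamma[i, , drop = TRUE] else numeric(0),
                if (T >= 2) epsilon[i, , drop = TRUE] else numeric(0),
                matrix(p[i, , ], T), matrix(y[i, , ], T))
  })
  list(
    nll = -sum(log(vapply(per_site, `[[`, numeric(1), "lik"))),
    smoothed = do.call(rbind, lapply(per_site, `[[`, "cond_occ"))
  )
}

# random small instance: rates plus detections simulated from them, with
# random missingness (whole seasons and individual visits)
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(1:10, 1); T <- sample(1:4, 1); J <- sample(1:3, 1)
  psi1 <- runif(n, 0.05, 0.95)
  gamma <- matrix(runif(n * max(T - 1, 0), 0.05, 0.95), n)
  epsilon <- matrix(runif(n * max(T - 1, 0), 0.05, 0.95), n)
  p <- array(runif(n * T * J, 0.05, 0.95), dim = c(n, T, J))
  Z <- matrix(0L, n, T)
  Z[, 1] <- rbinom(n, 1, psi1)
  if (T >= 2) {
    for (t in 2:T) {
      Z[, t] <- rbinom(n, 1, Z[, t - 1] * (1 - epsilon[, t - 1]) +
                         (1 - Z[, t - 1]) * gamma[, t - 1])
    }
  }
  y <- array(rbinom(n * T * J, 1, rep(as.vector(Z), J) * as.vector(p)),
             dim = c(n, T, J))
  drop_season <- matrix(runif(n * T) < 0.3, n, T)
  y[array(rep(as.vector(drop_season), J), dim = c(n, T, J))] <- NA
  y[array(runif(n * T * J) < 0.15, dim = c(n, T, J))] <- NA
  list(n = n, T = T, J = J, psi1 = psi1, gamma = gamma, epsilon = epsilon,
       p = p, y = y, Z = Z)
}
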