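# Independent oracles used across the suite.

# brute-force eigensolver via the characteristic polynomial (polyroot) and
# null-space cross products -- deliberately independent of the package's
# analytic solver
brute_eig3 <- function(t6) {
  A <- matrix(c(t6[1], t6[2], t6[3],
                t6[2], t6[4], t6[5],
                t6[3], t6[5], t6[6]), 3, 3)
  tr <- sum(diag(A))
  m2 <- sum(diag(A)[c(1, 1, 2)] * diag(A)[c(2, 3, 3)]) -
    A[1, 2]^2 - A[1, 3]^2 - A[2, 3]^2
  dt <- det(A)
  # lambda^3 - tr lambda^2 + m2 lambda - det = 0
  lam <- sort(Re(polyroot(c(-dt, m2, -tr, 1))), decreasing = TRUE)
  # Newton-polish the roots: polyroot is only ~1e-8 accurate, which the
  # eigenvector conditioning (error ~ root error / eigen gap) amplifies
  for (k in 1:3) for (it in 1:3) {
    p <- lam[k]^3 - tr * lam[k]^2 + m2 * lam[k] - dt
    dp <- 3 * lam[k]^2 - 2 * tr * lam[k] + m2
    if (abs(dp) > 1e-300) lam[k] <- lam[k] - p / dp
  }
  B <- A - lam[1] * diag(3)
  cr <- list(pracma_cross3(B[1, ], B[2, ]),
             pracma_cross3(B[1, ], B[3, ]),
             pracma_cross3(B[2, ], B[3, ]))
  nn <- vapply(cr, function(v) sqrt(sum(v^2)), 0)
  v <- cr[[which.max(nn)]]
  v <- v / sqrt(sum(v^2))
  # inverse iteration: with near-degenerate leading eigenvalues the
  # cross-product vector only reaches (root error / eigen gap); shifting
  # slightly off the root and solving recovers the conditioning floor
  shift <- lam[1] * (1 + 1e-9) + 1e-12
  for (it in 1:3) {
    w <- tryCatch(solve(A - shift * diag(3), v), error = function(e) NULL)
    if (is.null(w)) break
    v <- w / sqrt(sum(w^2))
  }
  list(values = lam, vector = v)
}

pracma_cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

random_spd <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lam <- sort(runif(3, 0.1, 3), decreasing = TRUE)
  A <- Q %*% diag(lam) %*% t(Q)
  c(A[1, 1], A[1, 2], A[1, 3], A[2, 2], A[2, 3], A[3, 3])
}

runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(th), r * sin(th), z)
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# solid-angle null: P(angle in [a, b]) for uniform directions vs a fixed axis
null_bin_prob <- function(a_deg, b_deg) {
  cos(a_deg * pi / 180) - cos(b_deg * pi / 180)
}
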