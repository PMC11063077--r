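# Small internal geometry / hashing helpers.

# Rodrigues rotation matrix for unit axis u and angle theta (radians).
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotation matrix mapping unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a
    return(rotation_about(axis, pi))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Kabsch: rigid transform (rotation R, translation t) minimizing
# ||P - (Q R + t)||; returns the transformed Q.
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(Q, 2, cq) %*% t(R), 2, cp, `+`)
}

# Best-fit RMSD after optimal superposition (same atom order assumed).
fit_rmsd <- function(P, Q) {
  Qf <- kabsch_transform(P, Q)
  sqrt(mean(rowSums((P - Qf)^2)))
}

# Deterministic 32-bit string hash (djb2-style; doubles stay exact
# because h * 33 + b < 2^38 < 2^53), returned as 8-hex-digit text.
# Used for protocol change detection, not cryptography.
fnv1a <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
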