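# Small numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Angle between two vectors in degrees, clamped against rounding.
vangle <- function(a, b) {
  ct <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ct))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed dihedral (degrees, right-handed about axis) between the projections
# of v1 and v2 onto the plane normal to axis. Returns values in (-180, 180].
signedDihedral <- function(v1, v2, axis) {
  m <- unitv(axis)
  u1 <- v1 - sum(v1 * m) * m
  u2 <- v2 - sum(v2 * m) * m
  if (vnorm(u1) < 1e-10 || vnorm(u2) < 1e-10) return(NA_real_)
  ang <- atan2(sum(cross3(u1, u2) * m), sum(u1 * u2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Least-squares rigid superposition (Kabsch via SVD) of mobile onto fixed.
# Row-vector convention: transformed = mobile %*% R + rep(t, each = n).
kabsch <- function(fixed, mobile) {
  stopifnot(nrow(fixed) == nrow(mobile), nrow(fixed) >= 3)
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cf - as.vector(cm %*% R)
  moved <- sweep(mobile %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

applyTransform <- function(xyz, rotation, translation) {
  sweep(xyz %*% rotation, 2, translation, "+")
}

# 32-bit FNV-1a hash of a string, as 8 hex characters; used for stable,
# platform-independent design identifiers.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# (a * b) mod 2^32 without exceeding double-precision exact-integer range.
mulmod32 <- function(a, b) {
  hi <- a %/% 65536
  lo <- a %% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# XOR for non-negative doubles below 2^32 (base bitwXor is 32-bit signed).
bitwXor32 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    r <- r + p * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
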