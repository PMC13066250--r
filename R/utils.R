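# Internal voxel-array helpers. All morphology is face-connected (6-neighbour)
# and treats the volume border as background.

# shift a 3D logical array by one voxel along an axis, filling with FALSE
.shift1 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (by == 1L) {
    idx[[axis]] <- 2:n
    src[[axis]] <- 1:(n - 1L)
  } else {
    idx[[axis]] <- 1:(n - 1L)
    src[[axis]] <- 2:n
  }
  if (n > 1L) out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# binary dilation by r face-connected steps (city-block ball of radius r)
.dilate <- function(a, r) {
  for (i in seq_len(r)) {
    b <- a
    for (axis in 1:3) {
      b <- b | .shift1(a, axis, 1L) | .shift1(a, axis, -1L)
    }
    a <- b
  }
  a
}

# binary erosion by r face-connected steps (border counts as background)
.erode <- function(a, r) {
  for (i in seq_len(r)) {
    b <- a
    for (axis in 1:3) {
      b <- b & .shift1(a, axis, 1L) & .shift1(a, axis, -1L)
    }
    a <- b
  }
  a
}

# surface voxels: foreground with at least one face-adjacent background
# voxel; the volume border counts as background
.surface <- function(a) {
  inner <- a
  for (axis in 1:3) {
    inner <- inner & .shift1(a, axis, 1L) & .shift1(a, axis, -1L)
  }
  a & !inner
}

# physical coordinates (mm) of TRUE voxels: n x 3 matrix of centers
.coordsMM <- function(a, spacing) {
  idx <- which(a, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  sweep(idx, 2L, spacing, `*`)
}

# 26-neighbourhood (3x3x3 box) dilation/erosion by one step: separable as
# sequential +-1 dilation along each axis
.dilateBox1 <- function(a) {
  for (axis in 1:3) a <- a | .shift1(a, axis, 1L) | .shift1(a, axis, -1L)
  a
}

.erodeBox1 <- function(a) {
  for (axis in 1:3) a <- a & .shift1(a, axis, 1L) & .shift1(a, axis, -1L)
  a
}

# for each row of A (n x 3, mm), the Euclidean distance to the nearest row of
# B (m x 3, mm); chunked |a|^2 + |b|^2 - 2 a.b via BLAS, row minima via
# max.col (C level; apply() is far too slow here)
.nearestDist <- function(A, B, chunk = 2048L) {
  stopifnot(nrow(B) > 0L)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    Ac <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * tcrossprod(Ac, B)
    amin <- max.col(-d2, ties.method = "first")
    out[i:j] <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), amin)], 0))
    i <- j + 1L
  }
  out
}

# deterministic seed fan-out: one master seed, fixed arithmetic per stream,
# so adding cases never reshuffles existing ones; kept below 2^31
.childSeed <- function(master, case = 0L, stream = 0L) {
  (as.numeric(master) + 7919 * as.numeric(case) + 104729 * as.numeric(stream)) %%
    2147483647
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
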