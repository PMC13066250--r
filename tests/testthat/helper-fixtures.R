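# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's internal helpers: surfaces, hulls and null distributions are
# recomputed from first principles so the tests cross two routes.

# small mask from foreground voxel indices (n x 3 matrix or vector rows)
mask_from_voxels <- function(dim3, voxels, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dim3)
  if (length(voxels)) {
    if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3, byrow = TRUE)
    a[voxels] <- TRUE
  }
  BinaryMask(a, VoxelGrid(dim3, spacing))
}

random_mask <- function(dim3, p = 0.2, spacing = c(1, 1, 1)) {
  BinaryMask(array(runif(prod(dim3)) < p, dim3), VoxelGrid(dim3, spacing))
}

random_label_volume <- function(dim3, C) {
  LabelVolume(array(sample.int(C, prod(dim3), replace = TRUE) - 1L, dim3),
              nClasses = C)
}

# two-class probability field from a tumor-probability array
prob_field2 <- function(p, spacing = c(1, 1, 1)) {
  d <- dim(p)
  v <- array(0, c(d, 2))
  v[, , , 1] <- 1 - p
  v[, , , 2] <- p
  ProbabilityField(v, VoxelGrid(d, spacing))
}

onehot_from_labels <- function(lab, C) {
  oneHotEncode(LabelVolume(lab, nClasses = C))
}

# hand-built StapleResult for threshold / grid-search tests
staple_result_from_weights <- function(w, spacing = c(1, 1, 1)) {
  new("StapleResult", grid = VoxelGrid(dim(w), spacing), weights = w,
      sens = 0.9, spec = 0.9, prior = 0.5, iterations = 1L, converged = TRUE)
}

# --- independent oracles ----------------------------------------------------

# exhaustive all-pairs surface-distance HD-percentile oracle; surface and
# distances recomputed from scratch (padding + explicit neighbour offsets)
brute_hd <- function(predArr, truthArr, spacing, percentile = 95) {
  surf <- function(a) {
    d <- dim(a)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
    idx <- which(pad, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(idx))) {
      for (o in seq_len(6)) {
        if (!pad[idx[r, 1] + offs[o, 1], idx[r, 2] + offs[o, 2],
                 idx[r, 3] + offs[o, 3]]) { keep[r] <- TRUE; break }
      }
    }
    sweep(idx[keep, , drop = FALSE] - 1L, 2L, spacing, `*`)
  }
  A <- surf(predArr)
  B <- surf(truthArr)
  allmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      min(sqrt(colSums((t(Q) - P[i, ])^2)))
    }, numeric(1))
  }
  unname(quantile(c(allmin(A, B), allmin(B, A)), percentile / 100, type = 7))
}

# q is inside-or-on the convex hull of integer points P iff adding q leaves
# the hull area unchanged (shoelace on the chull polygon)
hull_contains <- function(P, q) {
  shoelace <- function(M) {
    h <- grDevices::chull(M[, 1], M[, 2])
    X <- M[h, 1]; Y <- M[h, 2]
    abs(sum(X * c(Y[-1], Y[1]) - c(X[-1], X[1]) * Y)) / 2
  }
  isTRUE(all.equal(shoelace(P), shoelace(rbind(P, q))))
}

# two-sided signed-rank p-value by full enumeration of all 2^n sign vectors
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# tiny heterogeneous-regime config on a reduced grid for unit tests
small_het_cfg <- function(nCases = 2L, seed = 1L, ...) {
  experimentConfig(nCases = nCases, gridShape = c(24L, 24L, 24L),
                   radiiRange = c(5, 7),
                   sensitivities = c(0.95, 0.85, 0.70), seed = seed, ...)
}
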