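## Shared fixtures and independent oracles for the test suite.  Oracles are
## deliberately naive (nested loops, exhaustive enumeration) and never call
## the code paths they check.

flatSurfaces <- function(nSlices, nAscans, ilm, ez, rpe) {
  LayerSurfaces(matrix(ilm, nSlices, nAscans),
                matrix(ez, nSlices, nAscans),
                matrix(rpe, nSlices, nAscans))
}

emptyFluid <- function(shape) {
  FluidMasks(array(FALSE, dim = shape), array(FALSE, dim = shape))
}

tinySpec <- function(...) {
  cohortSpec(nRebounder = 2L, nNonrebounder = 2L,
             volumeShape = c(8L, 24L, 12L), ...)
}

# --- dense 3D correlation oracle (reflect padding, matching the stated
# --- boundary policy), straight triple loop over the kernel support
denseConv3 <- function(arr, kDepth, kAscan, kSlice) {
  d <- dim(arr)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  cD <- (length(kDepth) - 1) %/% 2
  cA <- (length(kAscan) - 1) %/% 2
  cS <- (length(kSlice) - 1) %/% 2
  out <- array(0, dim = d)
  for (s in seq_len(d[1])) for (dd in seq_len(d[2])) for (a in seq_len(d[3])) {
    acc <- 0
    for (ts in seq_along(kSlice)) for (td in seq_along(kDepth))
      for (ta in seq_along(kAscan)) {
        si <- refl(s + ts - 1 - cS, d[1])
        di <- refl(dd + td - 1 - cD, d[2])
        ai <- refl(a + ta - 1 - cA, d[3])
        acc <- acc + kSlice[ts] * kDepth[td] * kAscan[ta] * arr[si, di, ai]
      }
    out[s, dd, a] <- acc
  }
  out
}

# --- brute-force per-voxel GLCM + Haralick statistics oracle: nested loops
# --- over the window, dense GLCM, formulas transcribed from the definitions
bruteHaralick <- function(arr, mask, w, nLevels, offsets) {
  d <- dim(arr)
  v <- arr[mask]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim = d)
  if (hi > lo)
    lev[] <- as.integer(pmin(pmax(floor((arr - lo) / (hi - lo) * nLevels),
                                  0), nLevels - 1))
  h <- (w - 1) %/% 2
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(idx), 13)
  for (vi in seq_len(nrow(idx))) {
    s0 <- idx[vi, 1]; d0 <- idx[vi, 2]; a0 <- idx[vi, 3]
    sR <- max(1, s0 - h):min(d[1], s0 + h)
    dR <- max(1, d0 - h):min(d[2], d0 + h)
    aR <- max(1, a0 - h):min(d[3], a0 + h)
    glcm <- matrix(0, nLevels, nLevels)
    for (s in sR) for (dd in dR) for (a in aR) {
      if (!mask[s, dd, a]) next
      for (o in seq_len(nrow(offsets))) {
        s2 <- s + offsets[o, 1]; d2 <- dd + offsets[o, 2]
        a2 <- a + offsets[o, 3]
        if (s2 %in% sR && d2 %in% dR && a2 %in% aR && mask[s2, d2, a2]) {
          i <- lev[s, dd, a] + 1L; j <- lev[s2, d2, a2] + 1L
          glcm[i, j] <- glcm[i, j] + 1
          glcm[j, i] <- glcm[j, i] + 1
        }
      }
    }
    tot <- sum(glcm)
    if (tot == 0) next
    p <- glcm / tot
    iL <- row(p) - 1; jL <- col(p) - 1
    px <- rowSums(p)
    mu <- sum((0:(nLevels - 1)) * px)
    varx <- sum(((0:(nLevels - 1)) - mu)^2 * px)
    psum <- vapply(0:(2 * nLevels - 2), function(k) sum(p[iL + jL == k]),
                   numeric(1))
    pdiff <- vapply(0:(nLevels - 1), function(k) sum(p[abs(iL - jL) == k]),
                    numeric(1))
    ent <- -sum(ifelse(p > 0, p * log(p), 0))
    sa <- sum((0:(2 * nLevels - 2)) * psum)
    da <- sum((0:(nLevels - 1)) * pdiff)
    hx <- -sum(ifelse(px > 0, px * log(px), 0))
    pxy <- outer(px, px)
    hxy1 <- -sum(ifelse(pxy > 0, p * log(pxy), 0))
    hxy2 <- -sum(ifelse(pxy > 0, pxy * log(pxy), 0))
    out[vi, ] <- c(
      sum(p^2),
      sum((iL - jL)^2 * p),
      if (varx > 1e-12) (sum(iL * jL * p) - mu^2) / varx else 0,
      varx,
      sum(p / (1 + (iL - jL)^2)),
      sa,
      sum(((0:(2 * nLevels - 2)) - sa)^2 * psum),
      -sum(ifelse(psum > 0, psum * log(psum), 0)),
      ent,
      sum(((0:(nLevels - 1)) - da)^2 * pdiff),
      -sum(ifelse(pdiff > 0, pdiff * log(pdiff), 0)),
      if (hx > 1e-12) (ent - hxy1) / hx else 0,
      {
        arg <- 1 - exp(-2 * (hxy2 - ent))
        if (arg > 0) sqrt(arg) else 0
      })
  }
  out
}

glcmOffsets <- function() {
  rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
        c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
        c(1, 1, 0), c(1, -1, 0),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# --- AUC oracle: explicit concordant / tied pair count
aucPairs <- function(scores, labels, positive = "rebounder") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) tot <- tot + 1
    else if (scores[i] == scores[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# --- exact Wilcoxon rank-sum p by enumeration of all group assignments
wilcoxExactEnum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  vals <- c(x, y)
  r <- rank(vals)
  wObs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}
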