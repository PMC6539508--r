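# Shared fixture builders. Everything is generated in code; no data files.

# A small random cube with strictly increasing wavelengths.
randomCube <- function(rows = 8L, cols = 8L, bands = 5L, seed = 1L,
                       calibrated = TRUE, rangeTag = "VNIR") {
  set.seed(seed)
  hyperCube(array(runif(rows * cols * bands), c(rows, cols, bands)),
            wavelengths = seq(500, by = 10, length.out = bands),
            rangeTag = rangeTag, isCalibrated = calibrated)
}

# A mask with three disjoint axis-aligned squares of the given side.
threeSquareMask <- function(n = 40L, side = 10L) {
  m <- matrix(FALSE, n, n)
  m[2:(1 + side), 2:(1 + side)] <- TRUE
  m[2:(1 + side), (n - side):(n - 1L)] <- TRUE
  m[(n - side):(n - 1L), 2:(1 + side)] <- TRUE
  m
}

# Tiny scene config for fast end-to-end tests: 2 slices per class.
tinySceneConfig <- function(seed = 1L, signalSplit = "both", ...) {
  sceneConfig(slicesPerClass = 2L, vnirShape = c(80L, 120L),
              signalSplit = signalSplit, seed = seed, ...)
}

# Brute-force GLCM oracle: explicit double loop over all pixel pairs.
bruteGLCM <- function(levels, L, drdc) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, L, L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + drdc[1L]; c2 <- c + drdc[2L]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    i <- levels[r, c]; j <- levels[r2, c2]
    if (i > 0 && j > 0) {
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

bruteGLCMStats <- function(P) {
  L <- nrow(P)
  contrast <- 0; dissim <- 0; homog <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    dissim <- dissim + abs(i - j) * P[i, j]
    homog <- homog + P[i, j] / (1 + (i - j)^2)
  }
  pi <- rowSums(P); pj <- colSums(P)
  mui <- sum((1:L) * pi); muj <- sum((1:L) * pj)
  sdi <- sqrt(sum(((1:L) - mui)^2 * pi))
  sdj <- sqrt(sum(((1:L) - muj)^2 * pj))
  corr <- 0
  if (sdi * sdj > 0) {
    for (i in 1:L) for (j in 1:L)
      corr <- corr + (i - mui) * (j - muj) * P[i, j]
    corr <- corr / (sdi * sdj)
  }
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = sqrt(sum(P^2)), correlation = corr)
}

# Brute-force GLRLM oracle: walk every line pixel by pixel.
bruteRuns <- function(levels, step) {
  nr <- nrow(levels); nc <- ncol(levels)
  starts <- list()
  for (r in 1:nr) for (c in 1:nc) {
    pr <- r - step[1L]; pc <- c - step[2L]
    inPrev <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc
    if (!inPrev) starts[[length(starts) + 1L]] <- c(r, c)
  }
  runs <- NULL
  for (s in starts) {
    r <- s[1L]; c <- s[2L]
    cur <- 0L; len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (v == cur) len <- len + 1L
      else {
        if (cur > 0L) runs <- rbind(runs, c(cur, len))
        cur <- v; len <- 1L
      }
      r <- r + step[1L]; c <- c + step[2L]
    }
    if (cur > 0L) runs <- rbind(runs, c(cur, len))
  }
  runs
}

bruteGLRLMStats <- function(runs) {
  i <- runs[, 1L]; j <- runs[, 2L]
  Nr <- nrow(runs); Np <- sum(j)
  gl <- sapply(split(seq_len(Nr), i), length)
  rl <- sapply(split(seq_len(Nr), j), length)
  c(SRE = sum(1 / j^2) / Nr, LRE = sum(j^2) / Nr, GLN = sum(gl^2) / Nr,
    RP = Nr / Np, RLN = sum(rl^2) / Nr, LGLRE = sum(1 / i^2) / Nr,
    HGLRE = sum(i^2) / Nr)
}

# Independent BFS flood fill for component labelling.
bruteFloodFill <- function(mask, diag8 = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (diag8) offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextLab
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        r <- p[1L] + o[1L]; c <- p[2L] + o[2L]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}
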