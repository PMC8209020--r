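# Constructors and independent brute-force oracles used across the suite.

mkMask <- function(m, umpp = 1) new("BinaryMask", mask = m, umPerPx = umpp)
mkSkel <- function(m, umpp = 1) new("SkeletonImage", skeleton = m,
                                    umPerPx = umpp)

# adjacency-weighted length by exhaustive pair enumeration (µm)
bruteLengthUm <- function(m, umpp = 1) {
  co <- which(m, arr.ind = TRUE)
  n <- nrow(co)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    dr <- abs(co[(i + 1L):n, 1L] - co[i, 1L])
    dc <- abs(co[(i + 1L):n, 2L] - co[i, 2L])
    adj <- dr <= 1L & dc <= 1L
    tot <- tot + sum(adj & (dr + dc) < 2L) + sqrt(2) * sum(adj & dr + dc == 2L)
  }
  tot * umpp
}

# branch-point count by exhaustive neighbor enumeration + union-find merge
bruteBranchCount <- function(m) {
  co <- which(m, arr.ind = TRUE)
  n <- nrow(co)
  if (n == 0L) return(0L)
  deg <- integer(n)
  for (i in seq_len(n))
    deg[i] <- sum(abs(co[, 1L] - co[i, 1L]) <= 1L &
                    abs(co[, 2L] - co[i, 2L]) <= 1L) - 1L
  jc <- co[deg >= 3L, , drop = FALSE]
  k <- nrow(jc)
  if (k == 0L) return(0L)
  lab <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (lab[i] != lab[j] && abs(jc[i, 1L] - jc[j, 1L]) <= 1L &&
          abs(jc[i, 2L] - jc[j, 2L]) <= 1L) {
        l <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- l
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
}

# local mean with symmetric-reflect padding, direct double loop
bruteLocalMean <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- (w - 1L) %/% 2L
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1L))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1L))
  p <- m[ri, ci]
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc))
    out[r, cc] <- mean(p[r:(r + w - 1L), cc:(cc + w - 1L)])
  out
}

# number of 8-connected components by flood fill over coordinates
bruteComponentCount <- function(m) {
  co <- which(m, arr.ind = TRUE)
  n <- nrow(co)
  if (n == 0L) return(0L)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(lab == 0L & abs(co[, 1L] - co[j, 1L]) <= 1L &
                    abs(co[, 2L] - co[j, 2L]) <= 1L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

# noiseless, shading-free, artifact-free twin of a spec: same seed, same
# geometry, clean attenuation from which the true coverage can be inverted
cleanTwin <- function(spec) {
  spec@noiseSd <- 0
  spec@shadingAmplitude <- 0
  spec@nBlobArtifacts <- 0L
  spec
}

# true foreground mask at native resolution (coverage > 0.5)
trueMask <- function(spec) {
  g <- generateNetwork(cleanTwin(spec))
  cov <- (1 - imageMatrix(g$image) / 0.82) / spec@stainContrast
  mkMask(cov > 0.5, spec@umPerPx)
}
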