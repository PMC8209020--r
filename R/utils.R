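# Internal raster helpers shared by segmentation and morphometry.

# out[r, c] <- m[r - dr, c - dc]; cells shifted in from outside get `fill`.
shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rSrc <- seq_len(nr) - dr
  cSrc <- seq_len(nc) - dc
  rOk <- rSrc >= 1L & rSrc <= nr
  cOk <- cSrc >= 1L & cSrc <= nc
  out[rOk, cOk] <- m[rSrc[rOk], cSrc[cOk]]
  out
}

# offsets of the 8-neighborhood, clockwise from north
NBR8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
              dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# number of TRUE 8-neighbors of every pixel
neighborCount8 <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L))
    s <- s + shiftMat(m, NBR8[k, 1L], NBR8[k, 2L], FALSE)
  s
}

# symmetric reflection padding (edge pixel included in the mirror)
reflectPad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  if (pad >= nr || pad >= nc)
    stop("padding exceeds image size; window too large for this image")
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1L))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1L))
  if (pad == 0L) m else m[ri, ci]
}

# local mean over a w x w window with symmetric-reflect padding,
# computed with a summed-area table
localMean <- function(m, w) {
  pad <- (w - 1L) %/% 2L
  p <- reflectPad(m, pad)
  # summed-area table with a leading zero row/column
  sat <- rbind(0, apply(p, 2L, cumsum))
  sat <- cbind(0, t(apply(sat, 1L, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); r2 <- r1 + w - 1L
  c1 <- seq_len(nc); c2 <- c1 + w - 1L
  # window sum via inclusion-exclusion on the padded table
  s <- sat[r2 + 1L, c2 + 1L] - sat[r1, c2 + 1L] -
       sat[r2 + 1L, c1] + sat[r1, c1]
  s / (w * w)
}

# 8-connected component labels; 0 = background. Uses igraph for the
# union-find (EBImage::bwlabel is 4-connected).
labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  edges <- NULL
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    both <- mask & shiftMat(mask, sh[1L], sh[2L], FALSE)
    to <- which(both)
    if (length(to)) {
      from <- to - sh[1L] - sh[2L] * nr
      edges <- rbind(edges, cbind(from, to))
    }
  }
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(vid[edges[, 1L]], vid[edges[, 2L]]))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# evaluate thunk with the global RNG seeded at `seed`, restoring the
# caller's RNG state afterwards
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
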