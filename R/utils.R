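# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# Shift a 3D logical/numeric array by one voxel along an axis, zero-filling.
shift3 <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_src[[axis]] <- seq_len(d[axis] - by)
    idx_dst[[axis]] <- seq(by + 1L, d[axis])
  } else {
    idx_src[[axis]] <- seq(1L - by, d[axis])
    idx_dst[[axis]] <- seq_len(d[axis] + by)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-connected dilation / erosion on a 3D logical array.
dilate6 <- function(x) {
  x | shift3(x, 1, 1) | shift3(x, 1, -1) |
    shift3(x, 2, 1) | shift3(x, 2, -1) |
    shift3(x, 3, 1) | shift3(x, 3, -1)
}

erode6 <- function(x) {
  !dilate6(!x)
}

# 4-connected dilation / erosion on a 2D logical matrix (zero outside).
shift2 <- function(x, axis, by) {
  d <- dim(x)
  out <- matrix(FALSE, d[1], d[2])
  if (axis == 1) {
    if (by > 0) out[(by + 1):d[1], ] <- x[1:(d[1] - by), ]
    else out[1:(d[1] + by), ] <- x[(1 - by):d[1], ]
  } else {
    if (by > 0) out[, (by + 1):d[2]] <- x[, 1:(d[2] - by)]
    else out[, 1:(d[2] + by)] <- x[, (1 - by):d[2]]
  }
  out
}

dilate4 <- function(x) {
  x | shift2(x, 1, 1) | shift2(x, 1, -1) | shift2(x, 2, 1) | shift2(x, 2, -1)
}

erode4 <- function(x) !dilate4(!x)

# Largest 2D connected component (8-connectivity) of a logical matrix,
# via graph components on the pixel adjacency graph.
largest_component2d <- function(x) {
  idx <- which(x)
  if (!length(idx)) return(x)
  nr <- nrow(x); nc <- ncol(x)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  pairs <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    ok <- r + off[1] >= 1L & r + off[1] <= nr &
      c + off[2] >= 1L & c + off[2] <= nc
    nb <- idx[ok] + off[1] + off[2] * nr
    ok2 <- x[nb]
    pairs <- rbind(pairs, cbind(id[idx[ok][ok2]], id[nb[ok2]]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    # no adjacencies: every pixel its own component; keep the first
    out <- matrix(FALSE, nr, nc)
    out[idx[1]] <- TRUE
    return(out)
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- matrix(FALSE, nr, nc)
  out[idx[keep]] <- TRUE
  out
}

# Bounding box of TRUE entries in a logical matrix: rows/cols ranges.
bbox2d <- function(x) {
  idx <- which(x, arr.ind = TRUE)
  list(r = range(idx[, 1]), c = range(idx[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
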