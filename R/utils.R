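# Internal helpers shared across modules.

# Classed error so callers (and the CLI) can distinguish failure kinds.
iris_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "irisseg_error")))
}

iris_warn <- function(message, class = "irisseg_warning") {
  warning(warningCondition(message, class = c(class, "irisseg_warning")))
}

# Shift a 3D logical/numeric array by (dz, dr, dc), filling vacated cells.
shift3 <- function(a, dz, dr, dc, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  rs <- max(1, 1 + dr):min(d[2], d[2] + dr)
  cs <- max(1, 1 + dc):min(d[3], d[3] + dc)
  if (length(zs) < 1 || length(rs) < 1 || length(cs) < 1) return(out)
  out[zs, rs, cs] <- a[zs - dz, rs - dr, cs - dc]
  out
}

# Shift a 2D matrix by (dr, dc).
shift2 <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# In-plane Euclidean disk offsets (dr, dc) with dr^2 + dc^2 <= radius^2.
disk_offsets <- function(radius) {
  r <- as.integer(floor(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Run an expression with a private RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Label connected components of a 3D logical array (6-connectivity).
# Returns an integer array: 0 = background, 1..k = component labels ordered
# by their first voxel in (slice, row, col)-major scan order.
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  vid <- integer(prod(d))
  vid[idx] <- seq_along(idx)

  edges <- list()
  if (d[1] > 1) {
    both <- mask[-d[1], , , drop = FALSE] & mask[-1, , , drop = FALSE]
    w <- which(both)
    if (length(w)) {
      a <- arrayInd(w, dim(both))
      lin <- a[, 1] + (a[, 2] - 1) * d[1] + (a[, 3] - 1) * d[1] * d[2]
      edges[[length(edges) + 1L]] <- cbind(lin, lin + 1L)
    }
  }
  if (d[2] > 1) {
    both <- mask[, -d[2], , drop = FALSE] & mask[, -1, , drop = FALSE]
    w <- which(both)
    if (length(w)) {
      a <- arrayInd(w, dim(both))
      lin <- a[, 1] + (a[, 2] - 1) * d[1] + (a[, 3] - 1) * d[1] * d[2]
      edges[[length(edges) + 1L]] <- cbind(lin, lin + d[1])
    }
  }
  if (d[3] > 1) {
    both <- mask[, , -d[3], drop = FALSE] & mask[, , -1, drop = FALSE]
    w <- which(both)
    if (length(w)) {
      a <- arrayInd(w, dim(both))
      lin <- a[, 1] + (a[, 2] - 1) * d[1] + (a[, 3] - 1) * d[1] * d[2]
      edges[[length(edges) + 1L]] <- cbind(lin, lin + d[1] * d[2])
    }
  }

  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(vid[e[, 1]], vid[e[, 2]]))
  }
  memb <- igraph::components(g)$membership
  # relabel so components are numbered by first occurrence in scan order
  first <- !duplicated(memb)
  relabel <- integer(max(memb))
  relabel[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relabel[memb]
  lab
}

# Bounds check for a (slice, row, col) coordinate against array dims.
in_bounds <- function(coord, d) {
  length(coord) == 3 && all(coord >= 1) && all(coord <= d) &&
    all(coord == floor(coord))
}
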