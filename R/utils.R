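# Internal helpers shared across modules.

# mclust resolves mclustBIC and the per-model density functions in the
# caller's scope; alias them here so calls from this namespace work without
# attaching mclust.
mclustBIC <- mclust::mclustBIC
cdensVVV <- mclust::cdensVVV
cdensEEE <- mclust::cdensEEE
cdensV <- mclust::cdensV
cdensE <- mclust::cdensE
meVVV <- mclust::meVVV
meEEE <- mclust::meEEE
meV <- mclust::meV
meE <- mclust::meE

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Moore-Penrose pseudoinverse via SVD.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# H x W (row = y) matrix <-> EBImage's x-major convention.
.asEB <- function(m) t(m)
.fromEB <- function(m) t(m)

# Tight 0-based half-open bounding box (x0, y0, x1, y1) of a binary mask.
.maskBBox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

# Number of 4-connected foreground components.
.countComponents <- function(mask) {
  lab <- .fromEB(EBImage::bwlabel(.asEB((mask > 0) * 1)))
  max(lab)
}

# Largest 4-connected component of a binary mask (as 0/1 matrix).
.largestComponent <- function(mask) {
  lab <- .fromEB(EBImage::bwlabel(.asEB((mask > 0) * 1)))
  if (max(lab) == 0) return(mask * 0)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

# Fill 4-connected background holes: background regions not connected to the
# frame border are turned into foreground.
.fillHoles <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- mask <= 0
  lab <- matrix(0L, h, w)
  lab[bg] <- .labelComponents4(bg)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0]
  out <- (mask > 0) | (bg & !(lab %in% border))
  out * 1
}

# Like .fillHoles, but only fills holes up to `cap` pixels.
.fillHolesCapped <- function(mask, cap) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- mask <= 0
  if (!any(bg)) return(mask)
  lab <- matrix(0L, h, w)
  lab[bg] <- .labelComponents4(bg)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  sizes <- tabulate(lab[lab > 0])
  fillable <- setdiff(which(sizes <= cap), border)
  out <- (mask > 0) | (bg & lab %in% fillable)
  out * 1
}

# 4-connectivity labelling of TRUE cells; returns labels for those cells in
# matrix order (used by .fillHoles). Simple two-pass via igraph components.
.labelComponents4 <- function(sel) {
  h <- nrow(sel); w <- ncol(sel)
  id <- matrix(0L, h, w)
  id[sel] <- seq_len(sum(sel))
  e <- NULL
  right <- sel[, -w, drop = FALSE] & sel[, -1, drop = FALSE]
  if (any(right)) {
    a <- id[, -w, drop = FALSE][right]; b <- id[, -1, drop = FALSE][right]
    e <- rbind(e, cbind(a, b))
  }
  down <- sel[-h, , drop = FALSE] & sel[-1, , drop = FALSE]
  if (any(down)) {
    a <- id[-h, , drop = FALSE][down]; b <- id[-1, , drop = FALSE][down]
    e <- rbind(e, cbind(a, b))
  }
  n <- sum(sel)
  if (n == 0) return(integer(0))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(e)) g <- igraph::add_edges(g, t(e))
  as.integer(igraph::components(g)$membership)
}

# Hex colour string -> unit-length CMY vector.
.hexToCmyUnit <- function(hex) {
  rgb <- as.numeric(col2rgb(hex))
  .unit(1 - rgb / 255)
}
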