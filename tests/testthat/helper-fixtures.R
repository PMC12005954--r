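# Small fixtures shared across tests. Everything is generated in code; the
# 96^3 phantom and registration fixtures are cached per session because
# several files reuse them.

small_volume <- function(dims = c(8L, 8L, 8L), value = 0,
                         spacing = c(1, 1, 1)) {
  new_volume(array(value, dims), spacing = spacing)
}

ramp_volume <- function(dims = c(12L, 12L, 12L)) {
  g <- .mapply(function(i, j, k) i + 2 * j + 3 * k,
               expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                           k = seq_len(dims[3])), NULL)
  new_volume(array(unlist(g), dims))
}

# session-cached default phantom (windowed) and its labels
.fixture_env <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    ph <- make_phantom(phantom_spec())
    .fixture_env$phantom <- list(
      raw = ph$volume,
      windowed = apply_soft_tissue_window(ph$volume),
      labels = ph$labels)
  }
  .fixture_env$phantom
}

# small phantom for cheap tests
fixture_small_phantom <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- phantom_spec(shape = c(48L, 48L, 48L), texture_knot = 8L)
    ph <- make_phantom(spec)
    .fixture_env$small <- list(
      spec = spec,
      raw = ph$volume,
      windowed = apply_soft_tissue_window(ph$volume),
      labels = ph$labels)
  }
  .fixture_env$small
}

# random 12-DOF affine within the study's parameter ranges
random_affine <- function() {
  sc <- diag(stats::runif(3, 0.9, 1.15))
  sh <- diag(3); sh[upper.tri(sh)] <- stats::runif(3, -0.1, 0.1)
  ang <- stats::runif(3, -10, 10) * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  affine_transform(sc %*% sh %*% Rx %*% Ry %*% Rz, stats::runif(3, -10, 10))
}

# brute-force directed Hausdorff oracle (O(n*m))
brute_hausdorff <- function(P, G) {
  dmin <- apply(P, 1, function(p)
    min(sqrt(colSums((t(G) - p)^2))))
  max(dmin)
}

# brute-force joint minimization oracle for the tree-regularized objective on
# a path lattice (n <= 3 control points): enumerates all labelings
brute_tree_argmin <- function(costs, cands, alpha, quant) {
  n <- nrow(costs); m <- ncol(costs)
  states <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  pen <- function(a, b) alpha * sum((cands[a, ] - cands[b, ])^2) / quant^2
  best <- Inf; bestlab <- NULL
  for (r in seq_len(nrow(states))) {
    lab <- states[r, ]
    obj <- sum(costs[cbind(seq_len(n), lab)])
    if (n > 1) for (e in seq_len(n - 1)) obj <- obj + pen(lab[e], lab[e + 1])
    if (obj < best - 1e-12) { best <- obj; bestlab <- lab }
  }
  list(lab = bestlab, objective = best)
}
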