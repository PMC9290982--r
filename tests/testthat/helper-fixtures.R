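# Shared fixtures and independent oracles used across the test files.

# Brute-force all-pairs voxel marking oracle: open iff the distance from
# the voxel center to every atom (center or vdW surface, by mode)
# exceeds the probe radius.  Deliberately independent of the package's
# stamping implementation.
brute_force_open <- function(s, grid) {
  at <- s$atom
  off <- if (grid$mode == "vdw") helixweak:::vdw_radius(at$elesy) else 0
  dims <- grid$dim
  open <- array(TRUE, dims)
  coords <- as.matrix(expand.grid(
    x = grid$origin[1] + (seq_len(dims[1]) - 1) * grid$spacing,
    y = grid$origin[2] + (seq_len(dims[2]) - 1) * grid$spacing,
    z = grid$origin[3] + (seq_len(dims[3]) - 1) * grid$spacing))
  # expand.grid varies x fastest, matching R's array linear order
  mind <- rep(Inf, nrow(coords))
  for (a in seq_len(nrow(at))) {
    d <- sqrt((coords[, 1] - at$x[a])^2 + (coords[, 2] - at$y[a])^2 +
                (coords[, 3] - at$z[a])^2) - (if (length(off) > 1) off[a] else off)
    mind <- pmin(mind, d)
  }
  array(mind > grid$probe, dims)
}

# Random atom cloud structure.
random_cloud <- function(n = 50, seed = 1, extent = 8) {
  set.seed(seed)
  atom <- data.frame(chain = "X", resno = seq_len(n), insert = "",
                     resid = "UNK", elety = "C",
                     elesy = sample(c("C", "N", "O", "S"), n, replace = TRUE),
                     het = TRUE,
                     x = runif(n, 0, extent), y = runif(n, 0, extent),
                     z = runif(n, 0, extent), stringsAsFactors = FALSE)
  hw_structure(atom, id = paste0("cloud", seed))
}

# Deterministic axis-angle rotation-grid oracle for the optimal
# superposition RMSD: a coarse global grid followed by local refinement,
# evaluating plain least-squares RMSD after centroid alignment.
oracle_superpose_rmsd <- function(mobile, reference) {
  a <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  b <- sweep(as.matrix(reference), 2, colMeans(reference))
  ev <- function(v) {
    ang <- sqrt(sum(v^2))
    r <- if (ang < 1e-12) diag(3)
    else helixweak:::rotation_matrix(v / ang, ang * 180 / pi)
    sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  }
  # coarse global grid over rotation vectors (Fibonacci axes x angles)
  nf <- 100
  i <- seq_len(nf) - 0.5
  zf <- 1 - 2 * i / nf
  rho <- sqrt(pmax(0, 1 - zf^2))
  th <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(rho * cos(th), rho * sin(th), zf)
  best_v <- c(0, 0, 0)
  best <- ev(best_v)
  for (k in seq_len(nf)) for (ang in seq(10, 180, by = 10) * pi / 180) {
    v <- dirs[k, ] * ang
    r <- ev(v)
    if (r < best) { best <- r; best_v <- v }
  }
  # pattern search in rotation-vector space
  step <- 0.15
  while (step > 1e-6) {
    improved <- FALSE
    for (dim in 1:3) for (sgn in c(-1, 1)) {
      v <- best_v
      v[dim] <- v[dim] + sgn * step
      r <- ev(v)
      if (r < best) { best <- r; best_v <- v; improved <- TRUE }
    }
    if (!improved) step <- step / 2
  }
  best
}
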