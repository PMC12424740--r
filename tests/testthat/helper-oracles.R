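# Shared helpers: small numerical oracles used across test files.

rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Euler-angle rotation matrix (independent of the package's Kabsch path)
euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

# brute-force minimum superposition RMSD via rotation-grid search with a
# local refinement, independent of the SVD solution
grid_superpose_rmsd <- function(A, B, coarse = 10) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
  }
  grid <- seq(-pi, pi, by = coarse * pi / 180)
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < bestv) { bestv <- v; best <- c(a, b, c) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$value
}

# standard-normal Gumbel draws shaped L x 20, all zero (deterministic limit)
zero_gumbel <- function(L) matrix(0, L, 20L)

# add small random perturbations to every parameter of a denoiser so that
# the zero-initialized gates/heads produce non-trivial outputs in tests
randomize_denoiser <- function(model, sd = 0.05, seed = 1) {
  set.seed(seed)
  model$params <- lapply(model$params, function(p) {
    p + sd * stats::rnorm(length(p))
  })
  model
}
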