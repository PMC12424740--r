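test_that("linear survival schedule has the required endpoints and slope", {
  expect_equal(alpha_linear(0), 1)
  expect_equal(alpha_linear(1), 0)
  expect_equal(alpha_linear(0.25), 0.75)
  expect_error(alpha_linear(1.5), "outside")
})

test_that("forward masking keeps positions with probability alpha_t", {
  s0 <- rep(3L, 10)
  expect_identical(mask_forward(s0, 0, seed = 1)$tokens, s0)
  expect_true(all(mask_forward(s0, 1, seed = 1)$tokens == mask_token()))
  L <- 1e4
  st <- mask_forward(rep(1L, L), 0.5, seed = 2)$tokens
  frac <- mean(st == mask_token())
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / L))
  expect_error(mask_forward(c(1L, 21L), 0.5), "mask-free")
})

test_that("reverse posterior carries unmasked tokens and splits masked mass exactly", {
  x0_hat <- c(rep(0, 20), 0); x0_hat[3] <- 1
  # unmasked token: delta
  p <- reverse_posterior(5L, x0_hat, 0.75, 0.5)
  expect_equal(p[5], 1); expect_equal(sum(p), 1)
  # masked, alpha_t = 0.5, alpha_s = 0.75, point-mass prediction on token 3
  p <- reverse_posterior(mask_token(), x0_hat, 0.75, 0.5)
  expect_equal(p[3], 0.5)
  expect_equal(p[mask_token()], 0.5)
  # normalization on random simplex inputs
  set.seed(3)
  for (i in 1:10) {
    q <- c(rexp(20), 0); q <- q / sum(q)
    expect_equal(sum(reverse_posterior(mask_token(), q, 0.9, 0.4)), 1)
  }
  expect_error(reverse_posterior(mask_token(), x0_hat, 0.4, 0.5), "alpha_s")
})

test_that("sequence loss supervises only masked positions with weight 1 - t", {
  L <- 4
  expect_equal(seq_loss(matrix(rnorm(L * 21), L, 21), rep(1L, L), rep(2L, L), 0.3), 0)
  # uniform logits over the amino acids, all masked, t = 0.25
  expect_equal(seq_loss(matrix(0, L, 21), rep(1L, L), rep(21L, L), 0.25),
               0.75 * log(20), tolerance = 1e-10)
  # near-perfect logits drive the loss to zero
  lg <- matrix(-50, L, 21); lg[cbind(1:L, c(1L, 4L, 2L, 7L))] <- 50
  expect_lt(seq_loss(lg, c(1L, 4L, 2L, 7L), rep(21L, L), 0.25), 1e-8)
  # invariance to logits at unmasked positions
  st <- c(21L, 5L, 21L, 5L)
  lg1 <- matrix(rnorm(L * 21), L, 21)
  lg2 <- lg1; lg2[c(2, 4), ] <- rnorm(42)
  expect_equal(seq_loss(lg1, rep(2L, L), st, 0.6),
               seq_loss(lg2, rep(2L, L), st, 0.6))
})

test_that("path-planning keep-set size follows L_free - round(s * L_free) exactly", {
  st <- path_planning_step(matrix(rnorm(210), 10, 21), rep(21L, 10), 0.4, 1)
  expect_length(attr(st, "keep_set"), 6L)
  # s = 0 unmasks everything
  st0 <- path_planning_step(matrix(rnorm(210), 10, 21), rep(21L, 10), 0, 0.5)
  expect_true(all(st0$tokens != mask_token()))
  # exhaustive size check over L <= 64 and a grid of s
  for (L in 1:64) {
    lg <- matrix(rnorm(L * 21), L, 21)
    for (s in c(0.1, 0.25, 0.5, 0.9)) {
      st <- path_planning_step(lg, rep(21L, L), s, 1)
      k_expect <- L - floor(s * L + 0.5)   # half-away-from-zero
      expect_length(attr(st, "keep_set"), k_expect)
      expect_equal(sum(st$tokens == mask_token()), L - k_expect)
    }
  }
  expect_error(path_planning_step(matrix(0, 4, 21), rep(21L, 4), 0.5, 0.5),
               "s < t")
})

test_that("zero-noise path-planning reduces to the greedy ranking oracle", {
  set.seed(4)
  L <- 8
  lg <- matrix(rnorm(L * 21), L, 21)
  gamma <- 1e-3
  st <- path_planning_step(lg, rep(21L, L), s = 0.5, t = 1, gamma = gamma,
                           noise = zero_gumbel(L))
  # oracle: per-position argmax over amino-acid logits; keep-set = top
  # max-log-softmax positions (computed without the package's path)
  scaled <- lg[, 1:20] / gamma
  ls <- scaled - apply(scaled, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  y_star <- apply(lg[, 1:20], 1, which.max)
  u_star <- ls[cbind(1:L, y_star)]
  k <- L - round(0.5 * L)
  keep_star <- sort(order(-u_star)[1:k])
  expect_identical(attr(st, "keep_set"), keep_star)
  expect_identical(st$tokens[keep_star], y_star[keep_star])
  expect_true(all(st$tokens[-keep_star] == mask_token()))
})

test_that("co-generation mode carries current tokens and can re-mask them", {
  L <- 4
  # adversarial logits: position 2 already unmasked but its token has very
  # low model probability; positions 1,3,4 masked with confident logits
  lg <- matrix(-5, L, 21)
  lg[1, 1] <- 10; lg[3, 2] <- 10; lg[4, 3] <- 10
  lg[2, ] <- 0   # uniform: low max confidence for the carried token
  st_in <- c(21L, 7L, 21L, 21L)
  st <- path_planning_step(lg, st_in, s = 0.25, t = 0.5, gamma = 0.5,
                           mode = "cogeneration", noise = zero_gumbel(L))
  # keep-set has size 3; position 2's carried confidence ranks last -> re-masked
  expect_false(2L %in% attr(st, "keep_set"))
  expect_identical(st$tokens[2], mask_token())
})

test_that("clamped positions are never masked or resampled", {
  L <- 6
  set.seed(5)
  for (i in 1:10) {
    lg <- matrix(rnorm(L * 21), L, 21)
    st_in <- c(4L, 21L, 21L, 9L, 21L, 21L)
    st <- path_planning_step(lg, st_in, s = 0.6, t = 0.9, clamp = c(1L, 4L))
    expect_identical(st$tokens[c(1, 4)], c(4L, 9L))
    # k counts only free positions
    expect_length(attr(st, "keep_set"), 4L - round(0.6 * 4))
  }
  expect_error(path_planning_step(matrix(0, 4, 21), rep(21L, 4), 0.5, 1,
                                  clamp = 9L))
})

test_that("ancestral sampling with the exact posterior recovers an enumerable joint", {
  joint <- enumerate_discrete_joint(4, 3, seed = 6)
  n <- 2e4
  draws <- sample_sequence(joint$model, L = 3, n_steps = 12,
                           mode = "ancestral", seed = 7, n_samples = n)
  key <- (draws[, 1] - 1) * 16 + (draws[, 2] - 1) * 4 + draws[, 3]
  emp <- tabulate(key, nbins = 64) / n
  truth <- numeric(64)
  for (r in seq_len(nrow(joint$sequences))) {
    s <- joint$sequences[r, ]
    truth[(s[1] - 1) * 16 + (s[2] - 1) * 4 + s[3]] <- joint$probs[r]
  }
  tv <- 0.5 * sum(abs(emp - truth))
  expect_lt(tv, 0.05)
})

test_that("sequence rollout honours clamping and seeding contracts", {
  joint <- enumerate_discrete_joint(4, 3, seed = 8)
  clamp <- list(positions = 1:3, tokens = c(2L, 1L, 4L))
  out <- sample_sequence(joint$model, 3, n_steps = 4, clamp = clamp, seed = 9)
  expect_identical(out$tokens, c(2L, 1L, 4L))
  a <- sample_sequence(joint$model, 3, n_steps = 6, seed = 10)
  b <- sample_sequence(joint$model, 3, n_steps = 6, seed = 10)
  expect_identical(a$tokens, b$tokens)
  expect_error(sample_sequence(joint$model, 3, clamp = list(positions = 5L,
                                                            tokens = 1L)),
               "out of range")
})

test_that("inverse folding samples one position per step at low temperature", {
  # L = 1: a single categorical draw
  lg1 <- matrix(0, 1, 21); lg1[1, 7] <- 5
  model1 <- function(tokens, t) lg1
  out <- inverse_fold_sample(model1, 1, seed = 11)
  expect_length(out$tokens, 1L)
  expect_false(out$tokens == mask_token())
  # temperature-0 limit: argmax regardless of unmasking order
  L <- 6
  lg <- matrix(rnorm(L * 21), L, 21)
  model <- function(tokens, t) lg
  for (seed in 1:5) {
    out <- inverse_fold_sample(model, L, temperature = 0, seed = seed)
    expect_identical(out$tokens, apply(lg[, 1:20], 1, which.max))
  }
})

test_that("inverse folding recovers the toy generating sequence from geometry", {
  spec <- toy_family_spec(length = 20, noise_sd = 0)
  p <- make_toy_protein(spec, seed = 12)
  # stub model: reads classes off the structure's local geometry
  toks <- toy_inverse_fold(p$structure$coords, spec)
  stub <- function(tokens, t) {
    lg <- matrix(-30, length(toks), 21)
    lg[cbind(seq_along(toks), toks)] <- 30
    lg
  }
  out <- inverse_fold_sample(stub, 20, seed = 13)
  expect_identical(out$tokens, p$sequence$tokens)
})
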