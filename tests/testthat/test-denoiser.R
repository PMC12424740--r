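tiny_cfg <- denoiser_config(n_blocks = 2L, hidden_dim = 64L, n_heads = 2L,
                            dropout = 0, max_length = 32L,
                            n_function_terms = 4L, time_channels = 32L)

test_that("a small configuration builds and runs a forward pass", {
  model <- build_denoiser(tiny_cfg, seed = 1)
  L <- 16L
  out <- denoise(model, rep(mask_token(), L), matrix(rnorm(L * 3), L, 3),
                 t_seq = 1, t_struct = 50)
  expect_identical(dim(out$logits), c(L, 21L))
  expect_identical(dim(out$structure_pred), c(L, 3L))
  expect_true(all(is.finite(out$logits)), all(is.finite(out$structure_pred)))
  expect_error(denoiser_config(hidden_dim = 65L, n_heads = 2L))
})

test_that("adaLN-Zero blocks contribute nothing at initialization", {
  # with zero-initialized gates, randomizing the block interiors must not
  # change the output
  m1 <- build_denoiser(tiny_cfg, seed = 2)
  m2 <- m1
  for (nm in names(m2$params)) {
    if (grepl("^b[0-9]+_(qkv|proj|ffn)", nm)) {
      m2$params[[nm]] <- m2$params[[nm]] +
        matrix(rnorm(length(m2$params[[nm]])), nrow = NROW(m2$params[[nm]]))
    }
  }
  L <- 8
  x <- matrix(rnorm(L * 3), L, 3)
  tok <- c(1L, 21L, 3L, 21L, 5L, 6L, 21L, 2L)
  o1 <- denoise(m1, tok, x, 0.5, 10)
  o2 <- denoise(m2, tok, x, 0.5, 10)
  expect_identical(o1$logits, o2$logits)
  expect_identical(o1$structure_pred, o2$structure_pred)
})

test_that("inference is deterministic and dropout only acts in training mode", {
  cfg <- denoiser_config(n_blocks = 2L, hidden_dim = 32L, n_heads = 2L,
                         dropout = 0.5, max_length = 16L, time_channels = 16L)
  model <- randomize_denoiser(build_denoiser(cfg, seed = 3))
  L <- 8
  x <- matrix(rnorm(L * 3), L, 3); tok <- rep(mask_token(), L)
  o1 <- denoise(model, tok, x, 1, 20)
  o2 <- denoise(model, tok, x, 1, 20)
  expect_identical(o1$logits, o2$logits)
  set.seed(4)
  o3 <- denoise(model, tok, x, 1, 20, train = TRUE)
  o4 <- denoise(model, tok, x, 1, 20, train = TRUE)
  expect_false(identical(o3$logits, o4$logits))
})

test_that("parameter count is a pure function of the configuration", {
  expect_identical(count_parameters(build_denoiser(tiny_cfg, seed = 5)),
                   count_parameters(tiny_cfg))
  expect_identical(count_parameters(build_denoiser(tiny_cfg, seed = 6)),
                   count_parameters(tiny_cfg))
})

test_that("parameter count matches an independent layer-by-layer tally", {
  d <- 64; blocks <- 2; f <- 4 * d; tc <- 32; nt <- 4; ml <- 32
  by_hand <-
    21 * d + ml * d +                        # token + position embeddings
    (3 * d + d) + (3 * d + d) + d + d +      # structure/motif embeds + marks
    (tc * d + d) + (d * d + d) +             # sinusoidal-time MLP
    nt * d + d +                             # term table + null term
    blocks * (3 * (d * d + d) + (d * d + d) + 2 * d +   # qkv, proj, qk-norm
              (d * f + f) + (f * d + d) +               # ffn
              (6 * d * d + 6 * d)) +                    # adaLN modulation
    (2 * d * d + 2 * d) +                    # final-layer modulation
    (d * 21 + 21) + (d * 3 + 3)              # output heads
  expect_identical(count_parameters(tiny_cfg), by_hand)
})

test_that("forward pass is invariant to rigid translation of the input", {
  model <- randomize_denoiser(build_denoiser(tiny_cfg, seed = 7))
  L <- 10
  x <- matrix(rnorm(L * 3), L, 3)
  tok <- sample(1:20, L, replace = TRUE)
  o1 <- denoise(model, tok, x, 0.2, 5)
  o2 <- denoise(model, tok, sweep(x, 2, c(100, -50, 3), `+`), 0.2, 5)
  expect_equal(o1$logits, o2$logits, tolerance = 1e-9)
  expect_equal(o1$structure_pred, o2$structure_pred, tolerance = 1e-9)
})

test_that("absent motif and zero-position motif condition identically", {
  model <- randomize_denoiser(build_denoiser(tiny_cfg, seed = 8))
  L <- 6
  x <- matrix(rnorm(L * 3), L, 3); tok <- rep(mask_token(), L)
  empty <- motif_spec(integer(0), matrix(0, 0, 3), integer(0))
  o1 <- denoise(model, tok, x, 1, 30)
  o2 <- denoise(model, tok, x, 1, 30, motif = empty)
  expect_identical(o1$logits, o2$logits)
  # a non-empty motif does change the output
  m <- motif_spec(2:3, matrix(rnorm(6), 2, 3), c(4L, 5L))
  o3 <- denoise(model, tok, x, 1, 30, motif = m)
  expect_false(identical(o1$logits, o3$logits))
  expect_error(denoise(model, tok, x, 1, 30, term = 99L), "out of range")
})

test_that("the model is position-sensitive (no permutation equivariance)", {
  model <- randomize_denoiser(build_denoiser(tiny_cfg, seed = 9))
  L <- 8
  x <- matrix(rnorm(L * 3), L, 3)
  tok <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 6L, 7L)
  o1 <- denoise(model, tok, x, 0.5, 10)
  o2 <- denoise(model, tok[perm], x[perm, ], 0.5, 10)
  # un-permuting the permuted output does NOT recover the original:
  # positional information is present
  expect_gt(max(abs(o2$logits[order(perm), ] - o1$logits)), 1e-6)
})

test_that("analytic gradients match finite differences on a micro model", {
  cfg <- denoiser_config(n_blocks = 2L, hidden_dim = 16L, n_heads = 2L,
                         dropout = 0, max_length = 8L,
                         n_function_terms = 3L, time_channels = 8L)
  params <- codiffuse:::.init_params(cfg, seed = 10)
  set.seed(11)
  for (nm in names(params)) {
    if (grepl("ada|head_", nm)) {
      params[[nm]] <- params[[nm]] + 0.1 * rnorm(length(params[[nm]]))
    }
  }
  L <- 5
  input <- list(tokens = c(1L, 21L, 3L, 21L, 2L),
                X = matrix(rnorm(L * 3), L, 3), tp = 0.42,
                motif = list(positions = c(2L, 4L),
                             coords = matrix(rnorm(6), 2, 3),
                             tokens = c(5L, 3L)),
                term = 1L)
  out <- codiffuse:::.denoiser_forward(params, cfg, input, want_cache = TRUE)
  w1 <- matrix(rnorm(L * 21), L, 21); w2 <- matrix(rnorm(L * 3), L, 3)
  g <- codiffuse:::.denoiser_backward(params, cfg, out$cache, w1, w2)
  loss <- function(p) {
    o <- codiffuse:::.denoiser_forward(p, cfg, input)
    sum(w1 * o$logits) + sum(w2 * o$structure_pred)
  }
  eps <- 1e-5
  set.seed(12)
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      fd <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(g[[nm]][j], fd, tolerance = 1e-4,
                   label = sprintf("grad[%s][%d]", nm, j))
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  model <- randomize_denoiser(build_denoiser(tiny_cfg, seed = 13))
  path <- tempfile(fileext = ".rds")
  save_denoiser(model, path)
  back <- load_denoiser(path)
  L <- 6
  x <- matrix(rnorm(L * 3), L, 3); tok <- rep(mask_token(), L)
  expect_identical(denoise(model, tok, x, 1, 40)$logits,
                   denoise(back, tok, x, 1, 40)$logits)
  saveRDS(list(foo = 1), path)
  expect_error(load_denoiser(path), "checkpoint")
})
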