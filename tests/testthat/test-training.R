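test_that("combined loss weights the sequence term by 3", {
  expect_equal(combined_loss(1, 2), 7)
  expect_equal(combined_loss(0, 0), 0)
  expect_equal(combined_loss(2.5, 0), 2.5)
  expect_error(combined_loss(-1, 0))
})

test_that("modality noise levels are independent uniforms", {
  n <- 1e5
  set.seed(2)
  x <- vapply(1:n, function(i) sample_noise_levels(), numeric(2))
  a <- x[1, ]; b <- x[2, ]
  expect_lt(abs(cor(a, b)), 0.01)
  # binned uniformity check (KS is unsuitable: runif's 2^-32 grid ties)
  expect_gt(stats::chisq.test(tabulate(ceiling(a * 50), nbins = 50))$p.value, 0.01)
  expect_gt(stats::chisq.test(tabulate(ceiling(b * 50), nbins = 50))$p.value, 0.01)
  expect_identical(sample_noise_levels(seed = 3), sample_noise_levels(seed = 3))
})

test_that("conditioning policy hits its attachment and drop rates", {
  spec <- toy_family_spec(length = 20, noise_sd = 0)
  p <- make_toy_protein(spec, seed = 4)
  ex <- list(tokens = p$sequence$tokens, coords = p$structure$coords)
  # no terms -> never a term
  set.seed(5)
  outs <- replicate(200, conditioning_policy(ex), simplify = FALSE)
  expect_true(all(vapply(outs, function(o) is.null(o$term), logical(1))))
  n <- 1e4
  set.seed(6)
  outs <- replicate(n, conditioning_policy(ex), simplify = FALSE)
  motif_rate <- mean(vapply(outs, function(o) !is.null(o$motif), logical(1)))
  ds_rate <- mean(vapply(outs, function(o) o$drop_seq, logical(1)))
  dx_rate <- mean(vapply(outs, function(o) o$drop_struct, logical(1)))
  expect_lt(abs(motif_rate - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(ds_rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_lt(abs(dx_rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("terms are drawn in proportion to inverse frequency", {
  spec <- toy_family_spec(length = 12, noise_sd = 0)
  p <- make_toy_protein(spec, seed = 7)
  ex <- list(tokens = p$sequence$tokens, coords = p$structure$coords,
             terms = c(1L, 2L))
  w <- c("1" = 10, "2" = 1000)
  n <- 1e4
  set.seed(8)
  terms <- vapply(1:n, function(i) {
    o <- conditioning_policy(ex, vocab_weights = w,
                             policy = training_policy(term_use_prob = 1))
    o$term
  }, integer(1))
  p1 <- (1 / 10) / (1 / 10 + 1 / 1000)   # ~0.9901: ratio about 100:1
  expect_lt(abs(mean(terms == 1L) - p1), 3 * sqrt(p1 * (1 - p1) / n))
})

test_that("training motifs are contiguous segments covering 5-50% of residues", {
  spec <- toy_family_spec(length = 40, noise_sd = 0)
  p <- make_toy_protein(spec, seed = 9)
  set.seed(10)
  for (i in 1:50) {
    m <- sample_training_motif(p$sequence$tokens, p$structure$coords)
    cov <- length(m$positions) / 40
    expect_gte(cov, 0.025); expect_lte(cov, 0.525)
    runs <- split(m$positions, cumsum(c(1, diff(m$positions) != 1)))
    expect_lte(length(runs), 4L)
    expect_identical(p$sequence$tokens[m$positions], m$identities)
  }
})

test_that("hierarchical sampling is uniform over clusters, not proteins", {
  # outer cluster A has 1 inner cluster; outer B has 99: flat sampling
  # would pick B ~99% of the time, hierarchical ~50%
  tab <- data.frame(
    id = seq_len(100),
    outer_cluster = c("A", rep("B", 99)),
    inner_cluster = c("a1", paste0("b", 1:99)),
    quality = 90)
  n <- 4000
  set.seed(11)
  picks <- vapply(1:n, function(i) hierarchical_sample(tab)$outer_cluster,
                  character(1))
  expect_lt(abs(mean(picks == "A") - 0.5), 3 * sqrt(0.25 / n))
  # quality filtering removes whole clusters
  tab2 <- tab; tab2$quality[tab2$outer_cluster == "A"] <- 50
  picks2 <- vapply(1:200, function(i) hierarchical_sample(tab2)$outer_cluster,
                   character(1))
  expect_true(all(picks2 == "B"))
  # single-protein table
  one <- tab[1, ]
  expect_identical(hierarchical_sample(one)$id, 1L)
  expect_error(hierarchical_sample(data.frame(id = 1, outer_cluster = "A",
                                              inner_cluster = "a",
                                              quality = 10)),
               "quality")
})

test_that("term propagation computes the transitive is_a closure", {
  ont <- list(a = "b", b = "c", c = character(0), d = character(0))
  closed <- propagate_terms(list(p1 = "a", p2 = "d"), ont)
  expect_identical(closed$p1, c("a", "b", "c"))
  expect_identical(closed$p2, "d")
  expect_true(all(c("c", "d") %in% attr(closed, "roots")))
  # 7-term DAG vs an independent breadth-first closure oracle
  dag <- list(t1 = c("t2", "t3"), t2 = "t4", t3 = c("t4", "t5"),
              t4 = "t6", t5 = "t6", t6 = character(0), t7 = "t6")
  bfs_closure <- function(start) {
    seen <- character(0); frontier <- start
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(dag[frontier], use.names = FALSE), seen)
    }
    sort(seen)
  }
  closed <- propagate_terms(list(x = "t1", y = c("t7", "t5")), dag)
  expect_identical(closed$x, bfs_closure("t1"))
  expect_identical(closed$y, bfs_closure(c("t7", "t5")))
  cyc <- list(a = "b", b = "a")
  expect_error(propagate_terms(list(p = "a"), cyc), "cycle")
})

test_that("EMA update obeys its one-step arithmetic and endpoints", {
  ema <- list(w = matrix(0, 2, 2), b = numeric(3))
  par <- list(w = matrix(1, 2, 2), b = rep(1, 3))
  one <- ema_update(ema, par, 0.999)
  expect_equal(one$w, matrix(0.001, 2, 2), tolerance = 1e-15)
  expect_identical(ema_update(ema, par, 0)$w, par$w)
  expect_identical(ema_update(ema, par, 1)$w, ema$w)
})

test_that("sequence-loss gradients vanish at unmasked positions", {
  L <- 5
  lg <- matrix(rnorm(L * 21), L, 21)
  s0 <- c(1L, 2L, 3L, 4L, 5L); st <- c(21L, 2L, 21L, 4L, 5L)
  g <- codiffuse:::.seq_loss_grad(lg, s0, st, 0.4)
  expect_true(all(g[c(2, 4, 5), ] == 0))
  expect_true(all(g[, 21] == 0))
  # finite-difference confirmation at an unmasked position
  h <- 1e-6
  lg2 <- lg; lg2[2, 7] <- lg2[2, 7] + h
  expect_equal(seq_loss(lg2, s0, st, 0.4), seq_loss(lg, s0, st, 0.4))
  # and a masked position has the analytic gradient
  lg3 <- lg; lg3[1, 1] <- lg3[1, 1] + h
  fd <- (seq_loss(lg3, s0, st, 0.4) - seq_loss(lg, s0, st, 0.4)) / h
  expect_equal(g[1, 1], fd, tolerance = 1e-4)
})

test_that("zero training steps return the model unchanged", {
  cfg <- denoiser_config(n_blocks = 1L, hidden_dim = 16L, n_heads = 2L,
                         dropout = 0, max_length = 16L, time_channels = 8L)
  model <- build_denoiser(cfg, seed = 12)
  spec <- toy_family_spec(length = 8, noise_sd = 0.05)
  p <- make_toy_protein(spec, seed = 13)
  ds <- list(list(tokens = p$sequence$tokens, coords = p$structure$coords))
  out <- train_denoiser(model, ds, steps = 0L)
  expect_identical(out$model$params, model$params)
})

test_that("non-finite losses abort with a diagnostic", {
  cfg <- denoiser_config(n_blocks = 1L, hidden_dim = 16L, n_heads = 2L,
                         dropout = 0, max_length = 16L, time_channels = 8L)
  model <- build_denoiser(cfg, seed = 14)
  bad <- list(list(tokens = rep(1L, 8),
                   coords = matrix(c(NaN, rnorm(23)), 8, 3)))
  expect_error(train_denoiser(model, bad, steps = 3L, batch_size = 1L,
                              seed = 15),
               "non-finite")
})

test_that("toy training halves the combined loss", {
  fit <- get_toy_fit()
  early <- mean(fit$history[1:100])
  late <- mean(tail(fit$history, 100))
  expect_lt(late, 0.5 * early)
})
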