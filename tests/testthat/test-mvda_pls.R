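# Batch-level unfolding, NIPALS PLS1 against the SIMPLS oracle, VIP
# identities, and the coefficient-sum nutrient ranking.

test_that("batch-level unfolding has the expected shape and normalization", {
  set <- suppressMessages(simulate_study(gy_conditions(noise_cv = 0.02),
                                         feed_schedule(), seed = 8))
  blm <- suppressMessages(unfold_batch_level(set))
  n_vars <- length(unique(blm$columns$variable))
  expect_equal(nrow(blm$X), 15)                       # 5 conditions x 3
  expect_lte(ncol(blm$X), n_vars * 8)                 # minus dropped columns
  expect_equal(max(blm$y), 1)                         # normalized to max
  expect_false(anyNA(blm$X))
})

test_that("constant columns are dropped with a message", {
  cond <- condition_spec("C", noise_cv = 0.02, n_replicates = 3,
                         base_rates = c(Glc = -0.5, Ala = 0))
  sched <- feed_schedule(feed_composition = c(Ala = 0))
  ## Ala never moves -> every Ala column is constant across batches? no:
  ## noise varies it. Use two zero-noise batches of one condition plus a
  ## second condition to create true constants.
  c1 <- condition_spec("A", noise_cv = 0, n_replicates = 2)
  c2 <- condition_spec("B", noise_cv = 0, n_replicates = 2, qp_max = 30)
  set <- suppressMessages(simulate_study(list(c1, c2), sched, seed = 1))
  ## VCD identical across all four batches (same growth model): constant
  expect_message(blm <- unfold_batch_level(set), "zero-variance")
  expect_false(any(grepl("^VCD@", colnames(blm$X))))
})

test_that("NIPALS coefficients match the SIMPLS oracle", {
  set.seed(202)
  for (trial in 1:20) {
    n <- sample(8:20, 1); p <- sample(4:10, 1)
    A <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    fit <- fit_pls(X, ncomp = A, y = y)
    oracle <- simpls1_coef(X, y, A)
    expect_equal(unname(fit$b), unname(oracle), tolerance = 1e-6)
  }
})

test_that("one-component coefficients align with the X'y direction", {
  set.seed(3)
  X <- matrix(rnorm(60), 12)
  y <- rnorm(12)
  fit <- fit_pls(X, ncomp = 1, y = y)
  d <- as.numeric(crossprod(scale(X), scale(y)))
  expect_equal(cor(fit$b, d), 1, tolerance = 1e-10)
})

test_that("scores are orthogonal and VIP identities hold on every fit", {
  set.seed(77)
  for (trial in 1:5) {
    X <- matrix(rnorm(15 * 8), 15)
    y <- rnorm(15)
    fit <- fit_pls(X, ncomp = 3, y = y)
    G <- crossprod(fit$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-10)
    expect_equal(sqrt(colSums(fit$W^2)), rep(1, 3), tolerance = 1e-10)
  }
  # single column: VIP exactly 1
  X1 <- matrix(rnorm(10), 10, 1)
  f1 <- fit_pls(X1, ncomp = 1, y = rnorm(10))
  expect_equal(unname(f1$vip), 1, tolerance = 1e-12)
})

test_that("a planted linear signal is recovered with high R2", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20)
  beta <- c(2, -1.5, 1, rep(0, 7))
  y <- as.numeric(X %*% beta) + rnorm(20, sd = 0.2)
  fit <- fit_pls(X, ncomp = 3, y = y)
  pred <- predict(fit, X)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.9)
})

test_that("autoscaling makes results invariant to column rescaling", {
  set.seed(9)
  X <- matrix(rnorm(14 * 6), 14)
  y <- rnorm(14)
  f1 <- fit_pls(X, ncomp = 2, y = y)
  X2 <- X; X2[, 3] <- X2[, 3] * 1000
  f2 <- fit_pls(X2, ncomp = 2, y = y)
  expect_equal(unname(f1$b), unname(f2$b), tolerance = 1e-10)
  expect_equal(unname(f1$vip), unname(f2$vip), tolerance = 1e-10)
})

test_that("ranking handles empty selections and breaks ties by name", {
  set.seed(21)
  X <- matrix(rnorm(12 * 4), 12,
              dimnames = list(NULL, c("A@d4", "A@d5", "B@d4", "B@d5")))
  y <- rnorm(12)
  fit <- fit_pls(X, ncomp = 1, y = y)
  expect_warning(rk <- coefficient_sum_ranking(fit, vip_threshold = 100),
                 "no column")
  expect_equal(nrow(rk), 0)
  ## symmetric duplicated columns give tied sums; order is lexicographic
  X2 <- X; X2[, 3:4] <- X2[, 1:2]
  colnames(X2) <- c("B@d4", "B@d5", "A@d4", "A@d5")
  fit2 <- fit_pls(X2, ncomp = 1, y = y)
  rk2 <- coefficient_sum_ranking(fit2, vip_threshold = 0)
  expect_equal(abs(rk2$coef_sum[1]), abs(rk2$coef_sum[2]), tolerance = 1e-10)
  expect_equal(rk2$variable, sort(rk2$variable))
})

test_that("a planted negative nutrient tops the ranking end-to-end", {
  wins <- 0
  for (seed in 1:5) {
    conds <- plant_titer_correlation(gy_conditions(), "Glu", -1, 0.3)
    set <- suppressMessages(simulate_study(conds, feed_schedule(), seed = seed))
    filt <- filter_outliers(set, detect_outliers(set))
    blm <- suppressMessages(unfold_batch_level(filt))
    fit <- fit_pls(blm, ncomp = 2)
    rk <- coefficient_sum_ranking(fit, blm$columns)
    if (nrow(rk) && rk$variable[1] == "Glu" && rk$coef_sum[1] < 0) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
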