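make_factor_matrix <- function(n = 300, per_block = 4, k = 5, noise = 0.5,
                               seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * k), n, k)
  X <- do.call(cbind, lapply(seq_len(k), function(j) {
    sapply(seq_len(per_block), function(i) f[, j] + noise * rnorm(n))
  }))
  colnames(X) <- paste0("x", seq_len(k * per_block))
  X
}

test_that("PMM imputation returns observed donors and is seed-deterministic", {
  X <- make_factor_matrix(n = 120)
  full <- impute_pmm(X, m = 3, seed = 5)
  expect_true(all(vapply(full$imputations, identical, logical(1), X)))

  Xna <- X
  set.seed(2)
  holes <- cbind(sample(nrow(X), 30), sample(ncol(X), 30, replace = TRUE))
  Xna[holes] <- NA
  imp <- impute_pmm(Xna, m = 4, maxit = 5, seed = 9)
  imp2 <- impute_pmm(Xna, m = 4, maxit = 5, seed = 9)
  expect_identical(imp$imputations, imp2$imputations)
  for (cp in imp$imputations) {
    expect_false(anyNA(cp))
    # observed cells identical across copies; imputed cells are donor values
    expect_equal(cp[!is.na(Xna)], Xna[!is.na(Xna)])
    for (r in seq_len(nrow(holes))) {
      j <- holes[r, 2]
      expect_true(cp[holes[r, 1], j] %in% Xna[, j])
    }
  }
  expect_error(impute_pmm(cbind(X[, 1], NA)), "observed")
})

test_that("parallel analysis recovers the generating component count", {
  X5 <- make_factor_matrix(n = 400, per_block = 5, k = 5, noise = 0.6)
  expect_equal(choose_k(X5)$n_components, 5L)

  set.seed(5)
  noise <- matrix(rnorm(300 * 20), 300, 20)
  expect_equal(choose_k(noise)$n_components, 0L)

  set.seed(5)
  f <- rnorm(300)
  rank1 <- sapply(1:8, function(i) f + 0.4 * rnorm(300))
  expect_equal(choose_k(rank1)$n_components, 1L)
})

test_that("promax PCA recovers block structure with small cross-loadings", {
  X <- make_factor_matrix(n = 500, per_block = 5, k = 5, noise = 0.4, seed = 3)
  fit <- fit_pca_promax(X, k = 5)
  block <- rep(1:5, each = 5)
  assigned <- apply(abs(fit$loadings), 1, which.max)
  # variables of a block land on a common component
  expect_equal(length(unique(tapply(assigned, block, function(z)
    names(sort(table(z), decreasing = TRUE))[1]))), 5L)
  for (i in seq_len(nrow(fit$loadings))) {
    main <- abs(fit$loadings[i, assigned[i]])
    expect_gt(main, 0.7)
    expect_lt(max(abs(fit$loadings[i, -assigned[i]])), 0.35)
  }
  # sign convention: dominant variable of each component loads positive
  for (j in 1:5) expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  # duplicated variable -> identical loading rows
  X2 <- cbind(X, dup = X[, 1])
  fit2 <- fit_pca_promax(X2, k = 5)
  expect_equal(unname(fit2$loadings["dup", ]), unname(fit2$loadings["x1", ]),
               tolerance = 1e-8)
  expect_error(fit_pca_promax(X[, 1:3], k = 4), "rank")
})

test_that("promax reduces to an orthogonal solution for uncorrelated factors", {
  X <- make_factor_matrix(n = 2000, per_block = 5, k = 4, noise = 0.5, seed = 8)
  fit <- fit_pca_promax(X, k = 4)
  off <- fit$Phi[row(fit$Phi) != col(fit$Phi)]
  expect_lt(max(abs(off)), 0.1)
})

test_that("pruning and assignment reproduce the published composite structure", {
  pub <- published_loadings()
  sol <- prune_and_assign(pub, cutoff = 0.512)
  expect_equal(as.integer(sort(table(sol$assignment$composite),
                              decreasing = TRUE)),
               c(10L, 8L, 7L, 5L, 3L))
  row19 <- sol$assignment[sol$assignment$id == "19", ]
  expect_equal(row19$composite, "Sleep Activity")
  expect_equal(row19$sign, -1)
  expect_equal(row19$loading, -0.89)
  # a weak variable is dropped at the cutoff
  pub2 <- rbind(pub, weak = c(0.40, 0.1, 0.05, 0.02, 0.1))
  sol2 <- prune_and_assign(pub2, cutoff = 0.512)
  expect_true("weak" %in% sol2$dropped_low)
  expect_equal(sol2$retained, rownames(pub))
  # explicit drop list
  sol3 <- prune_and_assign(pub, drop = "19")
  expect_equal(sol3$dropped_explicit, "19")
  expect_equal(length(sol3$retained) + length(sol3$dropped_low) +
                 length(sol3$dropped_explicit), nrow(pub))
})

test_that("composite scores are signed unweighted averages of z-scores", {
  set.seed(10)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  X[, "b"] <- -X[, "a"] + 0.1 * rnorm(100)
  L <- matrix(c(0.9, -0.85), 2, 1, dimnames = list(c("a", "b"), NULL))
  sol <- prune_and_assign(L, cutoff = 0.5)
  sc <- score_composites(X, sol)
  za <- as.numeric(scale(X[, "a"]))
  zb <- as.numeric(scale(X[, "b"]))
  expect_equal(as.numeric(sc), (za - zb) / 2)
  # relabeling the variables within a composite leaves scores unchanged
  X2 <- X[, c("b", "a")]
  sc2 <- score_composites(X2, sol)
  expect_equal(as.numeric(sc2), as.numeric(sc))
  expect_error(score_composites(rbind(X, NA), sol), "complete")
})

test_that("Rubin pooling combines within and between variance", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$se^2, 1 + (1 + 1 / 2) * 2)
  # identical estimates: no between-imputation variance
  p2 <- pool_rubin(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(p2$estimate, 2)
  expect_equal(p2$between_var, 0)
  expect_equal(p2$se, 0.5)
  expect_warning(p3 <- pool_rubin(1.5, 0.2), "single")
  expect_equal(p3$estimate, 1.5)
})
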