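test_that("within-replicate centering equalizes replicate means", {
  # hand arithmetic: replicate means 2 and 4, grand mean 3 -> +/- 1 shifts
  bm <- make_bm(matrix(c(1, 3, 3, 5), ncol = 1), temps = c(20, 25, 20, 25),
                reps = c("a", "a", "b", "b"))
  cen <- center_within_replicates(bm)
  expect_equal(band_values(cen)[, 1], c(2, 4, 2, 4), ignore_attr = TRUE)
  # already-centered input is a fixed point
  cen2 <- center_within_replicates(cen)
  expect_equal(band_values(cen2), band_values(cen))
  # replicate signal removed: PERMANOVA replicate sum of squares vanishes
  sim <- simulate_band_matrix(band_sim_spec(seed = 5))
  cenS <- center_within_replicates(sim$matrix)
  pt <- permanova(cenS, n_permutations = 99, seed = 1)
  expect_lt(pt$R2[pt$term == "replicate"], 1e-12)
})

test_that("PERMANOVA matches a naive sequential-SS oracle and vegan", {
  sim <- simulate_band_matrix(band_sim_spec(seed = 8))
  pt <- permanova(sim$matrix, n_permutations = 99, seed = 2)
  # R2 partition sums to one
  expect_equal(sum(pt$R2[pt$term %in% c("temperature", "replicate", "Residual")]), 1,
               tolerance = 1e-9)
  # naive per-column lm() route gives the same sequential SS and F
  o <- naive_seq_F(band_values(sim$matrix), sim$matrix$temperature,
                   sim$matrix$replicate)
  expect_equal(pt$SumOfSqs[1:2], o$ss, tolerance = 1e-8)
  expect_equal(pt$F[1:2], o$F, tolerance = 1e-8)
  # vegan's adonis2 agrees on SS, R2 and pseudo-F
  skip_if_not_installed("vegan")
  df <- data.frame(temperature = factor(sim$matrix$temperature),
                   replicate = factor(sim$matrix$replicate))
  va <- vegan::adonis2(band_values(sim$matrix) ~ temperature + replicate,
                       data = df, method = "euclidean", by = "terms",
                       permutations = 99)
  expect_equal(pt$SumOfSqs[1:2], va$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pt$R2[1:2], va$R2[1:2], tolerance = 1e-8)
  expect_equal(pt$F[1:2], va$F[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA R2 is deterministic; only p depends on the seed", {
  sim <- simulate_band_matrix(band_sim_spec(seed = 12))
  a <- permanova(sim$matrix, n_permutations = 199, seed = 1)
  b <- permanova(sim$matrix, n_permutations = 199, seed = 2)
  expect_equal(a$R2, b$R2)
  expect_equal(a$F, b$F)
  expect_true(all(a$p_value >= 1 / 200, na.rm = TRUE))
  expect_identical(a, permanova(sim$matrix, n_permutations = 199, seed = 1))
  expect_error(permanova(make_bm(matrix(1, 6, 2)), n_permutations = 99),
               "constant")
})

test_that("LDA separates along the informative band and matches an eigen oracle", {
  # two uncorrelated equal-variance bands, means separated along band 1:
  # the discriminant axis is proportional to (1, 0)
  set.seed(21)
  n <- 200
  g <- rep(c("a", "b"), each = n / 2)
  Y <- cbind(rnorm(n, ifelse(g == "a", 0, 6), 1), rnorm(n, 0, 1))
  fit <- fit_lda(Y, groups = g)
  ax <- fit$axes[, 1] / sqrt(sum(fit$axes[, 1]^2))
  expect_gt(abs(ax[1]), 0.99)
  expect_lt(abs(ax[2]), 0.12)
  # invariance: adding a constant to any band leaves the scores unchanged
  Y2 <- Y
  Y2[, 2] <- Y2[, 2] + 100
  expect_equal(fit_lda(Y2, groups = g)$scores, fit$scores, tolerance = 1e-8)
})

test_that("LDA equals the brute-force generalized-eigen oracle", {
  set.seed(33)
  for (rep in 1:5) {
    Y <- matrix(rnorm(30 * 5), 30, 5)
    g <- factor(rep(c(20, 25, 30), each = 10))
    Y[g == 25, 1] <- Y[g == 25, 1] + 1
    Y[g == 30, 2] <- Y[g == 30, 2] + 2
    fit <- fit_lda(Y, groups = g, ridge = 0)
    # oracle: eigen of solve(W) %*% B computed directly
    Yc <- scale(Y, scale = FALSE)
    mus <- rowsum(Yc, g) / as.vector(table(g))
    W <- crossprod(Yc - mus[g, ]) / (nrow(Y) - nlevels(g))
    B <- crossprod(mus * sqrt(as.vector(table(g)))) / (nlevels(g) - 1)
    e <- eigen(solve(W) %*% B)
    ev <- Re(e$values[1:2])
    expect_equal(fit$fisher, ev, tolerance = 1e-8)
    for (j in 1:2) {
      a <- fit$axes[, j] / sqrt(sum(fit$axes[, j]^2))
      b <- Re(e$vectors[, j])
      b <- b / sqrt(sum(b^2))
      expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
    }
  }
})

test_that("LDA on strongly separated synthetic groups yields disjoint clouds", {
  sim <- simulate_band_matrix(band_sim_spec(effect_size = 4, noise_sd = 2,
                                            replicate_sd = 1, seed = 17))
  fit <- fit_lda(center_within_replicates(sim$matrix))
  # every individual is closest to its own temperature centroid
  d <- as.matrix(dist(rbind(fit$scores, fit$centroids)))
  d <- d[seq_len(nrow(fit$scores)), nrow(fit$scores) + seq_len(3)]
  assigned <- rownames(fit$centroids)[apply(d, 1, which.min)]
  expect_equal(assigned, as.character(fit$groups), ignore_attr = TRUE)
  # groups do not overlap along the first axis
  r20 <- range(fit$scores[fit$groups == 20, 1])
  r25 <- range(fit$scores[fit$groups == 25, 1])
  r30 <- range(fit$scores[fit$groups == 30, 1])
  rs <- rbind(r20, r25, r30)[order(c(mean(r20), mean(r25), mean(r30))), ]
  expect_lt(rs[1, 2], rs[2, 1])
  expect_lt(rs[2, 2], rs[3, 1])
})

test_that("singular within-group covariance is reported with the ridge hint", {
  Y <- cbind(rnorm(12), 0)  # one constant band
  g <- rep(c("a", "b"), 6)
  expect_error(fit_lda(Y, groups = g, ridge = 0), "ridge")
  expect_silent(fit_lda(Y, groups = g))  # default ridge regularizes
})

test_that("centroid trend arrow is the least-squares line through the centroids", {
  # hand OLS on three points: slope 0, intercept mean(y) = 1/3
  a <- centroid_trend_arrow(rbind(c(0, 0), c(1, 1), c(2, 0)))
  expect_equal(a$slope, 0)
  expect_equal(a$intercept, 1 / 3)
  expect_equal(a$direction, c(1, 0))
  # identity-line centroids
  b <- centroid_trend_arrow(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(b$direction, c(sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(b$intercept, 0)
  # collinear centroids: zero residuals
  expect_equal(b$centroids[, 2], b$slope * b$centroids[, 1] + b$intercept,
               ignore_attr = TRUE)
  # orientation follows increasing temperature (reversed order flips the arrow)
  d <- centroid_trend_arrow(rbind(c(2, 2), c(1, 1), c(0, 0)))
  expect_equal(d$direction, -b$direction)
  expect_error(centroid_trend_arrow(rbind(c(1, 1), c(1, 1), c(1, 1))),
               "coincident")
})

test_that("band-trend correlations follow the Spearman definition", {
  # arrow along LD1; arrow scores are then the first score column
  arrow <- centroid_trend_arrow(rbind(c(0, 0), c(1, 0), c(2, 0)))
  scores <- cbind(c(2, 1, 4, 3, 5), 0)
  Y <- cbind(b1 = c(1, 2, 3, 4, 5),    # hand ranks: sum d^2 = 4, rho = 0.8
             b2 = c(2, 1, 4, 3, 5),    # identical to the arrow scores: rho = 1
             b3 = rep(1, 5))           # constant: undefined, flagged
  ct <- band_trend_correlations(Y, arrow, scores)
  expect_equal(ct$rho[1], 1 - 6 * 4 / (5 * 24))
  expect_equal(ct$rho[2], 1)
  expect_true(is.na(ct$rho[3]))
  expect_false(ct$candidate[3])
  expect_equal(ct$p_adj, pmin(1, ct$p * 3))
})

test_that("the trend workflow flags planted bands as candidates", {
  sim <- simulate_band_matrix(band_sim_spec(seed = 41))
  tr <- venom_trend(sim$matrix, n_permutations = 199, seed = 4)
  planted <- sim$truth$band[sim$truth$class != "unaffected"]
  expect_true(all(planted %in% tr$correlations$band[tr$correlations$candidate]))
  # planted direct bands rise with temperature: positive trend sign
  expect_true(all(tr$correlations$sign[tr$correlations$band %in% planted] == 1))
  expect_s3_class(tr$permanova, "permanova_table")
  expect_output(print(tr), "correlated with the trend")
})
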