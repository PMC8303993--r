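make_records <- function(L, LOC, CC, non = 10, multi = 2,
                         temps = NULL) {
  n <- length(L)
  if (is.null(temps)) temps <- rep(c(20, 25, 30), length.out = n)
  data.frame(dish_id = sprintf("d%02d", seq_len(n)),
             replicate_id = rep(c("r1", "r2"), length.out = n),
             temperature = temps, non_parasitized = non,
             mono_L = L, mono_LOC = LOC, mono_CC = CC,
             multi_parasitized = multi, stringsAsFactors = FALSE)
}

test_that("interaction responses follow the category definitions", {
  rec <- make_records(L = 10, LOC = 5, CC = 5, non = 7, multi = 3, temps = 25)
  resp <- derive_interaction_responses(rec)
  get <- function(m) unlist(resp[resp$metric == m, c("successes", "failures")])
  expect_equal(unname(get("parasitic_success")), c(15, 5))
  expect_equal(unname(get("encapsulation_capacity")), c(10, 10))
  expect_equal(unname(get("inhibition_capacity")), c(10, 10))
  expect_equal(unname(get("escape_capacity")), c(5, 5))
  # multi-parasitized larvae count toward the parasitism rate only
  expect_equal(unname(get("parasitism_rate")), c(23, 7))
  # all-CC dish: no parasitic success
  cc <- derive_interaction_responses(make_records(L = 0, LOC = 0, CC = 8, temps = 20))
  expect_equal(cc$successes[cc$metric == "parasitic_success"], 0)
  expect_equal(cc$failures[cc$metric == "parasitic_success"], 8)
})

test_that("success + failure decomposition and exclusions are consistent", {
  rec <- simulate_outcomes(outcome_sim_spec(seed = 31))
  resp <- derive_interaction_responses(rec)
  ps <- resp[resp$metric == "parasitic_success", ]
  mono <- rec$mono_L + rec$mono_LOC + rec$mono_CC
  expect_equal(ps$successes + ps$failures, mono[mono > 0][match(ps$dish_id, rec$dish_id[mono > 0])])
  # dishes without mono-parasitized larvae are dropped from mono metrics
  none <- make_records(L = c(5, 0), LOC = c(2, 0), CC = c(1, 0), temps = c(20, 25))
  expect_message(r2 <- derive_interaction_responses(none), "excluded")
  expect_equal(attr(r2, "excluded"), "d02")
  expect_false("d02" %in% r2$dish_id[r2$metric != "parasitism_rate"])
  expect_true("d02" %in% r2$dish_id[r2$metric == "parasitism_rate"])
  expect_error(derive_interaction_responses(make_records(L = -1, LOC = 0, CC = 0)),
               "non-negative")
})

test_that("melanization classes binarize at the 2-5 vs 0-1 boundary", {
  rec <- data.frame(
    larva_id = 1:10, capillary_id = "cap_1", temperature = 25,
    species = "D. melanogaster",
    class = c(0, 0, 1, 1, 1, 2, 4, 4, 5, 5))  # hand pooling: 5 vs 5
  b <- binarize_melanization(rec)
  expect_equal(b$successes, 5)
  expect_equal(b$failures, 5)
  # all class 0: nothing melanized
  rec0 <- transform(rec, class = 0)
  expect_equal(binarize_melanization(rec0)$successes, 0)
  # grouping key includes the capillary
  rec$capillary_id <- rep(c("cap_1", "cap_2"), each = 5)
  b2 <- binarize_melanization(rec)
  expect_equal(nrow(b2), 2)
  expect_error(binarize_melanization(transform(rec, class = 7)), "0..5")
})

test_that("the binomial GLMM recovers a planted effect and applies the OLRE rule", {
  os <- outcome_sim_spec(n_dishes_per_temperature = 50,
                         logit_parasitism = c(-1, 0, 1), replicate_sd = 0.5,
                         seed = 61)
  resp <- derive_interaction_responses(simulate_outcomes(os))
  pr <- resp[resp$metric == "parasitism_rate", ]
  fit <- suppressWarnings(fit_binomial_glmm(pr))
  est <- fit$coefficients["temperature30", "Estimate"]
  expect_lt(abs(est - 2), 0.4)
  # the OLRE flag mirrors the Pearson-ratio rule
  expect_identical(fit$olre, unname(fit$overdispersion > 2))
  # without dish heterogeneity the rule does not trigger
  os0 <- outcome_sim_spec(n_dishes_per_temperature = 50,
                          logit_parasitism = c(-1, 0, 1), replicate_sd = 0,
                          seed = 62)
  resp0 <- derive_interaction_responses(simulate_outcomes(os0))
  fit0 <- suppressWarnings(fit_binomial_glmm(resp0[resp0$metric == "parasitism_rate", ]))
  expect_false(fit0$olre)
  expect_lt(fit0$overdispersion, 2)
})

test_that("complete separation is flagged rather than silently returned", {
  rec <- make_records(L = rep(10, 6), LOC = 0, CC = 0, non = 0, multi = 0)
  resp <- derive_interaction_responses(rec)
  ps <- resp[resp$metric == "parasitic_success", ]
  fit <- suppressWarnings(fit_binomial_glmm(ps))
  expect_true(fit$separation)
})

test_that("Tukey contrasts cover all pairs and dominate unadjusted p-values", {
  os <- outcome_sim_spec(n_dishes_per_temperature = 20,
                         logit_parasitism = c(0, 0.7, 0.7), replicate_sd = 0,
                         seed = 77)
  rec <- simulate_outcomes(os)
  # make 25 and 30 degC literally identical dishes
  rec[rec$temperature == 30, -(1:3)] <- rec[rec$temperature == 25, -(1:3)]
  resp <- derive_interaction_responses(rec)
  fit <- suppressWarnings(fit_binomial_glmm(resp[resp$metric == "parasitism_rate", ]))
  expect_equal(nrow(fit$contrasts), 3)  # 3 temperatures -> 3 contrasts
  p2530 <- fit$contrasts$p_value[fit$contrasts$contrast == "temperature25 - temperature30"]
  expect_gt(p2530, 0.9)
  # multiplicity adjustment can only increase p
  emm <- emmeans::emmeans(fit$model, "temperature")
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))$p.value
  expect_true(all(fit$contrasts$p_value >= raw - 1e-12))
})

test_that("the Monte-Carlo Fisher test matches exact and degenerate expectations", {
  tab <- matrix(c(10, 2, 3, 9), 2)
  p_mc <- fisher_class_independence(tab, n_sim = 10000, seed = 5)
  p_ex <- fisher.test(tab)$p.value
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 10000))
  # proportional rows: perfect independence, p near 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_gte(fisher_class_independence(prop, n_sim = 2000, seed = 6), 0.5)
  # zero-margin rows dropped with a warning
  z <- rbind(c(5, 1), c(0, 0), c(2, 6))
  expect_warning(pz <- fisher_class_independence(z, n_sim = 500, seed = 7),
                 "zero margin")
  expect_true(pz > 0 && pz <= 1)
  # intended use: melanization classes x temperatures
  mel <- simulate_melanization(melanization_sim_spec(temperature_effect = c(0, 0, -2),
                                                     seed = 8))
  tab6 <- table(mel$class, mel$temperature)
  p6 <- fisher_class_independence(tab6, n_sim = 2000, seed = 9)
  expect_lt(p6, 0.05)
  expect_identical(as.numeric(p6),
                   as.numeric(fisher_class_independence(tab6, n_sim = 2000, seed = 9)))
})

test_that("the Gaussian LMM uses containment df and supports Box-Cox", {
  sim <- simulate_band_matrix(band_sim_spec(seed = 91))
  tot <- total_band_intensity(sim$matrix)
  tot$value <- tot$total_intensity
  fit <- fit_gaussian_lmm(tot)
  # balanced 3 temperatures x 5 replicates: F_2,12
  expect_equal(fit$F_test$df1, 2)
  expect_equal(fit$F_test$df2, 12)
  expect_equal(nrow(fit$contrasts), 3)
  # Box-Cox on right-skewed positive data
  set.seed(12)
  skew <- data.frame(value = rlnorm(60, 5, 0.4),
                     temperature = rep(c(20, 25, 30), each = 20),
                     replicate = rep(rep(c("r1", "r2"), each = 10), 3))
  fitb <- fit_gaussian_lmm(skew, transform = "boxcox")
  expect_true(is.finite(fitb$lambda))
  expect_error(fit_gaussian_lmm(transform(skew, value = value - 200),
                                transform = "boxcox"), "offset")
  # zero residual variance: degenerate flag
  degen <- data.frame(value = rep(c(1, 2, 3), each = 10),
                      temperature = rep(c(20, 25, 30), each = 10),
                      replicate = rep(c("r1", "r2"), 15))
  fitd <- suppressWarnings(suppressMessages(fit_gaussian_lmm(degen)))
  expect_true(fitd$degenerate)
})

test_that("a planted intensity shift is covered by +/- 2 SE most of the time", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    spec <- band_sim_spec(seed = 400 + s)
    sim <- simulate_band_matrix(spec)
    tot <- total_band_intensity(sim$matrix)
    tot$value <- tot$total_intensity
    fit <- suppressMessages(fit_gaussian_lmm(tot))
    # truth: direct + indirect bands add 6 * effect_size * 5 between 25 and 20
    truth <- 6 * spec$effect_size * 5
    est <- fit$coefficients["temperature25", "Estimate"]
    se <- fit$coefficients["temperature25", "Std. Error"]
    hits <- hits + (abs(est - truth) <= 2 * se)
  }
  expect_gte(hits, 17)
})
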