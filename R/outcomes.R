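#' Derive binomial responses from parasitism outcome records
#'
#' Turns per-dish dissection counts into the success/failure pairs analysed
#' by the binomial mixed models:
#' \describe{
#'   \item{parasitism_rate}{mono- + multi-parasitized vs non-parasitized}
#'   \item{parasitic_success}{L + LOC vs CC}
#'   \item{encapsulation_capacity}{LOC + CC vs L}
#'   \item{inhibition_capacity}{L vs LOC + CC}
#'   \item{escape_capacity}{LOC vs CC}
#' }
#' All metrics except `parasitism_rate` use mono-parasitized larvae only
#' (multi-parasitized hosts are uninterpretable for the interaction outcome).
#' Dishes with zero mono-parasitized larvae are excluded from the mono-based
#' metrics, with a message listing them.
#'
#' @param records data frame of per-dish counts as returned by
#'   [simulate_outcomes()]: columns `dish_id`, `replicate_id`, `temperature`,
#'   `non_parasitized`, `mono_L`, `mono_LOC`, `mono_CC`, `multi_parasitized`.
#' @return data frame with columns `metric`, `dish_id`, `replicate_id`,
#'   `temperature`, `successes`, `failures` (one row per dish and metric);
#'   excluded dish ids are attached as attribute `excluded`.
#' @export
derive_interaction_responses <- function(records) {
  need <- c("dish_id", "replicate_id", "temperature", "non_parasitized",
            "mono_L", "mono_LOC", "mono_CC", "multi_parasitized")
  stopifnot(all(need %in% names(records)))
  cnt <- records[, c("non_parasitized", "mono_L", "mono_LOC", "mono_CC",
                     "multi_parasitized")]
  if (any(cnt < 0)) stop("counts must be non-negative")
  mono <- records$mono_L + records$mono_LOC + records$mono_CC
  base <- records[, c("dish_id", "replicate_id", "temperature")]
  mk <- function(metric, succ, fail, keep = rep(TRUE, nrow(records))) {
    cbind(data.frame(metric = metric, stringsAsFactors = FALSE),
          base, successes = succ, failures = fail)[keep, , drop = FALSE]
  }
  has_mono <- mono > 0
  excluded <- records$dish_id[!has_mono]
  if (length(excluded) > 0) {
    message("dishes with no mono-parasitized larvae excluded from mono-based metrics: ",
            paste(excluded, collapse = ", "))
  }
  out <- rbind(
    mk("parasitism_rate", mono + records$multi_parasitized, records$non_parasitized),
    mk("parasitic_success", records$mono_L + records$mono_LOC, records$mono_CC, has_mono),
    mk("encapsulation_capacity", records$mono_LOC + records$mono_CC, records$mono_L, has_mono),
    mk("inhibition_capacity", records$mono_L, records$mono_LOC + records$mono_CC, has_mono),
    mk("escape_capacity", records$mono_LOC, records$mono_CC, has_mono)
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Binarize melanization classes
#'
#' Pools the ordinal oil-drop melanization classes into melanized (classes
#' 2-5) versus not melanized (classes 0-1) counts per capillary and
#' temperature (and species, when present), the response of the
#' encapsulation-capacity GLMM with capillary as random effect.
#'
#' @param records per-larva data frame with columns `class` (integer 0-5),
#'   `capillary_id`, `temperature`, optionally `species`.
#' @return data frame with one row per capillary x temperature (x species):
#'   `successes` (melanized) and `failures` (not melanized).
#' @export
binarize_melanization <- function(records) {
  stopifnot(all(c("class", "capillary_id", "temperature") %in% names(records)))
  if (any(!(records$class %in% 0:5))) stop("melanization classes must be integers in 0..5")
  keys <- c("capillary_id", "temperature", intersect("species", names(records)))
  grp <- interaction(records[keys], drop = TRUE)
  mel <- as.integer(records$class >= 2)
  agg <- rowsum(cbind(successes = mel, failures = 1L - mel), grp)
  key_df <- unique(records[keys])
  key_df <- key_df[match(rownames(agg), as.character(interaction(key_df, drop = TRUE))), ,
                   drop = FALSE]
  out <- cbind(key_df, as.data.frame(agg))
  rownames(out) <- NULL
  out
}

# Pearson overdispersion ratio of a (g)lmer fit: chi^2 / residual df
.overdispersion_ratio <- function(fit) {
  sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
}

#' Binomial GLMM with the overdispersion rule
#'
#' Fits a logit-link binomial mixed model `cbind(successes, failures) ~
#' temperature + (1 | random)` with [lme4::glmer()]. The Pearson
#' overdispersion ratio (chi-squared over residual df) of this first fit is
#' computed; when it exceeds `olre_threshold` (default 2) the model is
#' refitted with an additional observation-level random intercept (OLRE) and
#' flagged. Complete separation (all successes or all failures) is detected
#' and flagged rather than silently returned. Temperature is tested by a
#' likelihood-ratio test against the model without it, and all pairwise
#' temperature contrasts are Tukey-adjusted via [emmeans::emmeans()].
#'
#' @param data data frame with columns `successes`, `failures`,
#'   `temperature` and the grouping variable named by `random`; e.g. one
#'   metric's rows from [derive_interaction_responses()] or the output of
#'   [binarize_melanization()].
#' @param random name of the random-intercept grouping column (default
#'   `"replicate_id"`; use `"capillary_id"` for melanization data).
#' @param olre_threshold Pearson-ratio threshold above which the OLRE is
#'   added.
#' @param tukey compute the Tukey contrast table (default `TRUE`; skipping it
#'   speeds up large simulation loops).
#' @return object of class `glmm_fit`: list with the fitted `model`,
#'   `family`, `coefficients`, `ranef_variance`, `overdispersion` (ratio from
#'   the initial fit), `olre`, `separation`, `converged`, `temperature_test`
#'   (LRT chisq/df/p) and the Tukey `contrasts` table.
#' @export
fit_binomial_glmm <- function(data, random = "replicate_id", olre_threshold = 2,
                              tukey = TRUE) {
  stopifnot(all(c("successes", "failures", "temperature", random) %in% names(data)))
  data <- as.data.frame(data)
  data <- data[data$successes + data$failures > 0, , drop = FALSE]
  data$temperature <- factor(data$temperature)
  if (nlevels(data$temperature) < 2) stop("at least 2 temperature levels with data are required")
  data$.grp <- factor(data[[random]])
  separation <- all(data$failures == 0) || all(data$successes == 0)
  fit1 <- tryCatch(
    suppressMessages(lme4::glmer(
      cbind(successes, failures) ~ temperature + (1 | .grp),
      data = data, family = stats::binomial())),
    error = function(e) if (separation) NULL else stop(e))
  if (is.null(fit1)) {
    # degenerate likelihood (e.g. all successes everywhere): report the flag
    return(structure(
      list(model = NULL, family = "binomial-logit", coefficients = NULL,
           ranef_variance = NULL, overdispersion = NA_real_, olre = FALSE,
           separation = TRUE, converged = FALSE,
           temperature_test = list(chisq = NA_real_, df = NA_integer_,
                                   p_value = NA_real_),
           contrasts = NULL, data = data),
      class = "glmm_fit"))
  }
  ratio <- .overdispersion_ratio(fit1)
  olre <- is.finite(ratio) && ratio > olre_threshold
  if (olre) {
    data$.obs <- factor(seq_len(nrow(data)))
    fit <- suppressMessages(lme4::glmer(
      cbind(successes, failures) ~ temperature + (1 | .grp) + (1 | .obs),
      data = data, family = stats::binomial()))
  } else {
    fit <- fit1
  }
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  # LRT for the temperature fixed effect
  null_form <- if (olre) cbind(successes, failures) ~ (1 | .grp) + (1 | .obs)
               else cbind(successes, failures) ~ (1 | .grp)
  fit0 <- suppressMessages(lme4::glmer(null_form, data = data, family = stats::binomial()))
  lrt <- suppressMessages(stats::anova(fit, fit0))
  temperature_test <- list(chisq = lrt$Chisq[2], df = lrt$Df[2],
                           p_value = lrt$`Pr(>Chisq)`[2])
  structure(
    list(model = fit, family = "binomial-logit",
         coefficients = summary(fit)$coefficients,
         ranef_variance = unlist(lapply(lme4::VarCorr(fit), function(v) v[1, 1])),
         overdispersion = ratio, olre = olre, separation = separation,
         converged = conv, temperature_test = temperature_test,
         contrasts = if (tukey) tukey_pairwise(fit) else NULL, data = data),
    class = "glmm_fit"
  )
}

#' Tukey-adjusted pairwise temperature contrasts
#'
#' All pairwise comparisons of the temperature levels on the link scale, with
#' multiplicity adjustment from the studentized-range / multivariate-normal
#' family, computed via [emmeans::emmeans()] marginal means. Three levels
#' give three contrasts.
#'
#' @param fit a `glmm_fit`, `lmm_fit`, or a raw `merMod` model with a
#'   `temperature` fixed factor.
#' @return data frame with columns `contrast`, `estimate`, `SE`, `statistic`,
#'   `p_value` (Tukey-adjusted).
#' @export
tukey_pairwise <- function(fit) {
  model <- if (inherits(fit, c("glmm_fit", "lmm_fit"))) fit$model else fit
  if (!inherits(model, "merMod")) stop("'fit' must be a fitted mixed model")
  emm <- emmeans::emmeans(model, "temperature", lmer.df = "asymptotic")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(prs))[1]
  data.frame(contrast = as.character(prs$contrast), estimate = prs$estimate,
             SE = prs$SE, statistic = prs[[stat_col]],
             p_value = prs$p.value, stringsAsFactors = FALSE)
}

#' @export
print.glmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("binomial GLMM (logit link)%s\n",
              if (x$olre) ", observation-level random effect added (overdispersion ratio > 2)" else ""))
  cat(sprintf("overdispersion ratio of initial fit: %.3f\n", x$overdispersion))
  if (x$separation) cat("WARNING: complete separation (all successes or all failures)\n")
  if (!x$converged) cat("WARNING: convergence issues reported by the optimizer\n")
  cat("fixed effects:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("temperature LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$temperature_test$chisq, x$temperature_test$df,
              x$temperature_test$p_value))
  cat("Tukey pairwise contrasts:\n")
  print.data.frame(format(x$contrasts, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo Fisher test of class x temperature independence
#'
#' Tests independence of the melanization classes (rows) and temperatures
#' (columns) by Monte-Carlo simulation: `n_sim` tables are drawn with the
#' observed margins fixed ([stats::r2dtable()]) and the p-value is
#' `(1 + #\{simulated table probability <= observed\}) / (1 + n_sim)`, the
#' simulated analogue of the exact conditional test. Rows or columns with a
#' zero margin are dropped with a warning.
#'
#' @param table matrix of non-negative counts with >= 2 rows and columns.
#' @param n_sim number of simulated tables (default 2000).
#' @param seed integer seed, or `NULL`.
#' @return the Monte-Carlo p-value, with attributes `n_sim` and `statistic`
#'   (the observed log table probability).
#' @export
fisher_class_independence <- function(table, n_sim = 2000, seed = NULL) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping row(s)/column(s) with zero margin")
    tab <- tab[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(tab); cs <- colSums(tab)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least 2 rows and 2 columns with data")
  if (!is.null(seed)) set.seed(seed)
  # log probability of a table under the fixed-margins (multiv. hypergeometric) null
  logp <- function(m) sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(m)) - sum(lfactorial(m))
  obs <- logp(tab)
  sims <- stats::r2dtable(n_sim, rs, cs)
  tol <- abs(obs) * 64 * .Machine$double.eps
  count <- sum(vapply(sims, logp, numeric(1)) <= obs + tol)
  p <- (1 + count) / (1 + n_sim)
  attr(p, "n_sim") <- n_sim
  attr(p, "statistic") <- obs
  p
}

#' Gaussian linear mixed model for intensity responses
#'
#' Fits `value ~ temperature + (1 | replicate)` with [lme4::lmer()], used for
#' the total band intensity and for Western-blot relative intensities. An
#' optional Box-Cox transformation (maximum-likelihood lambda via
#' [MASS::boxcox()]) limits deviations of the residuals from normality. The
#' temperature F statistic is reported with containment degrees of freedom:
#' the denominator df is the number of temperature x replicate cells minus
#' the number of temperature levels (3 x 5 cells and 3 levels give
#' denominator 12 in the balanced default design). Tukey pairwise contrasts
#' as in [tukey_pairwise()].
#'
#' @param data data frame with columns `value`, `temperature`, `replicate`
#'   (e.g. [total_band_intensity()] output with `total_intensity` renamed, or
#'   pass `value_col`).
#' @param transform `"none"` or `"boxcox"`.
#' @param value_col name of the response column (default `"value"`).
#' @param offset value added to the response before the Box-Cox transform
#'   when non-positive values are present (default 0, i.e. error out).
#' @return object of class `lmm_fit`: list with the fitted `model`,
#'   `coefficients`, `ranef_variance`, `sigma`, `F_test` (statistic, df1,
#'   df2, p), `lambda` (Box-Cox, or NA), `degenerate` flag and the Tukey
#'   `contrasts` table.
#' @export
fit_gaussian_lmm <- function(data, transform = c("none", "boxcox"),
                             value_col = "value", offset = 0) {
  transform <- match.arg(transform)
  stopifnot(all(c(value_col, "temperature", "replicate") %in% names(data)))
  data <- as.data.frame(data)
  data$.y <- data[[value_col]] + offset
  data$temperature <- factor(data$temperature)
  data$replicate <- factor(data$replicate)
  if (nlevels(data$replicate) < 2) stop("at least 2 replicates are required")
  lambda <- NA_real_
  if (transform == "boxcox") {
    if (any(data$.y <= 0)) {
      stop("Box-Cox requires positive values; supply a positive 'offset'")
    }
    bc <- MASS::boxcox(stats::lm(.y ~ temperature, data = data, y = TRUE,
                                 qr = TRUE),
                       lambda = seq(-2, 2, 0.01), plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
    data$.y <- if (abs(lambda) < 1e-8) log(data$.y) else (data$.y^lambda - 1) / lambda
  }
  fit <- lme4::lmer(.y ~ temperature + (1 | replicate), data = data, REML = TRUE)
  degenerate <- stats::sigma(fit) < 1e-10
  av <- stats::anova(fit)
  df1 <- nlevels(data$temperature) - 1
  n_cells <- nrow(unique(data[, c("temperature", "replicate")]))
  df2 <- n_cells - nlevels(data$temperature)
  Fstat <- av["temperature", "F value"]
  structure(
    list(model = fit, family = "gaussian",
         coefficients = summary(fit)$coefficients,
         ranef_variance = unlist(lapply(lme4::VarCorr(fit), function(v) v[1, 1])),
         sigma = stats::sigma(fit),
         F_test = list(statistic = Fstat, df1 = df1, df2 = df2,
                       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE)),
         lambda = lambda, degenerate = degenerate,
         contrasts = tukey_pairwise(fit), data = data),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Gaussian LMM: value ~ temperature + (1 | replicate)\n")
  if (!is.na(x$lambda)) cat(sprintf("Box-Cox lambda = %.3f\n", x$lambda))
  if (x$degenerate) cat("WARNING: residual variance is (near) zero\n")
  cat(sprintf("temperature: F_%d,%d = %.3f, p = %.4g (containment df)\n",
              x$F_test$df1, x$F_test$df2, x$F_test$statistic, x$F_test$p_value))
  cat("Tukey pairwise contrasts:\n")
  print.data.frame(format(x$contrasts, digits = digits), row.names = FALSE)
  invisible(x)
}
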