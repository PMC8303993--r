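#' Center a band matrix within replicates
#'
#' Removes the replicate (gel/batch) signal before discriminant analysis: for
#' every band, each replicate's mean is shifted to the grand mean while
#' within-replicate deviations are left unchanged. Applied twice internally so
#' the postcondition (replicate means equal to the grand mean) holds to
#' machine precision even with accumulated rounding.
#'
#' @param x a [band_matrix()].
#' @return the centered `band_matrix` (values may be negative).
#' @export
center_within_replicates <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  vals <- band_values(x)
  rep_f <- factor(x$replicate)
  if (any(table(rep_f) == 0)) stop("every replicate must have at least one row")
  for (pass in 1:2) {
    grand <- colMeans(vals)
    rep_means <- apply(vals, 2, function(col) stats::ave(col, rep_f))
    vals <- vals - rep_means + matrix(grand, nrow(vals), ncol(vals), byrow = TRUE)
  }
  set_band_values(x, vals)
}

# all permutations of 1..n as a list (n! entries; callers guard the size)
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  for (sub in .all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# sequential ("Type I") sums of squares of a multivariate response for an
# ordered list of factors, via orthonormal bases of the nested design spaces
.seq_ss <- function(Yc, factors) {
  qs <- list()
  X <- matrix(1, nrow(Yc), 1)
  for (f in factors) {
    X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
    qs[[length(qs) + 1]] <- qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
  }
  qs
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Euclidean-distance PERMANOVA of the band intensities on temperature and
#' replicate, entered in that order with sequential (Type I) sums of squares.
#' Pseudo-F statistics are referred to a null distribution obtained by freely
#' permuting the rows of the response; p = (1 + #\{permuted F >= observed F\})
#' / (1 + n_permutations).
#'
#' @param x a [band_matrix()] or numeric matrix.
#' @param temperature,replicate factors; taken from the metadata when `x` is
#'   a `band_matrix`.
#' @param n_permutations number of free row permutations (default 5000).
#' @param seed integer seed for the permutation stream, or `NULL`.
#' @param exhaustive if `TRUE`, enumerate all `n!` row permutations instead
#'   of sampling (feasible for n <= 8); the p-value is then the exact
#'   permutation p `#\{F* >= F\} / n!` (the identity permutation included).
#' @return data frame of class `permanova_table` with one row per term plus
#'   `Residual` and `Total` rows; columns `Df`, `SumOfSqs`, `R2`, `F`,
#'   `p_value`.
#' @export
permanova <- function(x, temperature = NULL, replicate = NULL,
                      n_permutations = 5000, seed = NULL, exhaustive = FALSE) {
  if (inherits(x, "band_matrix")) {
    if (is.null(temperature)) temperature <- x$temperature
    if (is.null(replicate)) replicate <- x$replicate
  }
  Y <- band_values(x)
  factors <- list(temperature = factor(temperature))
  if (!is.null(replicate)) factors$replicate <- factor(replicate)
  if (any(vapply(factors, nlevels, integer(1)) < 2)) {
    stop("each factor must have at least 2 levels")
  }
  if (!exhaustive && n_permutations < 99) stop("'n_permutations' must be at least 99")
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  tot <- sum(Yc^2)
  if (tot <= .Machine$double.eps * n) stop("constant response matrix: total sum of squares is zero")
  qs <- .seq_ss(Yc, factors)
  fit_ss <- vapply(qs, function(Q) sum(crossprod(Q, Yc)^2), numeric(1))
  ss <- diff(c(0, fit_ss))
  ranks <- vapply(qs, ncol, integer(1))
  df <- diff(c(1, ranks))
  df_res <- n - ranks[length(ranks)]
  ss_res <- tot - fit_ss[length(fit_ss)]
  Fobs <- (ss / df) / (ss_res / df_res)

  perm_F <- function(perm) {
    fit_p <- vapply(qs, function(Q) sum(crossprod(Q[perm, , drop = FALSE], Yc)^2),
                    numeric(1))
    ss_p <- diff(c(0, fit_p))
    (ss_p / df) / ((tot - fit_p[length(fit_p)]) / df_res)
  }
  counts <- numeric(length(Fobs))
  eps <- sqrt(.Machine$double.eps)  # ties at F* == F count as >=
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is only feasible for n <= 8 rows")
    perms <- .all_perms(n)
    for (perm in perms) counts <- counts + (perm_F(perm) >= Fobs - eps)
    pvals <- counts / length(perms)
    n_permutations <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    for (b in seq_len(n_permutations)) {
      counts <- counts + (perm_F(sample.int(n)) >= Fobs - eps)
    }
    pvals <- (1 + counts) / (1 + n_permutations)
  }

  out <- data.frame(
    term = c(names(factors), "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(ss, ss_res, tot),
    R2 = c(ss, ss_res, tot) / tot,
    F = c(Fobs, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' @export
print.permanova_table <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (Euclidean distance, sequential SS, %d free permutations)\n",
              attr(x, "n_permutations")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Linear discriminant analysis of band intensities
#'
#' Fisher discriminant axes maximizing the ratio of between-group to pooled
#' within-group variance, obtained from the generalized eigenproblem
#' `B a = lambda W a` via whitening (Cholesky of `W`, symmetric
#' eigendecomposition). Axes are scaled so that the pooled within-group
#' variance of each score is 1. With g groups, g - 1 axes are returned.
#'
#' @param x a [band_matrix()] or numeric matrix.
#' @param groups grouping factor; the temperature metadata when `x` is a
#'   `band_matrix`.
#' @param ridge ridge added to the within-group covariance as
#'   `ridge * mean(diag(W))` on the diagonal; default `1e-8`. Quantile
#'   normalization makes every lane share one value multiset, so the band
#'   sums are constant and the within-group covariance is rank-deficient by
#'   one: the small default ridge keeps the eigenproblem well posed there
#'   while leaving well-conditioned problems numerically untouched. Set to 0
#'   for exact unregularized axes.
#' @return object of class `venom_lda`: list with `axes` (bands x g-1),
#'   `scores` (individuals x g-1), `centroids` (per-group mean scores, in
#'   increasing group order), `fisher` (between/within variance ratio per
#'   axis), `groups`.
#' @export
fit_lda <- function(x, groups = NULL, ridge = 1e-8) {
  if (inherits(x, "band_matrix") && is.null(groups)) groups <- x$temperature
  Y <- band_values(x)
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2) stop("at least 2 groups are required")
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  mus <- rowsum(Yc, groups) / as.vector(table(groups))
  within <- Yc - mus[groups, , drop = FALSE]
  W <- crossprod(within) / (n - g)
  ng <- as.vector(table(groups))
  B <- crossprod(mus * sqrt(ng)) / (g - 1)
  if (ridge > 0) W <- W + diag(ridge * mean(diag(W)), ncol(W))
  R <- tryCatch(chol(W), error = function(e) {
    stop("within-group covariance is singular; supply a positive 'ridge' ",
         "(e.g. ridge = 1e-8) to regularize", call. = FALSE)
  })
  Rinv <- backsolve(R, diag(ncol(W)))
  A <- crossprod(Rinv, B %*% Rinv)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- g - 1
  axes <- Rinv %*% e$vectors[, seq_len(k), drop = FALSE]
  # fix sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(Y)
  colnames(axes) <- paste0("LD", seq_len(k))
  scores <- Yc %*% axes
  centroids <- rowsum(scores, groups) / ng
  structure(
    list(axes = axes, scores = scores, centroids = centroids,
         fisher = e$values[seq_len(k)], groups = groups, ridge = ridge),
    class = "venom_lda"
  )
}

#' @export
print.venom_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant analysis: %d groups, %d axes, %d bands\n",
              nlevels(x$groups), ncol(x$axes), nrow(x$axes)))
  cat("Fisher criterion (between/within ratio) per axis:",
      paste(signif(x$fisher, 4), collapse = ", "), "\n")
  cat("group centroids:\n")
  print(signif(x$centroids, 4))
  invisible(x)
}

#' Least-squares trend arrow through the temperature centroids
#'
#' Ordinary least squares of the second discriminant coordinate on the first,
#' over the three temperature-group centroids (ordered 20 -> 25 -> 30). The
#' arrow summarizes the direction of venom change with increasing
#' temperature: its unit direction is oriented from the 20 degC centroid
#' toward the 30 degC centroid's projection on the fitted line.
#'
#' @param centroids matrix with one row per temperature (in increasing
#'   temperature order) and two columns (the discriminant plane), e.g.
#'   `fit_lda(x)$centroids`.
#' @return object of class `trend_arrow`: list with `slope`, `intercept`,
#'   `direction` (unit 2-vector), `centroids`.
#' @export
centroid_trend_arrow <- function(centroids) {
  centroids <- as.matrix(centroids)
  stopifnot(ncol(centroids) == 2)
  if (max(dist(centroids)) < 1e-12) stop("coincident centroids: trend direction undefined")
  cx <- centroids[, 1]
  cy <- centroids[, 2]
  vx <- stats::var(cx)
  if (vx < 1e-24 * max(1, stats::var(cy))) {
    # vertical trend line
    slope <- Inf
    intercept <- NA_real_
    dir <- c(0, 1)
  } else {
    slope <- stats::cov(cx, cy) / vx
    intercept <- mean(cy) - slope * mean(cx)
    dir <- c(1, slope) / sqrt(1 + slope^2)
  }
  span <- centroids[nrow(centroids), ] - centroids[1, ]
  if (sum(span * dir) < 0) dir <- -dir
  structure(list(slope = slope, intercept = intercept, direction = dir,
                 centroids = centroids),
            class = "trend_arrow")
}

#' @export
print.trend_arrow <- function(x, ...) {
  cat(sprintf("centroid trend arrow: slope %.4g, intercept %.4g, direction (%.4f, %.4f)\n",
              x$slope, x$intercept, x$direction[1], x$direction[2]))
  invisible(x)
}

#' Spearman screen of bands against the temperature trend
#'
#' Each individual's "arrow score" is the scalar projection of its
#' discriminant-plane score onto the trend arrow direction. For every band, a
#' Spearman rank correlation with the arrow scores is computed, p-values are
#' Bonferroni corrected over the number of bands, and bands with adjusted
#' p < 0.05 form the candidate set, carrying the sign of their correlation as
#' the trend direction (+1 increasing with temperature, -1 decreasing).
#' Correlation-circle coordinates (Spearman correlation of the band with each
#' discriminant axis score) are included for plotting.
#'
#' @param x a [band_matrix()] or numeric matrix (same rows as `scores`).
#' @param arrow a [centroid_trend_arrow()].
#' @param scores per-individual discriminant scores (n x 2), e.g.
#'   `fit_lda(x)$scores`.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @return data frame of class `band_correlations`: `band`, `rho`, `p`,
#'   `p_adj`, `candidate`, `sign`, `circle_1`, `circle_2`; constant bands get
#'   `NA` correlations and are excluded from the candidate set. Arrow scores
#'   are attached as attribute `arrow_scores`.
#' @export
band_trend_correlations <- function(x, arrow, scores, alpha = 0.05) {
  Y <- band_values(x)
  stopifnot(inherits(arrow, "trend_arrow"), nrow(scores) == nrow(Y))
  s <- as.vector(as.matrix(scores)[, 1:2] %*% arrow$direction)
  n_bands <- ncol(Y)
  rho <- p <- rep(NA_real_, n_bands)
  for (j in seq_len(n_bands)) {
    if (stats::sd(Y[, j]) == 0) next  # constant band: correlation undefined
    ct <- suppressWarnings(stats::cor.test(Y[, j], s, method = "spearman",
                                           exact = FALSE))
    rho[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  p_adj <- pmin(1, p * n_bands)
  out <- data.frame(
    band = colnames(Y), rho = rho, p = p, p_adj = p_adj,
    candidate = !is.na(p_adj) & p_adj < alpha,
    sign = ifelse(is.na(rho), 0L, as.integer(sign(rho))),
    circle_1 = suppressWarnings(as.vector(stats::cor(Y, scores[, 1], method = "spearman"))),
    circle_2 = suppressWarnings(as.vector(stats::cor(Y, scores[, 2], method = "spearman"))),
    stringsAsFactors = FALSE
  )
  attr(out, "arrow_scores") <- s
  attr(out, "alpha") <- alpha
  class(out) <- c("band_correlations", "data.frame")
  out
}

#' Global venom-composition trend analysis
#'
#' The full multivariate workflow for one parasitoid line: PERMANOVA of the
#' (normalized) band intensities on temperature and replicate, then
#' within-replicate centering, linear discriminant analysis of the centered
#' intensities on temperature, the least-squares trend arrow through the
#' three temperature centroids, and the Bonferroni-corrected Spearman screen
#' of every band against the arrow scores.
#'
#' @param x a normalized [band_matrix()].
#' @param n_permutations permutations for the PERMANOVA (default 5000).
#' @param seed integer seed for the permutation stream, or `NULL`.
#' @param ridge ridge regularization passed to [fit_lda()].
#' @param alpha significance level for the band screen.
#' @return object of class `venom_trend`: list with `permanova`, `lda`,
#'   `arrow`, `correlations`, `centered` (the centered matrix).
#' @export
venom_trend <- function(x, n_permutations = 5000, seed = NULL, ridge = 1e-8,
                        alpha = 0.05) {
  stopifnot(inherits(x, "band_matrix"))
  perm <- permanova(x, n_permutations = n_permutations, seed = seed)
  centered <- center_within_replicates(x)
  lda <- fit_lda(centered, ridge = ridge)
  arrow <- centroid_trend_arrow(lda$centroids[, 1:2, drop = FALSE])
  cors <- band_trend_correlations(centered, arrow, lda$scores, alpha = alpha)
  structure(
    list(permanova = perm, lda = lda, arrow = arrow, correlations = cors,
         centered = centered, call = match.call()),
    class = "venom_trend"
  )
}

#' @export
print.venom_trend <- function(x, ...) {
  cat("Venom composition temperature-trend analysis\n\n")
  print(x$permanova)
  cat("\n")
  print(x$lda)
  cat("\n")
  print(x$arrow)
  nc <- sum(x$correlations$candidate)
  cat(sprintf("\n%d of %d bands correlated with the trend (Bonferroni p < %.2g): %s\n",
              nc, nrow(x$correlations), attr(x$correlations, "alpha"),
              paste(x$correlations$band[x$correlations$candidate], collapse = ", ")))
  invisible(x)
}

#' @export
summary.venom_trend <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot a venom trend analysis
#'
#' Two panels: individuals on the two discriminant axes, colored by
#' temperature, with the centroid trend arrow; and the correlation circle of
#' the bands, candidates highlighted.
#'
#' @param x a [venom_trend()] object.
#' @param ... ignored.
#' @export
plot.venom_trend <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sc <- x$lda$scores
  grp <- x$lda$groups
  cols <- grDevices::hcl.colors(nlevels(grp), "Zissou 1")[as.integer(grp)]
  graphics::plot(sc[, 1], sc[, 2], col = cols, pch = 19,
                 xlab = "LD1", ylab = "LD2", main = "Discriminant scores")
  graphics::legend("topright", legend = levels(grp), col =
                     grDevices::hcl.colors(nlevels(grp), "Zissou 1"), pch = 19,
                   title = "temperature", bty = "n")
  cen <- x$arrow$centroids
  graphics::points(cen[, 1], cen[, 2], pch = 4, cex = 2, lwd = 2)
  graphics::arrows(cen[1, 1], cen[1, 2],
                   cen[1, 1] + x$arrow$direction[1] * max(dist(cen)),
                   cen[1, 2] + x$arrow$direction[2] * max(dist(cen)),
                   col = "darkgreen", lwd = 2)
  co <- x$correlations
  graphics::symbols(0, 0, circles = 1, inches = FALSE, asp = 1,
                    xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                    xlab = "cor with LD1", ylab = "cor with LD2",
                    main = "Correlation circle", fg = "grey")
  graphics::text(co$circle_1, co$circle_2, labels = sub("band_", "", co$band),
                 col = ifelse(co$candidate, "red", "grey30"), cex = 0.7)
  graphics::arrows(0, 0, x$arrow$direction[1], x$arrow$direction[2],
                   col = "darkgreen", lwd = 2)
  invisible(x)
}
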