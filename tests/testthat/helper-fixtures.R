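# small fixture builders shared across test files

# band matrix from a plain value matrix, balanced temps x replicates
make_bm <- function(values, temps = NULL, reps = NULL) {
  n <- nrow(values)
  if (is.null(temps)) temps <- rep(c(20, 25, 30), length.out = n)
  if (is.null(reps)) reps <- rep(c("r1", "r2"), length.out = n)
  band_matrix(values, temperature = temps, replicate = reps)
}

# naive sequential multivariate ANOVA F statistics (independent of the
# package's QR route): per-column sums of squares via fitted values of lm()
naive_seq_F <- function(Y, f1, f2 = NULL) {
  Yc <- sweep(Y, 2, colMeans(Y))
  tot <- sum(Yc^2)
  ss_fit <- function(form, dat) {
    fits <- lm(form, data = dat)
    sum(scale(fitted(fits), scale = FALSE)^2)
  }
  dat <- data.frame(f1 = factor(f1))
  s1 <- ss_fit(Y ~ f1, dat)
  if (is.null(f2)) {
    df1 <- nlevels(dat$f1) - 1
    dfr <- nrow(Y) - nlevels(dat$f1)
    ssr <- tot - s1
    return(list(ss = s1, F = (s1 / df1) / (ssr / dfr), tot = tot))
  }
  dat$f2 <- factor(f2)
  s12 <- ss_fit(Y ~ f1 + f2, dat)
  df1 <- nlevels(dat$f1) - 1
  df2 <- qr(model.matrix(~ f1 + f2, dat))$rank - qr(model.matrix(~f1, dat))$rank
  dfr <- nrow(Y) - qr(model.matrix(~ f1 + f2, dat))$rank
  ssr <- tot - s12
  list(ss = c(s1, s12 - s1), F = c((s1 / df1) / (ssr / dfr), ((s12 - s1) / df2) / (ssr / dfr)),
       tot = tot)
}

# all permutations of 1..n, iteratively (oracle-side enumeration)
all_perms_oracle <- function(n) {
  out <- list(1L)
  for (m in 2:n) {
    nxt <- vector("list", length(out) * m)
    k <- 0L
    for (p in out) {
      for (pos in seq_len(m)) {
        k <- k + 1L
        nxt[[k]] <- append(p, m, after = pos - 1L)
      }
    }
    out <- nxt
  }
  out
}

# rank-based partial correlation by the textbook residual-on-residual route:
# rank-transform, regress x and y on the conditioners, correlate residuals
residual_partial_cor <- function(x, y, Z) {
  Rk <- apply(cbind(x, y, Z), 2, rank)
  rx <- residuals(lm(Rk[, 1] ~ Rk[, -(1:2)]))
  ry <- residuals(lm(Rk[, 2] ~ Rk[, -(1:2)]))
  cor(rx, ry)
}
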