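#' UPGMA tree of bands on the correlation distance
#'
#' Pairwise distance between bands is `1 - |rho|` with rho the Spearman
#' correlation of their intensities across individuals, so that strongly
#' correlated bands (of either sign) are close. Agglomeration is
#' average-linkage (UPGMA). Constant bands have undefined correlations and
#' are assigned distance 1 to every other band, with a warning.
#'
#' @param x a [band_matrix()] or numeric matrix with >= 2 bands.
#' @return an [stats::hclust] tree whose labels are the band names.
#' @export
correlation_distance_tree <- function(x) {
  Y <- band_values(x)
  if (ncol(Y) < 2) stop("at least 2 bands are required")
  S <- suppressWarnings(stats::cor(Y, method = "spearman"))
  if (anyNA(S)) {
    warning("constant band(s) with undefined correlations; assigned distance 1 to all other bands")
    S[is.na(S)] <- 0
  }
  D <- 1 - abs(S)
  diag(D) <- 0
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Cut the band tree at a correlation threshold
#'
#' Flat clusters are formed by cutting the UPGMA tree at height
#' `1 - rho_threshold`, so that cluster members are linked at
#' `|rho| >= rho_threshold` (default 0.45, cut height 0.55).
#'
#' @param tree an [stats::hclust] tree from [correlation_distance_tree()].
#' @param rho_threshold correlation threshold in (0, 1).
#' @return named integer vector of cluster memberships, one per band.
#' @export
cut_tree_at_threshold <- function(tree, rho_threshold = 0.45) {
  if (rho_threshold <= 0 || rho_threshold >= 1) stop("'rho_threshold' must be in (0, 1)")
  stats::cutree(tree, h = 1 - rho_threshold)
}

# rank-based (Spearman-type) partial correlation of x and y given the columns
# of Z, via inversion of the Pearson correlation matrix of the rank-transformed
# variables; returns the coefficient and its t-test p-value
.rank_partial_cor <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  Rk <- apply(M, 2, rank)
  R <- stats::cor(Rk)
  P <- solve(R)
  pr <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  n <- nrow(M)
  k <- ncol(M) - 2
  stat <- pr * sqrt((n - 2 - k) / max(1 - pr^2, .Machine$double.eps))
  list(estimate = pr, p = 2 * stats::pt(-abs(stat), df = n - 2 - k))
}

#' Partial-correlation screen of candidate bands
#'
#' Disambiguates bands directly affected by temperature from bands that only
#' track an affected neighbour. Within every cluster holding at least two
#' candidate bands (from [band_trend_correlations()]), each candidate's
#' rank-based partial correlation with the arrow scores is computed,
#' conditioning on the other candidate bands of the cluster. P-values are
#' Bonferroni corrected over the number of bands screened in this step. A
#' screened candidate stays `direct` iff its adjusted partial p < `alpha`,
#' otherwise it becomes `indirect`; candidates alone in their cluster are
#' `direct` with their marginal classification; non-candidates are
#' `unaffected`. Direct bands keep the sign of their marginal Spearman
#' correlation as the trend direction.
#'
#' @param x the [band_matrix()] used for the correlations (centered).
#' @param clusters cluster memberships from [cut_tree_at_threshold()].
#' @param correlations a [band_trend_correlations()] table.
#' @param arrow_scores per-individual arrow scores; defaults to the ones
#'   attached to `correlations`.
#' @param alpha significance level on the adjusted partial p.
#' @return data frame of class `band_screen`: `band`, `cluster`, `class`
#'   (direct/indirect/unaffected), `sign`, marginal `rho` and `p_adj`,
#'   `partial_rho`, `partial_p`, `partial_p_adj`. The number of bands screened
#'   is attached as attribute `n_screened`.
#' @export
partial_correlation_screen <- function(x, clusters, correlations,
                                       arrow_scores = NULL, alpha = 0.05) {
  Y <- band_values(x)
  stopifnot(all(correlations$band %in% colnames(Y)),
            length(clusters) == ncol(Y))
  if (is.null(arrow_scores)) arrow_scores <- attr(correlations, "arrow_scores")
  stopifnot(length(arrow_scores) == nrow(Y))
  n <- nrow(Y)
  out <- data.frame(
    band = correlations$band,
    cluster = as.integer(clusters[correlations$band]),
    class = "unaffected",
    sign = 0L,
    rho = correlations$rho,
    p_adj = correlations$p_adj,
    partial_rho = NA_real_, partial_p = NA_real_, partial_p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  cand <- which(correlations$candidate)
  screened <- cand[vapply(cand, function(i) {
    sum(out$cluster[cand] == out$cluster[i]) >= 2
  }, logical(1))]
  n_screened <- length(screened)
  for (i in cand) {
    if (!(i %in% screened)) {
      out$class[i] <- "direct"  # nothing to condition on
      out$sign[i] <- correlations$sign[i]
      next
    }
    others <- setdiff(screened[out$cluster[screened] == out$cluster[i]], i)
    if (length(others) > n - 3) {
      stop("conditioning set larger than sample size - 3; cannot compute partial correlation")
    }
    pc <- .rank_partial_cor(Y[, out$band[i]], arrow_scores,
                            Y[, out$band[others], drop = FALSE])
    out$partial_rho[i] <- pc$estimate
    out$partial_p[i] <- pc$p
    out$partial_p_adj[i] <- min(1, pc$p * n_screened)
    out$class[i] <- if (out$partial_p_adj[i] < alpha) "direct" else "indirect"
    out$sign[i] <- correlations$sign[i]
  }
  attr(out, "n_screened") <- n_screened
  attr(out, "alpha") <- alpha
  class(out) <- c("band_screen", "data.frame")
  out
}

#' Cluster-and-partial-correlation screen of a venom trend analysis
#'
#' Convenience wrapper chaining [correlation_distance_tree()],
#' [cut_tree_at_threshold()] and [partial_correlation_screen()] on a fitted
#' [venom_trend()] object.
#'
#' @param trend a [venom_trend()] object.
#' @param rho_threshold correlation threshold for the tree cut (default
#'   0.45).
#' @param alpha significance level for the partial-correlation step.
#' @return a `band_screen` table (see [partial_correlation_screen()]) with
#'   the UPGMA tree attached as attribute `tree` and the threshold as
#'   attribute `rho_threshold`.
#' @export
screen_bands <- function(trend, rho_threshold = 0.45, alpha = 0.05) {
  stopifnot(inherits(trend, "venom_trend"))
  tree <- correlation_distance_tree(trend$centered)
  clusters <- cut_tree_at_threshold(tree, rho_threshold)
  screen <- partial_correlation_screen(trend$centered, clusters,
                                       trend$correlations, alpha = alpha)
  attr(screen, "tree") <- tree
  attr(screen, "rho_threshold") <- rho_threshold
  screen
}

#' @export
print.band_screen <- function(x, digits = 3, ...) {
  counts <- table(factor(x$class, levels = c("direct", "indirect", "unaffected")))
  cat(sprintf("band screen: %d direct, %d indirect, %d unaffected (of %d bands); %d screened by partial correlation\n",
              counts[["direct"]], counts[["indirect"]], counts[["unaffected"]],
              nrow(x), attr(x, "n_screened")))
  hit <- x[x$class != "unaffected", , drop = FALSE]
  if (nrow(hit) > 0) {
    hit$trend <- ifelse(hit$class == "direct",
                        ifelse(hit$sign > 0, "increasing", "decreasing"), "")
    print.data.frame(format(as.data.frame(hit), digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Annotate screened bands with their protein content
#'
#' Joins the screen classification with a band -> protein annotation table
#' and flags proteins as abundant when their mass-spectrometry peptide match
#' count reaches the threshold (default 10). Annotation tables for the ISm
#' and ISy lines (from the published venom proteomics) ship with the package
#' under `inst/extdata/`.
#'
#' @param screen a `band_screen` table.
#' @param annotations data frame with columns `band_id`, `protein`,
#'   `peptide_matches` (one row per protein found in a band).
#' @param min_peptide_matches abundance threshold on the peptide match count.
#' @return data frame of class `band_report`: one row per (band, protein)
#'   with `band`, `class`, `trend`, `protein`, `peptide_matches`, `abundant`.
#'   Unmatched annotation band ids are dropped with a warning.
#' @export
annotate_abundant_proteins <- function(screen, annotations,
                                       min_peptide_matches = 10) {
  stopifnot(inherits(screen, "band_screen"),
            all(c("band_id", "protein", "peptide_matches") %in% names(annotations)))
  band_ids <- sub("^band_", "", screen$band)
  unknown <- !(as.character(annotations$band_id) %in% band_ids)
  if (any(unknown)) {
    warning("annotation band id(s) not in the screen, ignored: ",
            paste(unique(annotations$band_id[unknown]), collapse = ", "))
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  idx <- match(as.character(annotations$band_id), band_ids)
  out <- data.frame(
    band = screen$band[idx],
    class = screen$class[idx],
    trend = ifelse(screen$class[idx] == "direct",
                   ifelse(screen$sign[idx] > 0, "increasing", "decreasing"), ""),
    protein = annotations$protein,
    peptide_matches = annotations$peptide_matches,
    abundant = !is.na(annotations$peptide_matches) &
      annotations$peptide_matches >= min_peptide_matches,
    stringsAsFactors = FALSE
  )
  out <- out[order(idx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_peptide_matches") <- min_peptide_matches
  class(out) <- c("band_report", "data.frame")
  out
}

#' @export
print.band_report <- function(x, ...) {
  cat(sprintf("band report (abundant = >= %d peptide matches)\n",
              attr(x, "min_peptide_matches")))
  dir <- x[x$class == "direct" & x$abundant, , drop = FALSE]
  cat(sprintf("direct temperature-affected bands with abundant proteins: %d\n", nrow(dir)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
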