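#' Gene-set overlap statistics
#'
#' For two gene sets of sizes `n_A` and `n_B` drawn from a universe of `N`
#' tested genes, computes the independence expectation `n_A * n_B / N`, the
#' chi-squared statistic of the implied 2x2 contingency table (df = 1; no
#' continuity correction by default), and the hypergeometric upper-tail
#' probability of observing at least `observed` shared genes.
#'
#' @param n_A,n_B sizes of the two gene sets (0 <= n <= N).
#' @param N size of the tested-gene universe.
#' @param observed number of genes in both sets (<= min(n_A, n_B)).
#' @param correct logical, apply the Yates continuity correction to the
#'   chi-squared statistic (default FALSE).
#' @return an `overlap_result` list: `n_A`, `n_B`, `N`, `observed`,
#'   `expected`, `chi2`, `p_chi2`, `p_hypergeom`.
#' @examples
#' overlap_stats(1269, 765, 11640, 137)$expected  # 83.4
#' @export
overlap_stats <- function(n_A, n_B, N, observed, correct = FALSE) {
  for (nm in c("n_A", "n_B", "N", "observed"))
    assert_scalar_finite(get(nm), nm)
  if (n_A < 0 || n_B < 0 || n_A > N || n_B > N)
    stop_invalid("need 0 <= n_A, n_B <= N")
  if (observed < 0 || observed > min(n_A, n_B))
    stop_invalid("observed must lie in [0, min(n_A, n_B)]")
  if (observed < n_A + n_B - N)
    stop_invalid("observed incompatible with the marginals")
  expected <- n_A * n_B / N
  # 2x2 table: in-both, A-only, B-only, neither; expectations from margins
  obs <- c(observed, n_A - observed, n_B - observed, N - n_A - n_B + observed)
  exp4 <- c(expected, n_A * (N - n_B) / N, (N - n_A) * n_B / N,
            (N - n_A) * (N - n_B) / N)
  dev <- abs(obs - exp4)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / exp4)
  list(n_A = n_A, n_B = n_B, N = N, observed = observed, expected = expected,
       chi2 = chi2, p_chi2 = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       p_hypergeom = stats::phyper(observed - 1, n_A, N - n_A, n_B,
                                   lower.tail = FALSE))
}

#' Classify overlap genes by response direction
#'
#' A gene responding in opposite directions to the two treatments (mating vs
#' heat shock) is antagonistic; same direction is concordant. Genes with a
#' zero log-fold change in either treatment are excluded (counted in
#' `n_excluded`). Also returns the four-quadrant breakdown and the exact
#' binomial upper-tail probability of at least `max(antagonistic, concordant)`
#' successes out of the classified genes at null probability 0.5.
#'
#' @param panel data.frame with columns `gene_id`, `lfc_mating`, `lfc_heat`
#'   (finite for every gene).
#' @return a list: `antagonistic`, `concordant`, `quadrants` (named counts
#'   `up_mating_down_heat`, `down_mating_up_heat`, `both_up`, `both_down`),
#'   `n`, `n_excluded`, `p_binomial`.
#' @export
classify_directions <- function(panel) {
  need <- c("gene_id", "lfc_mating", "lfc_heat")
  if (!all(need %in% names(panel)))
    stop_schema("panel needs columns gene_id, lfc_mating, lfc_heat")
  if (any(!is.finite(panel$lfc_mating)) || any(!is.finite(panel$lfc_heat)))
    stop_invalid("log-fold changes must be finite for every gene")
  zero <- panel$lfc_mating == 0 | panel$lfc_heat == 0
  n_excluded <- sum(zero)
  if (n_excluded > 0)
    message(sprintf("excluded %d gene(s) with zero log-fold change",
                    n_excluded))
  p <- panel[!zero, , drop = FALSE]
  sm <- sign(p$lfc_mating); sh <- sign(p$lfc_heat)
  quadrants <- c(
    up_mating_down_heat = sum(sm > 0 & sh < 0),
    down_mating_up_heat = sum(sm < 0 & sh > 0),
    both_up = sum(sm > 0 & sh > 0),
    both_down = sum(sm < 0 & sh < 0))
  antag <- unname(quadrants[1] + quadrants[2])
  conc <- unname(quadrants[3] + quadrants[4])
  n <- antag + conc
  p_binom <- if (n > 0)
    stats::pbinom(max(antag, conc) - 1, n, 0.5, lower.tail = FALSE)
  else NA_real_
  list(antagonistic = antag, concordant = conc, quadrants = quadrants,
       n = n, n_excluded = n_excluded, p_binomial = p_binom)
}

#' Per-sample reproduction and heat-stress trade-off scores
#'
#' For each sample, `score_R = sum_g lfc_mating(g) * count(g)` and
#' `score_HS = sum_g lfc_heat(g) * count(g)` over the panel genes, using the
#' sample's normalized counts as provided (no internal re-normalization).
#' On a purely antagonistic panel the two scores are tightly negatively
#' correlated and place samples along a single reproduction-maintenance axis.
#'
#' @param panel data.frame with `gene_id`, `lfc_mating`, `lfc_heat`.
#' @param counts numeric matrix of normalized counts, genes x samples, with
#'   rownames matching `panel$gene_id` (same order and length).
#' @return data.frame with columns `sample_id`, `score_R`, `score_HS`.
#' @export
tradeoff_scores <- function(panel, counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) != nrow(panel))
    stop_invalid("counts rows must align with the gene panel")
  if (!is.null(rownames(counts)) &&
      !identical(rownames(counts), as.character(panel$gene_id)))
    stop_invalid("counts rownames do not match panel gene ids")
  if (any(counts < 0)) stop_invalid("normalized counts must be >= 0")
  score_R <- drop(crossprod(counts, panel$lfc_mating))
  score_HS <- drop(crossprod(counts, panel$lfc_heat))
  data.frame(sample_id = colnames(counts) %||% seq_len(ncol(counts)),
             score_R = score_R, score_HS = score_HS, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project samples onto the trade-off axis
#'
#' Centers the 2-D cloud of (score_R, score_HS) points, extracts the leading
#' eigenvector of its covariance matrix, and projects each sample onto it.
#' The eigenvector sign is fixed so that the positive direction has a
#' positive loading on `score_HS` (the cellular-maintenance pole), making
#' projections comparable across runs. Also returns the Pearson correlation
#' of the two scores.
#'
#' @param scores data.frame with columns `score_R`, `score_HS` (>= 3 rows,
#'   non-degenerate).
#' @return a list: `projection` (per-sample coordinate along the axis),
#'   `axis` (unit eigenvector, loadings on score_R and score_HS), `center`,
#'   `var_explained` (fraction of variance on the axis), `correlation`.
#' @export
tradeoff_axis_projection <- function(scores) {
  if (!all(c("score_R", "score_HS") %in% names(scores)) || nrow(scores) < 3)
    stop_invalid("scores need columns score_R, score_HS and >= 3 samples")
  X <- cbind(scores$score_R, scores$score_HS)
  if (all(apply(X, 2, stats::sd) == 0))
    stop_degenerate("zero-variance score cloud: axis undefined")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (v[2] < 0) v <- -v   # maintenance-pole sign convention
  proj <- drop(Xc %*% v)
  corr <- if (stats::sd(X[, 1]) > 0 && stats::sd(X[, 2]) > 0)
    stats::cor(X[, 1], X[, 2]) else NA_real_
  list(projection = proj, axis = c(score_R = v[1], score_HS = v[2]),
       center = c(score_R = ctr[1], score_HS = ctr[2]),
       var_explained = eg$values[1] / sum(eg$values),
       correlation = corr)
}
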