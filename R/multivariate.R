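#' Sample cross-product PCA of a processed feature table
#'
#' Forms the n x n sample cross-product of the processed abundance
#' matrix (samples in rows), eigen-decomposes it, and returns the
#' eigenvalues, the percent of total variation per component, and the
#' component scores (eigenvector * sqrt(eigenvalue)). This is exactly
#' the PCA obtained from the singular value decomposition of the data
#' matrix, computed on the sample side because p >> n. Signs are fixed
#' so the largest-magnitude entry of each score vector is positive.
#'
#' @param table A processed [feature_table()] (complete matrix), or a
#'   plain numeric matrix.
#' @return List of class `pca_result`: `eigenvalues` (descending),
#'   `percent_total_variation`, `scores` (samples x components).
#' @export
crossproduct_pca <- function(table) {
  X <- if (inherits(table, "feature_table")) table$abundances else as.matrix(table)
  if (anyNA(X)) stop("matrix must be complete; impute first")
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- eg$vectors %*% diag(sqrt(ev), n)
  # deterministic sign: largest-|.| coordinate of each component positive
  for (k in seq_len(n)) {
    j <- which.max(abs(scores[, k]))
    if (scores[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("Pc", seq_len(n))
  structure(
    list(eigenvalues = ev,
         percent_total_variation = 100 * ev / sum(ev),
         scores = scores),
    class = "pca_result"
  )
}

#' Regress a trait on one principal component score
#'
#' OLS of trait = intercept + age + smoking + Pc_k, with Bonferroni
#' adjustment over the number of components examined (default 10).
#'
#' @param trait Transformed response vector.
#' @param covariates data.frame with `age`, `smoking`.
#' @param scores Score matrix from [crossproduct_pca()].
#' @param k Component index (<= `n_tested`).
#' @param n_tested Number of components in the Bonferroni family.
#' @return One-row data.frame: `component`, `effect`, `se`, `p`,
#'   `bonferroni`, `df`.
#' @export
regress_trait_on_pc <- function(trait, covariates, scores, k,
                                n_tested = 10) {
  if (k > n_tested) stop("component index exceeds the tested family")
  rec <- fit_single_lipid(trait, covariates, scores[, k],
                          ion = paste0("Pc", k))
  data.frame(component = k, effect = rec$effect, se = rec$se, p = rec$p,
             bonferroni = min(1, rec$p * n_tested), df = rec$df,
             row.names = NULL)
}

#' Regress a principal component score on every lipid
#'
#' One-predictor OLS per lipid (score = intercept + lipid), Bonferroni
#' adjusted over all lipids, with the top and bottom effect lists used
#' to pick component-driving lipids.
#'
#' @param score Score vector for one component.
#' @param table Processed [feature_table()].
#' @param n_top Size of the top/bottom lists (default 10).
#' @return List: `records` (ion, effect, se, p, bonferroni),
#'   `top_positive`, `top_negative` (data.frames, strongest first).
#' @export
regress_pc_on_lipids <- function(score, table, n_top = 10) {
  L <- table$abundances
  if (anyNA(L)) stop("feature table has missing values")
  n <- nrow(L)
  Lc <- scale(L, center = TRUE, scale = FALSE)
  yc <- score - mean(score)
  ss_l <- colSums(Lc^2)
  beta <- colSums(Lc * yc) / ss_l
  df <- n - 2
  sigma2 <- pmax(sum(yc^2) - beta^2 * ss_l, 0) / df
  se <- sqrt(sigma2 / ss_l)
  pval <- 2 * stats::pt(-abs(beta / se), df)
  records <- data.frame(ion = colnames(L), effect = beta, se = se, p = pval,
                        bonferroni = pmin(1, pval * ncol(L)),
                        stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(records$effect, decreasing = TRUE)
  list(records = records,
       top_positive = records[ord[seq_len(min(n_top, nrow(records)))], ],
       top_negative = records[rev(ord)[seq_len(min(n_top, nrow(records)))], ])
}

#' SVD biplot of the lipid-by-trait effect matrix
#'
#' Decomposes the (lipids x traits) matrix of single-lipid effects as
#' U D V'; lipid points are U D (first two vectors), trait arrows are V.
#' The percent of variation carried by the first two vectors, the
#' per-lipid radius (Euclidean norm of its 2-D coordinates) and the
#' highlight flag (normalized radius > `highlight_radius`) are computed
#' before any display scaling; per-trait display factors affect the
#' plotted arrow coordinates only. NA effects (rank-deficient fits) are
#' replaced by 0 with a warning. Because the absolute coordinate units
#' of the radius rule are convention dependent, both the raw radius and
#' the radius normalized by the largest lipid norm are returned.
#'
#' @param effects Lipids x traits numeric matrix (>= 2 traits).
#' @param highlight_radius Highlight threshold on the normalized radius
#'   (default 0.15).
#' @param display_scale Optional named per-trait scale factors for
#'   plotting (e.g. `c(MCP1 = 25)`).
#' @return List of class `biplot_result`: `points` (lipids x 2),
#'   `arrows` (traits x 2), `plot_arrows` (display-scaled), `d`
#'   (singular values), `percent_first_two`, `radius`,
#'   `radius_normalized`, `highlighted`.
#' @export
effect_biplot <- function(effects, highlight_radius = 0.15,
                          display_scale = NULL) {
  effects <- as.matrix(effects)
  if (ncol(effects) < 2) stop("need at least 2 traits")
  if (anyNA(effects)) {
    warning("NA effects replaced by 0 in the biplot")
    effects[is.na(effects)] <- 0
  }
  sv <- svd(effects)
  # deterministic sign: largest-|.| trait loading positive per vector
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  pts <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  rownames(pts) <- rownames(effects)
  arrows <- sv$v[, 1:2, drop = FALSE]
  rownames(arrows) <- colnames(effects)
  colnames(pts) <- colnames(arrows) <- c("v1", "v2")
  radius <- sqrt(rowSums(pts^2))
  radius_norm <- if (max(radius) > 0) radius / max(radius) else radius
  plot_arrows <- arrows
  if (!is.null(display_scale)) {
    for (tr in names(display_scale)) {
      if (tr %in% rownames(plot_arrows)) {
        plot_arrows[tr, ] <- plot_arrows[tr, ] * display_scale[[tr]]
      }
    }
  }
  structure(
    list(points = pts, arrows = arrows, plot_arrows = plot_arrows,
         d = sv$d,
         percent_first_two = 100 * sum(sv$d[1:2]^2) / sum(sv$d^2),
         radius = radius, radius_normalized = radius_norm,
         highlighted = radius_norm > highlight_radius),
    class = "biplot_result"
  )
}
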