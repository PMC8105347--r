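#' Measurement-error percentage from repeated acquisitions
#'
#' One-way ANOVA with individuals as groups, following the
#' variance-component definition of measurement error: %ME is the within-
#' measurement variance component divided by the sum of the within- and
#' among-individual components, times 100. The among component uses the
#' standard ANOVA estimator \eqn{(MS_{among} - MS_{within})/m}, clamped
#' at zero.
#'
#' @param values numeric vector, one scalar per measurement.
#' @param individual_ids parallel vector of individual labels; the design
#'   must be balanced (each individual measured the same `m >= 2` times).
#' @return Object of class `me_result`: list with `F`, `p`, `pct_me`,
#'   `ms_within`, `ms_among`, `m`, `n_individuals`.
#' @export
measurement_error <- function(values, individual_ids) {
  ids <- factor(individual_ids)
  if (nlevels(ids) < 2) stop2("measurement_error needs >= 2 individuals")
  counts <- table(ids)
  if (length(unique(as.integer(counts))) != 1L)
    stop2("unbalanced design: individuals have differing repeat counts")
  m <- as.integer(counts[1])
  if (m < 2) stop2("each individual must be measured at least twice")
  fit <- stats::aov(values ~ ids)
  tab <- summary(fit)[[1]]
  ms_among <- tab["ids", "Mean Sq"]
  ms_within <- tab["Residuals", "Mean Sq"]
  s2w <- ms_within
  s2a <- max(0, (ms_among - ms_within) / m)
  pct <- if (s2w + s2a == 0) 0 else 100 * s2w / (s2w + s2a)
  structure(list(F = unname(tab["ids", "F value"]),
                 p = unname(tab["ids", "Pr(>F)"]),
                 pct_me = unname(pct),
                 ms_within = unname(ms_within), ms_among = unname(ms_among),
                 m = m, n_individuals = nlevels(ids)),
            class = "me_result")
}

#' @export
print.me_result <- function(x, ...) {
  cat(sprintf("<me_result> F = %.4g, p = %.3g, %%ME = %.3f (m = %d, N = %d)\n",
              x$F, x$p, x$pct_me, x$m, x$n_individuals))
  invisible(x)
}

#' Shape measurement error across principal components
#'
#' The reproducibility ANOVA needs a scalar; for multivariate shape
#' coefficients this computes %ME (a) separately on each retained PC of
#' the repeated-measures coefficient matrix and (b) pooled, from variance
#' components summed across those PCs.
#'
#' @param coeffs coefficient matrix (rows = repeated measurements).
#' @param individual_ids individual of each row (balanced design).
#' @param n_pc PCs to retain (default: enough for 95% of variance).
#' @return List with `per_pc` (data frame) and `pooled` (an `me_result`
#'   carrying the pooled %ME and the first PC's F test).
#' @export
measurement_error_shape <- function(coeffs, individual_ids, n_pc = NULL) {
  pca <- stats::prcomp(coeffs, center = TRUE, scale. = FALSE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  if (is.null(n_pc)) n_pc <- max(1L, which(cumsum(expl) >= 0.95)[1])
  n_pc <- min(n_pc, ncol(pca$x))
  per <- lapply(seq_len(n_pc), function(j)
    measurement_error(pca$x[, j], individual_ids))
  per_pc <- data.frame(pc = seq_len(n_pc),
                       F = vapply(per, `[[`, numeric(1), "F"),
                       p = vapply(per, `[[`, numeric(1), "p"),
                       pct_me = vapply(per, `[[`, numeric(1), "pct_me"))
  m <- per[[1]]$m
  s2w <- sum(vapply(per, `[[`, numeric(1), "ms_within"))
  s2a <- sum(vapply(per, function(x) max(0, (x$ms_among - x$ms_within) / m),
                    numeric(1)))
  pooled <- per[[1]]
  pooled$pct_me <- if (s2w + s2a == 0) 0 else 100 * s2w / (s2w + s2a)
  list(per_pc = per_pc, pooled = pooled, n_pc = n_pc)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based H statistic for a multi-group comparison
#' (wraps [stats::kruskal.test()]); all-identical values are guarded to
#' statistic 0 with p = 1 rather than a division by zero.
#'
#' @param values numeric vector.
#' @param groups parallel group labels (>= 2 non-empty groups).
#' @return List with `chi2`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop2("need at least 2 groups")
  if (any(table(groups) == 0)) stop2("empty group")
  if (length(unique(values)) == 1L)
    return(list(chi2 = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum P-value for every pair of groups: exact for small
#' samples without ties, normal approximation with tie and continuity
#' correction otherwise ([stats::wilcox.test()] semantics). P-values are
#' raw by default; set `p_adjust` to a [stats::p.adjust()] method to
#' correct them.
#'
#' @param values numeric vector.
#' @param groups parallel group labels.
#' @param p_adjust `"none"` (default) or a `p.adjust` method.
#' @return Symmetric matrix of P-values, diagonal `NA`.
#' @export
pairwise_wilcoxon <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop2("need at least 2 groups")
  if (any(table(groups) == 0)) stop2("empty group")
  g <- levels(groups)
  P <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)[-1]) for (j in seq_len(i - 1)) {
    P[i, j] <- P[j, i] <- suppressWarnings(
      stats::wilcox.test(values[groups == g[i]], values[groups == g[j]],
                         exact = NULL)$p.value)
  }
  if (p_adjust != "none") {
    lower <- P[lower.tri(P)]
    P[lower.tri(P)] <- stats::p.adjust(lower, method = p_adjust)
    P[upper.tri(P)] <- t(P)[upper.tri(P)]
  }
  P
}

#' Centered PCA with supplementary projection
#'
#' `pca_fit` runs a centered (unscaled) principal component analysis;
#' `pca_project` projects supplementary rows with the training center and
#' loadings so they do not influence the axes.
#'
#' @param X numeric matrix (>= 2 rows).
#' @return `pca_fit`: object of class `pca_model` with `center`,
#'   `loadings` (orthonormal columns), `explained` (variance fractions),
#'   `scores`.
#' @export
pca_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop2("PCA needs >= 2 rows")
  if (all(apply(X, 2, stats::var) < .Machine$double.eps))
    stop2("constant matrix: PCA undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(center = pc$center, loadings = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2), scores = pc$x),
            class = "pca_model")
}

#' @rdname pca_fit
#' @param model a `pca_model`.
#' @param new_rows matrix with the training variable count.
#' @export
pca_project <- function(model, new_rows) {
  new_rows <- rbind(new_rows)
  if (ncol(new_rows) != length(model$center))
    stop2("projection rows have ", ncol(new_rows), " variables; model has ",
          length(model$center))
  sweep(new_rows, 2, model$center) %*% model$loadings
}

#' Permutational MANOVA on Euclidean distances
#'
#' Distance-based one-way multivariate test: pseudo-F is
#' \eqn{(SS_B/(g-1)) / (SS_W/(N-g))} from the Euclidean partition of the
#' coefficient matrix (equivalently the Gower-centered distance matrix),
#' with the null distribution built by permuting group labels. The
#' P-value uses the \eqn{(1 + b)/(n_{perm} + 1)} estimator. The adjusted
#' R-squared applies the usual degrees-of-freedom penalty,
#' \eqn{1 - (1-R^2)(N-1)/(N-g)}.
#'
#' @param X numeric matrix of shape variables.
#' @param labels group of each row (every group needs >= 2 members).
#' @param n_perm permutations (>= 99).
#' @param seed RNG seed for the label permutations (required).
#' @return Object of class `permanova_result`: `F`, `r2`, `adj_r2`, `p`,
#'   `df_between`, `df_within`, `n_perm`.
#' @export
permutational_manova <- function(X, labels, n_perm = 999, seed) {
  if (missing(seed)) stop2("permutational_manova requires an explicit seed")
  if (n_perm < 99) stop2("n_perm must be >= 99")
  X <- as.matrix(X)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop2("every group needs at least 2 members")
  N <- nrow(X); g <- nlevels(labels)
  Xc <- sweep(X, 2, colMeans(X))
  ss_total <- sum(Xc^2)
  ssb <- function(lab) {
    S <- rowsum(Xc, lab)
    n <- as.numeric(table(lab))
    sum(S^2 / n)
  }
  ss_between <- ssb(labels)
  ss_within <- ss_total - ss_between
  Fobs <- (ss_between / (g - 1)) / (ss_within / (N - g))
  r2 <- ss_between / ss_total
  adj_r2 <- 1 - (1 - r2) * (N - 1) / (N - g)
  b <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      lab <- sample(labels)
      sb <- ssb(lab)
      Fp <- (sb / (g - 1)) / ((ss_total - sb) / (N - g))
      if (Fp >= Fobs) hits <- hits + 1L
    }
    hits
  })
  structure(list(F = Fobs, r2 = r2, adj_r2 = adj_r2,
                 p = (1 + b) / (n_perm + 1),
                 df_between = g - 1L, df_within = N - g, n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> df = %d, F = %.4g, r2 = %.3f, adj r2 = %.3f, p = %.4g (%d perms)\n",
              x$df_between, x$F, x$r2, x$adj_r2, x$p, x$n_perm))
  invisible(x)
}

#' Mean shape per taxon
#'
#' Arithmetic mean of each Fourier coefficient across the specimens of a
#' taxon, with the mean outline reconstructed from the averaged
#' coefficients.
#'
#' @param coeffs coefficient matrix ([coeff_matrix()] layout).
#' @param taxa taxon of each row.
#' @param k points for the reconstructed outlines.
#' @return List with `coeffs` (matrix of per-taxon means) and `outlines`
#'   (named list of reconstructions).
#' @export
mean_shapes <- function(coeffs, taxa, k = 360) {
  taxa <- factor(taxa)
  M <- rowsum(as.matrix(coeffs), taxa) / as.numeric(table(taxa))
  outs <- lapply(rownames(M), function(tx) inverse_efourier(row_to_eft(M[tx, ]), k = k))
  names(outs) <- rownames(M)
  list(coeffs = M, outlines = outs)
}

#' UPGMA tree on per-taxon mean coefficients
#'
#' Average-linkage agglomeration on the Euclidean distance matrix between
#' taxon mean coefficient vectors. Node heights are half the merge
#' distance, so cophenetic distances on the tree reproduce ultrametric
#' inputs exactly. The tree is returned as an `ape` phylo object (to be
#' drawn unrooted) and can be serialized to Newick.
#'
#' @param mean_coeffs matrix with one row per taxon (rownames = taxa).
#' @param newick_file optional path to write the Newick string.
#' @return An [ape][ape::read.tree] `phylo` object.
#' @export
upgma_tree <- function(mean_coeffs, newick_file = NULL) {
  if (nrow(mean_coeffs) < 2) stop2("UPGMA needs >= 2 taxa")
  if (anyDuplicated(rownames(mean_coeffs)))
    stop2("duplicate taxon names: ", paste(rownames(mean_coeffs)[duplicated(rownames(mean_coeffs))], collapse = ", "))
  hc <- stats::hclust(stats::dist(mean_coeffs), method = "average")
  # as.phylo places each merge at half its height, so tip-to-tip cophenetic
  # distances on the tree equal the hclust merge distances
  tree <- ape::as.phylo(hc)
  if (!is.null(newick_file)) ape::write.tree(tree, file = newick_file)
  tree
}
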