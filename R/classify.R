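#' Linear discriminant analysis with a shared covariance
#'
#' Gaussian LDA: per-class mean vectors, pooled within-class covariance,
#' and prior probabilities. Classification is by largest posterior under
#' the shared-covariance Gaussian model. A near-singular pooled
#' covariance (for example more shape variables than subsampled rows) is
#' ridge-regularized with epsilon `1e-8 * trace/p` on the diagonal, with
#' a warning.
#'
#' @param X numeric matrix of features.
#' @param y class label of each row (>= 2 classes, each with >= 2 rows).
#' @param priors `"equal"` (default; the benchmark design is balanced by
#'   construction), `"proportional"`, or a named numeric vector.
#' @return Object of class `lda_model`: `class_means`, `pooled_cov`,
#'   `priors`, `classes`, `cov_inv`.
#' @export
lda_fit <- function(X, y, priors = "equal") {
  X <- as.matrix(X)
  y <- factor(y)
  cls <- levels(y)
  if (length(cls) < 2) stop2("LDA needs >= 2 classes")
  n_k <- table(y)
  if (any(n_k < 2)) stop2("every class needs >= 2 rows")
  N <- nrow(X); g <- length(cls); p <- ncol(X)
  means <- rowsum(X, y) / as.numeric(n_k)
  W <- crossprod(X - means[as.integer(y), , drop = FALSE])
  Sigma <- W / (N - g)
  pri <- resolve_priors(priors, y)
  Sigma_r <- Sigma
  inv <- tryCatch(chol2inv(chol(Sigma_r)), error = function(e) NULL)
  if (is.null(inv) || rcond(Sigma_r) < 1e-12) {
    eps <- 1e-8 * sum(diag(Sigma)) / p
    if (eps <= 0) eps <- 1e-8
    Sigma_r <- Sigma + diag(eps, p)
    inv <- chol2inv(chol(Sigma_r))
    warning("singular pooled covariance; ridge-regularized with epsilon ",
            format(eps, digits = 3), call. = FALSE)
  }
  structure(list(class_means = means, pooled_cov = Sigma_r, cov_inv = inv,
                 priors = pri, classes = cls),
            class = "lda_model")
}

resolve_priors <- function(priors, y) {
  cls <- levels(y)
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    pri <- if (priors == "equal") rep(1 / length(cls), length(cls))
           else as.numeric(table(y)) / length(y)
    names(pri) <- cls
    pri
  } else {
    if (is.null(names(priors))) names(priors) <- cls
    pri <- priors[cls] / sum(priors)
    pri
  }
}

#' @rdname lda_fit
#' @param model an `lda_model`.
#' @param X_new matrix of rows to classify.
#' @return `lda_predict`: list with `labels` (factor) and `posteriors`
#'   (matrix, rows summing to 1).
#' @export
lda_predict <- function(model, X_new) {
  X_new <- rbind(X_new)
  M <- model$class_means
  A <- model$cov_inv %*% t(M)                        # p x g
  disc <- X_new %*% A                                # linear term
  disc <- sweep(disc, 2, 0.5 * colSums(t(M) * A))    # - mu' S^-1 mu / 2
  disc <- sweep(disc, 2, -log(model$priors))         # + log prior
  post <- exp(disc - apply(disc, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  labels <- factor(model$classes[max.col(disc, ties.method = "first")],
                   levels = model$classes)
  list(labels = labels, posteriors = post)
}

#' Leave-one-out cross-validated accuracy
#'
#' For each row, the model is refit without it and the row predicted;
#' accuracies are aggregated per true class. The default path refits by
#' rank-one downdates (class mean shift plus a Sherman-Morrison update of
#' the pooled covariance inverse); `method = "refit"` is the literal
#' n-model loop, kept as the reference implementation.
#'
#' @inheritParams lda_fit
#' @param method `"downdate"` (fast) or `"refit"` (literal).
#' @return List with `per_class` (named accuracies), `overall`, and
#'   `predicted` (factor of LOO predictions).
#' @export
loocv_accuracy <- function(X, y, priors = "equal", method = c("downdate", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- factor(y)
  N <- nrow(X); g <- nlevels(y); p <- ncol(X)
  if (method == "refit") {
    pred <- character(N)
    for (i in seq_len(N)) {
      fit <- suppressWarnings(lda_fit(X[-i, , drop = FALSE], droplevels(y[-i]), priors))
      pred[i] <- as.character(lda_predict(fit, X[i, , drop = FALSE])$labels)
    }
    pred <- factor(pred, levels = levels(y))
  } else {
    n_k <- as.numeric(table(y))
    means <- rowsum(X, y) / n_k
    W <- crossprod(X - means[as.integer(y), , drop = FALSE])
    ridge <- FALSE
    Winv <- tryCatch(chol2inv(chol(W)), error = function(e) NULL)
    if (is.null(Winv) || rcond(W) < 1e-12) {
      eps <- 1e-8 * sum(diag(W)) / p
      if (eps <= 0) eps <- 1e-8
      W <- W + diag(eps, p)
      Winv <- chol2inv(chol(W))
      ridge <- TRUE
      warning("singular pooled scatter in LOOCV; ridge-regularized", call. = FALSE)
    }
    pred <- character(N)
    for (i in seq_len(N)) {
      k <- as.integer(y[i])
      nk <- n_k[k]
      if (nk < 2) stop2("class '", levels(y)[k], "' has a single row; LOOCV undefined")
      u <- sqrt(nk / (nk - 1)) * (X[i, ] - means[k, ])
      Wu <- Winv %*% u
      denom <- 1 - sum(u * Wu)
      Winv_i <- Winv + (Wu %*% t(Wu)) / denom
      means_i <- means
      means_i[k, ] <- (nk * means[k, ] - X[i, ]) / (nk - 1)
      Sinv <- (N - 1 - g) * Winv_i
      pri <- if (identical(priors, "proportional")) {
        cnt <- n_k; cnt[k] <- cnt[k] - 1
        cnt / (N - 1)
      } else if (identical(priors, "equal")) rep(1 / g, g) else resolve_priors(priors, y)
      A <- Sinv %*% t(means_i)
      d <- X[i, ] %*% A - 0.5 * colSums(t(means_i) * A) + log(pri)
      pred[i] <- levels(y)[which.max(d)]
    }
    pred <- factor(pred, levels = levels(y))
  }
  ok <- pred == y
  per_class <- vapply(levels(y), function(cl) mean(ok[y == cl]), numeric(1))
  list(per_class = per_class, overall = mean(ok), predicted = pred)
}

# Balanced subsample: classes larger than n_per_class are sampled down to
# it without replacement; smaller classes are taken whole.
balance_indices <- function(y, n_per_class) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
    if (length(ii) > n_per_class) sample(ii, n_per_class) else ii
  }), use.names = FALSE)
  sort(idx)
}

#' Class-balanced repeated LDA benchmark
#'
#' Per permutation, every over-represented class is randomly subsampled
#' to `n_per_class` rows, and leave-one-out accuracies are computed per
#' class on each requested feature set. The resulting accuracy
#' distributions are the benchmark (mean and sd per class and feature
#' set).
#'
#' @param features data frame or matrix holding all feature columns.
#' @param y class labels (every class >= 2 rows).
#' @param feature_sets named list of character vectors of column names.
#' @param n_per_class target class size after balancing (default 30).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed (required).
#' @return Object of class `benchmark_report`: `accuracy` (long data
#'   frame: feature_set, class, perm, accuracy), `summary` (mean/sd), and
#'   the call parameters.
#' @export
balanced_benchmark <- function(features, y, feature_sets, n_per_class = 30,
                               n_perm = 1000, seed) {
  if (missing(seed)) stop2("balanced_benchmark requires an explicit seed")
  features <- as.data.frame(features)
  y <- factor(y)
  if (any(table(y) < 2)) stop2("every class needs >= 2 rows")
  check_feature_sets(features, feature_sets)
  rows <- with_seed(seed, {
    out <- vector("list", n_perm)
    for (pm in seq_len(n_perm)) {
      idx <- balance_indices(y, n_per_class)
      ysub <- droplevels(y[idx])
      acc <- lapply(names(feature_sets), function(fs) {
        Xsub <- as.matrix(features[idx, feature_sets[[fs]], drop = FALSE])
        a <- loocv_accuracy(Xsub, ysub)$per_class
        data.frame(feature_set = fs, class = names(a), perm = pm,
                   accuracy = unname(a))
      })
      out[[pm]] <- do.call(rbind, acc)
    }
    do.call(rbind, out)
  })
  summ <- stats::aggregate(accuracy ~ feature_set + class, rows,
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(summ[1:2], mean = summ$accuracy[, "mean"],
                     sd = summ$accuracy[, "sd"])
  structure(list(accuracy = rows, summary = summ,
                 n_per_class = n_per_class, n_perm = n_perm,
                 feature_sets = feature_sets),
            class = "benchmark_report")
}

check_feature_sets <- function(features, feature_sets) {
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets))))
    stop2("feature_sets must be a named list")
  for (fs in names(feature_sets)) {
    missing_cols <- setdiff(feature_sets[[fs]], colnames(features))
    if (length(missing_cols))
      stop2("feature set '", fs, "' refers to missing columns: ",
            paste(missing_cols, collapse = ", "))
  }
}

#' Shuffled-label chance baseline
#'
#' Within each permutation the balanced subsample's labels are shuffled
#' before LOOCV, and the maximum per-class accuracy of that permutation
#' is recorded. The distribution (and its maximum) is the chance ceiling
#' against which real accuracies are compared.
#'
#' @inheritParams balanced_benchmark
#' @param feature_set character vector of column names.
#' @return List with `max_accuracy` (per permutation), `overall_max`, and
#'   `per_class` (long data frame).
#' @export
shuffled_label_baseline <- function(features, y, feature_set, n_per_class = 30,
                                    n_perm = 100, seed) {
  if (missing(seed)) stop2("shuffled_label_baseline requires an explicit seed")
  features <- as.data.frame(features)
  y <- factor(y)
  check_feature_sets(features, list(baseline = feature_set))
  res <- with_seed(seed, {
    maxes <- numeric(n_perm)
    rows <- vector("list", n_perm)
    for (pm in seq_len(n_perm)) {
      idx <- balance_indices(y, n_per_class)
      ysub <- droplevels(y[idx])
      yshuf <- sample(ysub)
      Xsub <- as.matrix(features[idx, feature_set, drop = FALSE])
      a <- loocv_accuracy(Xsub, yshuf)$per_class
      maxes[pm] <- max(a)
      rows[[pm]] <- data.frame(class = names(a), perm = pm, accuracy = unname(a))
    }
    list(maxes = maxes, rows = do.call(rbind, rows))
  })
  list(max_accuracy = res$maxes, overall_max = max(res$maxes),
       per_class = res$rows, n_perm = n_perm)
}

#' Majority-vote assignment of unknown seeds
#'
#' Per permutation, an LDA is trained on a balanced subsample of the
#' known (modern) material and every unknown seed is predicted; the
#' dominant class across permutations is the assignment. Ties are
#' flagged ambiguous and resolved to the lexicographically first class.
#'
#' @param features_known,y_known training features and labels.
#' @param features_unknown features of the unknowns (same columns).
#' @param feature_set character vector of feature columns to use.
#' @inheritParams balanced_benchmark
#' @param n_perm permutations (default 100).
#' @return Object of class `assignment_result`: `assignments` (data
#'   frame: seed_id, predicted, vote_share, ambiguous, votes_<class>),
#'   `composition` (predicted-class counts), `votes` (matrix).
#' @export
assign_unknowns <- function(features_known, y_known, features_unknown,
                            feature_set, n_per_class = 30, n_perm = 100, seed) {
  if (missing(seed)) stop2("assign_unknowns requires an explicit seed")
  features_known <- as.data.frame(features_known)
  features_unknown <- as.data.frame(features_unknown)
  check_feature_sets(features_known, list(fs = feature_set))
  if (!all(feature_set %in% colnames(features_unknown)))
    stop2("unknown rows lack feature columns: ",
          paste(setdiff(feature_set, colnames(features_unknown)), collapse = ", "))
  y_known <- factor(y_known)
  cls <- levels(y_known)
  n_u <- nrow(features_unknown)
  Xu <- as.matrix(features_unknown[, feature_set, drop = FALSE])
  votes <- matrix(0L, n_u, length(cls), dimnames = list(NULL, cls))
  with_seed(seed, {
    for (pm in seq_len(n_perm)) {
      idx <- balance_indices(y_known, n_per_class)
      fit <- lda_fit(as.matrix(features_known[idx, feature_set, drop = FALSE]),
                     droplevels(y_known[idx]))
      pred <- lda_predict(fit, Xu)$labels
      for (cl in cls) votes[, cl] <- votes[, cl] + (pred == cl)
    }
  })
  top <- apply(votes, 1, max)
  predicted <- apply(votes, 1, function(v) colnames(votes)[which.max(v)])
  ambiguous <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  ids <- rownames(features_unknown) %||% as.character(seq_len(n_u))
  assignments <- data.frame(seed_id = ids, predicted = predicted,
                            vote_share = top / n_perm, ambiguous = ambiguous)
  vote_df <- as.data.frame(votes)
  names(vote_df) <- paste0("votes_", cls)
  assignments <- cbind(assignments, vote_df)
  composition <- table(factor(predicted, levels = cls))
  structure(list(assignments = assignments, composition = composition,
                 votes = votes, n_perm = n_perm, feature_set = feature_set),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result>", nrow(x$assignments), "unknowns over", x$n_perm,
      "permutations\n")
  print(x$composition)
  invisible(x)
}
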