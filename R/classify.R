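#' Contrast specification
#'
#' Names a binary classification contrast between two disjoint sets of
#' tissue-class labels.
#'
#' @param name contrast label.
#' @param positive_classes labels forming the positive class.
#' @param negative_classes disjoint labels forming the negative class.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(name, positive_classes, negative_classes) {
  if (length(positive_classes) == 0 || length(negative_classes) == 0)
    stop("both class sets must be non-empty")
  if (length(intersect(positive_classes, negative_classes)) > 0)
    stop("positive and negative class sets must be disjoint")
  structure(list(name = name, positive_classes = positive_classes,
                 negative_classes = negative_classes),
            class = "contrast_spec")
}

contrast_response <- function(labels, contrast) {
  keep <- labels %in% c(contrast$positive_classes, contrast$negative_classes)
  list(keep = which(keep),
       y = as.integer(labels[keep] %in% contrast$positive_classes))
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney statistic U / (n1 * n0) with ties counted 1/2
#' (identical to trapezoidal integration of the empirical ROC curve); the
#' 95% CI uses the DeLong placement-variance estimator, truncated to [0, 1].
#'
#' @param scores numeric scores (higher = more positive).
#' @param binary_labels 0/1 (or logical) labels, both classes present.
#' @param conf_level confidence level (default 0.95).
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `se`, `fpr`,
#'   `tpr`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, binary_labels, conf_level = 0.95) {
  y <- as.integer(binary_labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  # placements: V10[i] = P(pos_i > neg) with ties 1/2, V01[j] likewise
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  V10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  V01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / m,
                numeric(1))
  se <- sqrt(stats::var(V10) / m + stats::var(V01) / n)
  if (is.na(se)) se <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # threshold-swept empirical ROC
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
  structure(list(auc = auc,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 se = se, fpr = fpr, tpr = tpr,
                 n_pos = m, n_neg = n), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f, 95%% CI), n_pos %d, n_neg %d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Binary logistic regression on concentration profiles
#'
#' Unregularized maximum-likelihood fit (IRLS via `glm`) of the contrast
#' response on the component concentrations; per-predictor Wald z-test
#' p-values and in-sample predicted probabilities are returned. Complete
#' separation is flagged (the finite-iteration estimate is still returned).
#'
#' @param concentrations samples x components matrix (resolved C).
#' @param labels per-sample class labels.
#' @param contrast a [contrast_spec].
#' @param standardize z-score the predictors before fitting (default FALSE,
#'   matching the usual unstandardized convention).
#' @return A `logistic_report` list: `coefficients`, `wald_p_values`,
#'   `predicted_probabilities`, `response`, `sample_index`, `separation`.
#' @export
fit_logistic <- function(concentrations, labels, contrast,
                         standardize = FALSE) {
  X <- as.matrix(concentrations)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("component_", seq_len(ncol(X)))
  cr <- contrast_response(labels, contrast)
  if (length(unique(cr$y)) < 2 || min(table(cr$y)) < 2)
    stop("need at least 2 samples in each class")
  Xs <- X[cr$keep, , drop = FALSE]
  if (standardize) Xs <- scale(Xs)
  df <- data.frame(.y = cr$y, Xs, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm can also separate quietly: perfect classification at extreme odds
  if (!sep && max(abs(stats::fitted(fit) - cr$y)) < 1e-6) sep <- TRUE
  if (sep)
    warning("possible complete separation: coefficient estimates unstable")
  sm <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit),
                 wald_p_values = sm[, "Pr(>|z|)"],
                 predicted_probabilities = as.numeric(stats::fitted(fit)),
                 response = cr$y, sample_index = cr$keep,
                 separation = sep), class = "logistic_report")
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

pls1_fit <- function(X, y, n_latent) {
  # NIPALS PLS1 on centered data; returns the regression vector and centers
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  q <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]; break }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pvec)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  if (ncol(W) == 0) {
    beta <- rep(0, p)
  } else {
    beta <- W %*% solve(t(P) %*% W, q)
  }
  list(beta = as.numeric(beta), xm = xm, ym = ym)
}

pls1_predict <- function(fit, X) {
  as.numeric(sweep(as.matrix(X), 2, fit$xm) %*% fit$beta + fit$ym)
}

#' PLS-DA with stratified cross-validation
#'
#' PLS1 regression (NIPALS) on a 0/1 contrast response; out-of-fold
#' predicted values are assembled over a seeded stratified k-fold partition
#' and scored by ROC. When `n_latent = NULL` the latent-variable count is
#' chosen by an inner CV sweep over `1..max_latent` maximizing out-of-fold
#' AUC on the training part of each run (logged in the result).
#'
#' @param features samples x variables matrix.
#' @param labels per-sample class labels.
#' @param contrast a [contrast_spec].
#' @param n_latent number of latent variables, or NULL for inner-CV choice.
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param max_latent upper bound for the inner-CV sweep.
#' @return A `plsda_result` list: `predicted`, `response`, `sample_index`,
#'   `fold`, `roc` ([roc_auc] on out-of-fold predictions), `n_latent`.
#' @export
pls_da <- function(features, labels, contrast, n_latent = NULL, folds = 10,
                   seed = 1, max_latent = 10) {
  X <- as.matrix(features)
  cr <- contrast_response(labels, contrast)
  Xs <- X[cr$keep, , drop = FALSE]; y <- cr$y
  if (folds < 2) stop("folds must be >= 2")
  if (min(table(y)) < folds)
    folds <- max(2, min(table(y)))
  max_latent <- min(max_latent, ncol(Xs), nrow(Xs) - 2)
  if (is.null(n_latent)) {
    # inner CV on the full set (one sweep; folds reseeded per candidate)
    sweep_auc <- vapply(seq_len(max_latent), function(a) {
      pred <- cv_pls_predict(Xs, y, a, folds, seed + 1000L)
      roc_auc(pred, y)$auc
    }, numeric(1))
    n_latent <- which.max(sweep_auc)
  }
  n_latent <- min(n_latent, max_latent)
  fold <- stratified_folds(y, folds, seed)
  pred <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- pls1_fit(Xs[tr, , drop = FALSE], y[tr], n_latent)
    pred[!tr] <- pls1_predict(fit, Xs[!tr, , drop = FALSE])
  }
  structure(list(predicted = pred, response = y, sample_index = cr$keep,
                 fold = fold, roc = roc_auc(pred, y),
                 n_latent = as.integer(n_latent)), class = "plsda_result")
}

cv_pls_predict <- function(X, y, n_latent, folds, seed) {
  fold <- stratified_folds(y, folds, seed)
  pred <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], n_latent)
    pred[!tr] <- pls1_predict(fit, X[!tr, , drop = FALSE])
  }
  pred
}

#' Box-plot summary per group
#'
#' Quartiles by linear interpolation (type 7), whiskers at the most extreme
#' points within 1.5 IQR of the box, points beyond listed as outliers.
#'
#' @param values numeric vector.
#' @param group_labels grouping vector of the same length.
#' @return A `boxplot_summary` data frame (one row per group) plus an
#'   `outliers` attribute (named list of outlying values).
#' @export
boxplot_summary <- function(values, group_labels) {
  groups <- unique(as.character(group_labels))
  rows <- list(); outliers <- list()
  for (g in groups) {
    v <- values[group_labels == g]
    if (length(v) == 0) stop("group ", g, " is empty")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    rows[[g]] <- data.frame(group = g, n = length(v),
                            q1 = q[1], median = q[2], q3 = q[3],
                            whisker_low = min(inside),
                            whisker_high = max(inside))
    outliers[[g]] <- v[v < lo_fence | v > hi_fence]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outliers") <- outliers
  class(out) <- c("boxplot_summary", class(out))
  out
}

#' Default contrast battery
#'
#' The standard set evaluated on a five-class skin cohort: per-component
#' contrasts {BCC vs rest, BCC vs MM, malignant vs benign, MM vs PN} and
#' model-based contrasts {malignant vs benign, MM vs K+PN}.
#' @return list with `per_component` and `model_based` contrast lists.
#' @export
default_contrasts <- function() {
  list(
    per_component = list(
      contrast_spec("BCC_vs_rest", "BCC", c("NS", "K", "MM", "PN")),
      contrast_spec("BCC_vs_MM", "BCC", "MM"),
      contrast_spec("malignant_vs_benign", c("MM", "BCC"), c("K", "PN")),
      contrast_spec("MM_vs_PN", "MM", "PN")
    ),
    model_based = list(
      contrast_spec("malignant_vs_benign", c("MM", "BCC"), c("K", "PN")),
      contrast_spec("MM_vs_K_PN", "MM", c("K", "PN"))
    )
  )
}

#' Run the classification battery on resolved concentrations
#'
#' For each per-component contrast: one ROC per component plus box-plot
#' summaries. For each model-based contrast: logistic regression (with Wald
#' p-values) and PLS-DA with stratified 10-fold CV, each scored by ROC on
#' the predicted values.
#'
#' @param model a `component_model` from [fit_mcr] / [fit_with_basis] (or a
#'   plain concentration matrix).
#' @param labels per-sample class labels aligned with the C rows.
#' @param contrasts contrast battery as from [default_contrasts].
#' @param seed seed for the CV fold assignment.
#' @return A `classification_report` list: `per_component` (nested
#'   contrast -> component -> [roc_auc] result), `boxplots`, `logistic`,
#'   `plsda`.
#' @export
run_contrasts <- function(model, labels, contrasts = default_contrasts(),
                          seed = 1) {
  C <- if (inherits(model, "component_model")) model$concentrations else
    as.matrix(model)
  if (nrow(C) != length(labels))
    stop("labels length does not match the number of samples")
  known <- c("NS", "K", "BCC", "MM", "PN")
  used <- unique(unlist(lapply(unlist(contrasts, recursive = FALSE),
                               function(ct) c(ct$positive_classes,
                                              ct$negative_classes))))
  bad <- setdiff(used, unique(c(known, labels)))
  if (length(bad) > 0)
    stop("unknown class label(s) in contrasts: ", paste(bad, collapse = ", "))
  if (is.null(colnames(C)))
    colnames(C) <- paste0("component_", seq_len(ncol(C)))
  per_comp <- list()
  for (ct in contrasts$per_component) {
    cr <- contrast_response(labels, ct)
    rocs <- lapply(seq_len(ncol(C)), function(a)
      roc_auc(C[cr$keep, a], cr$y))
    names(rocs) <- colnames(C)
    per_comp[[ct$name]] <- rocs
  }
  boxplots <- lapply(seq_len(ncol(C)), function(a)
    boxplot_summary(C[, a], labels))
  names(boxplots) <- colnames(C)
  logistic <- list(); plsda <- list()
  for (ct in contrasts$model_based) {
    lr <- fit_logistic(C, labels, ct)
    logistic[[ct$name]] <- list(
      report = lr,
      roc = roc_auc(lr$predicted_probabilities, lr$response))
    pl <- pls_da(C, labels, ct, seed = seed)
    plsda[[ct$name]] <- pl
  }
  structure(list(per_component = per_comp, boxplots = boxplots,
                 logistic = logistic, plsda = plsda),
            class = "classification_report")
}
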