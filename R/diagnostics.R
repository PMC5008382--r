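#' Maximum-likelihood logistic regression by damped IRLS
#'
#' Newton/IRLS fit of a binomial GLM with logit link and a fixed tiny ridge
#' penalty (`1e-8` by default) so that perfectly separated data converge to
#' large but finite coefficients instead of diverging; a warning is issued
#' when apparent separation is detected.
#'
#' @param x Covariate matrix (samples x covariates), without intercept.
#' @param y 0/1 labels.
#' @param ridge Ridge penalty on all coefficients (default `1e-8`).
#' @param tol Convergence tolerance on the coefficient change
#'   (default `1e-8`).
#' @param maxit Maximum Newton iterations (default 100).
#' @param intercept Prepend an intercept column (default `TRUE`).
#' @return Numeric coefficient vector (intercept first when requested),
#'   with attribute `converged`.
#' @examples
#' fitLogistic(matrix(numeric(0), 4, 0), c(1, 1, 1, 0))  # intercept = ln 3
#' @export
fitLogistic <- function(x, y, ridge = 1e-8, tol = 1e-8, maxit = 100L,
                        intercept = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (ncol(x)) {
    const <- apply(x, 2L, function(v) diff(range(v)) == 0)
    if (any(const))
      stop("constant non-intercept covariate(s): ",
           paste(colnames(x)[const], collapse = ", "))
  }
  X <- if (intercept) cbind(`(Intercept)` = 1, x) else x
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(ridge, p)
    g <- drop(crossprod(X, y - mu)) - ridge * beta
    delta <- solve(H, g)
    # damp steps so separation drives coefficients out gradually
    if (max(abs(delta)) > 10) delta <- delta * (10 / max(abs(delta)))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(X %*% beta))
  if (max(abs(y - mu)) < 1e-4)
    warning("fitted probabilities are all 0 or 1: ",
            "data appear perfectly separated; ridge bounds the coefficients")
  names(beta) <- colnames(X)
  attr(beta, "converged") <- converged
  beta
}

.predictLogistic <- function(beta, x, intercept = TRUE) {
  X <- if (intercept) cbind(1, as.matrix(x)) else as.matrix(x)
  stats::plogis(drop(X %*% beta))
}

#' Leave-one-out cross-validated disease probabilities
#'
#' For each sample, the logistic model is fit to all *other* samples and
#' the predicted probability of disease is computed for the sample left
#' out, yielding exactly one out-of-fold probability per sample.  The
#' result is deterministic and invariant to sample order.
#'
#' @param x Covariate matrix (samples x covariates).
#' @param y 0/1 labels; every leave-one-out fold must retain both classes.
#' @param ... Passed to [fitLogistic()].
#' @return Numeric vector of out-of-fold probabilities, named like
#'   `rownames(x)`.
#' @export
loocvProbabilities <- function(x, y, ...) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n >= 3L, length(y) == n)
  if (any(tabulate(factor(y, levels = c(0, 1))) < 2))
    stop("a leave-one-out fold would lose a label class")
  probs <- vapply(seq_len(n), function(i) {
    beta <- fitLogistic(x[-i, , drop = FALSE], y[-i], ...)
    .predictLogistic(beta, x[i, , drop = FALSE])
  }, numeric(1))
  names(probs) <- rownames(x)
  probs
}

#' ROC curve over a fixed probability-threshold grid
#'
#' Thresholds run from 0.01 to 0.99 in steps of 0.01; at each threshold a
#' sample is classified as diseased when its probability is `>=` the
#' threshold, and sensitivity (`TP/(TP+FN)`) and specificity
#' (`TN/(TN+FP)`) are computed.  The AUC is the trapezoidal integral of
#' sensitivity over `1 - specificity` with `(0,0)` and `(1,1)` appended.
#'
#' @param probabilities Predicted disease probabilities.
#' @param labels 0/1 labels (both classes required).
#' @param thresholds Threshold grid (default `seq(0.01, 0.99, 0.01)`).
#' @return List of class `RocCurve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
rocCurve <- function(probabilities, labels,
                     thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to construct a ROC curve")
  sens <- vapply(thresholds, function(t) mean(p[y == 1] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(p[y == 0] < t), numeric(1))
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc),
            class = "RocCurve")
}

#' @export
print.RocCurve <- function(x, ...) {
  cat("RocCurve:", length(x$thresholds), "thresholds, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Operating point maximizing Youden's J
#'
#' Picks the grid threshold maximizing sensitivity + specificity (Youden's
#' J), breaking ties toward higher specificity (and then the higher
#' cutoff), and reports the confusion-table statistics at that cutoff.
#' PPV/NPV are `NaN` when no sample is predicted in the corresponding
#' class.
#'
#' @param roc A [rocCurve()] result.
#' @param probabilities,labels The vectors the ROC was built from.
#' @return List `(cutoff, sensitivity, specificity, ppv, npv)`.
#' @export
operatingPoint <- function(roc, probabilities, labels) {
  j <- roc$sensitivity + roc$specificity
  best <- which(j == max(j))
  best <- best[roc$specificity[best] == max(roc$specificity[best])]
  best <- best[which.max(roc$thresholds[best])]
  cutoff <- roc$thresholds[best]
  y <- as.numeric(labels)
  pred <- as.numeric(probabilities) >= cutoff
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  list(cutoff = cutoff,
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn))
}

#' The five diagnostic panel models
#'
#' Model specifications for the comparison of serum PSA against the
#' three-marker miRNA panels: PSA alone; the 3 mature miRNAs; the 3 mature
#' miRNAs plus PSA; the 3 isomiRs; the 3 isomiRs plus PSA.
#'
#' @param mature_assays,isomir_assays Assay ids of the mature and isomiR
#'   markers (defaults: [panelAssays()]).
#' @return Named list of model specs `(name, covariates)`; `"PSA"` denotes
#'   the clinical covariate.
#' @export
panelModels <- function(mature_assays = panelAssays("mature")$assay_id,
                        isomir_assays = panelAssays("isomir")$assay_id) {
  stopifnot(length(mature_assays) == 3L, length(isomir_assays) == 3L)
  list(
    PSA = list(name = "PSA", covariates = "PSA"),
    mature3 = list(name = "mature3", covariates = mature_assays),
    `mature3+PSA` = list(name = "mature3+PSA",
                         covariates = c(mature_assays, "PSA")),
    isomir3 = list(name = "isomir3", covariates = isomir_assays),
    `isomir3+PSA` = list(name = "isomir3+PSA",
                         covariates = c(isomir_assays, "PSA")))
}

#' Evaluate the five panel models by LOOCV, ROC and operating point
#'
#' Runs each of the five models ([panelModels()]) through leave-one-out
#' cross-validation, builds the threshold-grid ROC curve, and reports AUC
#' plus the Youden-optimal operating point (cutoff, sensitivity,
#' specificity, PPV, NPV) per model.
#'
#' PSA enters as `ln(PSA)` by default: serum PSA spans several orders of
#' magnitude (ng/ml) and would otherwise dominate the fit by leverage;
#' `log_psa = FALSE` switches to raw PSA.
#'
#' @param expr Samples x assays matrix of normalized ln-expression values
#'   (see [toExpressionMatrix()]), or the long `data.frame` from
#'   [normalizeDeltaCt()].
#' @param clinical `data.frame` with `sample_id`, `label` (0 = control,
#'   1 = cancer) and `psa` (ng/ml) for PSA-containing models.
#' @param models Model list as from [panelModels()].
#' @param log_psa Use `ln(PSA)` as the covariate (default `TRUE`).
#' @return List of class `PanelReport`: per model `auc`, `roc`,
#'   `operating_point` and `probabilities`, plus a `summary` data.frame.
#' @export
evaluatePanels <- function(expr, clinical, models = panelModels(),
                           log_psa = TRUE) {
  if (is.data.frame(expr) && all(c("sample_id", "assay_id") %in%
                                 colnames(expr)))
    expr <- toExpressionMatrix(expr)
  expr <- as.matrix(expr)
  clinical <- as.data.frame(clinical)
  idx <- match(rownames(expr), clinical$sample_id)
  if (anyNA(idx))
    stop("samples missing from the clinical table: ",
         paste(rownames(expr)[is.na(idx)], collapse = ", "))
  y <- as.numeric(clinical$label[idx])
  if (length(unique(y)) < 2L)
    stop("both control and cancer labels must be present")
  psa <- clinical$psa[idx]
  out <- lapply(models, function(m) {
    cov_assays <- setdiff(m$covariates, "PSA")
    missing <- setdiff(cov_assays, colnames(expr))
    if (length(missing))
      stop("model '", m$name, "' needs missing assay(s): ",
           paste(missing, collapse = ", "))
    x <- expr[, cov_assays, drop = FALSE]
    if ("PSA" %in% m$covariates) {
      if (anyNA(psa) || is.null(psa))
        stop("model '", m$name, "' needs PSA for every sample")
      x <- cbind(x, PSA = if (log_psa) log(psa) else psa)
    }
    if (anyNA(x))
      stop("model '", m$name, "' has missing covariate values")
    probs <- loocvProbabilities(x, y)
    roc <- rocCurve(probs, y)
    list(name = m$name, auc = roc$auc, roc = roc,
         operating_point = operatingPoint(roc, probs, y),
         probabilities = probs)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  summary <- data.frame(
    model = names(out),
    auc = vapply(out, `[[`, numeric(1), "auc"),
    cutoff = vapply(out, function(z) z$operating_point$cutoff, numeric(1)),
    sensitivity = vapply(out, function(z) z$operating_point$sensitivity,
                         numeric(1)),
    specificity = vapply(out, function(z) z$operating_point$specificity,
                         numeric(1)),
    ppv = vapply(out, function(z) z$operating_point$ppv, numeric(1)),
    npv = vapply(out, function(z) z$operating_point$npv, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(models = out, summary = summary), class = "PanelReport")
}

#' @export
print.PanelReport <- function(x, digits = 3, ...) {
  cat("PanelReport:", length(x$models), "models\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
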