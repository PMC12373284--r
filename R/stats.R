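# Point-wise group models with FDR, median imputation, the exponential
# learning-curve model, and 1-D profile augmentation.

#' Point-wise group model along a tract profile
#'
#' At every node, the metric is regressed (ordinary least squares) on a
#' group indicator plus covariates; the reported p-value is the two-sided
#' t-test on the group coefficient. All nodes share one design matrix, so
#' the fit is a single QR decomposition applied to the node-wise response
#' matrix.
#'
#' @param table tidy profile table for ONE (tract, metric) pair
#'   (columns `subject_id, tract_name, node_id, metric, value`).
#' @param covariates data.frame with `subject_id`, `group` (two levels) and
#'   optional further covariate columns (e.g. `age`, `sex`).
#' @param covariate_terms names of covariate columns to adjust for
#'   (default: all columns besides subject_id/group).
#' @return an object of class `pointwise_result`: data.frame with one row
#'   per node (`node_id, estimate, se, t, p`) plus attributes `tract_name`
#'   and `metric`.
#' @export
pointwise_group_model <- function(table, covariates,
                                  covariate_terms = NULL) {
  check_tidy(table)
  if (length(unique(table$tract_name)) != 1L ||
      length(unique(table$metric)) != 1L)
    stop("supply the rows of exactly one (tract, metric) pair")
  if (!all(c("subject_id", "group") %in% names(covariates)))
    stop("covariates need columns subject_id and group")
  if (anyNA(covariates))
    stop("covariates contain missing values; impute first")
  if (is.null(covariate_terms))
    covariate_terms <- setdiff(names(covariates), c("subject_id", "group"))
  nodes <- sort(unique(table$node_id))
  subjects <- sort(unique(table$subject_id))
  # response matrix: subjects x nodes
  Y <- matrix(NA_real_, length(subjects), length(nodes),
              dimnames = list(subjects, nodes))
  Y[cbind(match(table$subject_id, subjects),
          match(table$node_id, nodes))] <- table$value
  miss <- colSums(is.na(Y)) > 0
  if (any(miss))
    stop("missing observations at node(s): ",
         paste(nodes[miss], collapse = ", "))
  cv <- covariates[match(subjects, covariates$subject_id), , drop = FALSE]
  if (anyNA(cv$group))
    stop("covariates missing for subject(s): ",
         paste(subjects[is.na(cv$group)], collapse = ", "))
  grp <- factor(cv$group)
  if (nlevels(grp) != 2L) stop("group must have exactly two levels")
  if (min(table(grp)) < 2L) stop("each group needs at least 2 observations")
  form <- stats::as.formula(paste(
    "~ group", if (length(covariate_terms))
      paste("+", paste(covariate_terms, collapse = " + ")) else ""))
  mf <- cv
  mf$group <- grp
  X <- stats::model.matrix(form, data = mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  coefs <- qr.coef(qrx, Y)
  resid <- qr.resid(qrx, Y)
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfres
  xtxinv <- chol2inv(qr.R(qrx))
  gcol <- grep("^group", colnames(X))[1]
  est <- coefs[gcol, ]
  se <- sqrt(sigma2 * xtxinv[gcol, gcol])
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), dfres)
  const <- apply(Y, 2, function(y) stats::var(y) == 0)
  if (any(const)) {
    warning(sprintf("constant response at %d node(s); p set to 1", sum(const)),
            call. = FALSE)
    est[const] <- 0; se[const] <- NA_real_; tval[const] <- 0; p[const] <- 1
  }
  res <- data.frame(node_id = nodes, estimate = est, se = se, t = tval,
                    p = p, row.names = NULL)
  attr(res, "tract_name") <- table$tract_name[1]
  attr(res, "metric") <- table$metric[1]
  class(res) <- c("pointwise_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure at level `alpha`: with sorted p-values
#' \eqn{p_{(1)} \le \ldots \le p_{(m)}}, the largest k with
#' \eqn{p_{(k)} \le k\alpha/m} determines the rejected set. Adjusted
#' p-values are the usual monotone step-up adjustments.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `rejected` (logical, same order as input) and
#'   `p_adjusted`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (!length(pvals))
    return(list(rejected = logical(0), p_adjusted = numeric(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  # step-up: largest k with p_(k) <= k*alpha/m rejects hypotheses 1..k
  below <- which(ps <= seq_len(m) * alpha / m)
  k <- if (length(below)) max(below) else 0L
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  p_adjusted <- numeric(m)
  p_adjusted[ord] <- pmin(adj, 1)
  list(rejected = rejected, p_adjusted = p_adjusted)
}

#' Per-feature median imputation within train and test sets separately
#'
#' Each missing value is replaced by the median of ITS OWN set's non-missing
#' values for that feature; train medians never leak into the test set.
#'
#' @param train,test data.frames of numeric features (non-numeric columns,
#'   e.g. subject_id, are passed through untouched).
#' @return list with imputed `train` and `test`.
#' @export
median_impute <- function(train, test) {
  impute_one <- function(df, setname) {
    for (col in names(df)) {
      if (!is.numeric(df[[col]])) next
      nas <- is.na(df[[col]])
      if (!any(nas)) next
      if (all(nas))
        stop(sprintf("feature '%s' entirely missing in the %s set",
                     col, setname))
      df[[col]][nas] <- stats::median(df[[col]][!nas])
    }
    df
  }
  list(train = impute_one(train, "train"), test = impute_one(test, "test"))
}

#' Exponential learning-curve value
#'
#' \eqn{R^2(x) = \alpha - (\alpha - \beta) e^{-(x - x_{min})/\kappa}}:
#' performance rises from \eqn{\beta} at the smallest training size
#' \eqn{x_{min}} toward the asymptote \eqn{\alpha}; at
#' \eqn{x = x_{min} + \kappa} the curve has closed \eqn{1 - e^{-1}}
#' (about 63\%) of the \eqn{\alpha - \beta} gap.
#'
#' @param x training-set sizes.
#' @param alpha asymptotic performance.
#' @param beta performance at `x_min`.
#' @param kappa rate parameter (subjects).
#' @param x_min smallest training size.
#' @return predicted scores.
#' @export
learning_curve <- function(x, alpha, beta, kappa, x_min) {
  alpha - (alpha - beta) * exp(-(x - x_min) / kappa)
}

#' Fit the exponential learning-curve model
#'
#' `alpha` is fixed to the highest observed score; `beta` and `kappa` are
#' fitted by multi-start Levenberg-Marquardt nonlinear least squares
#' (starts: beta at `min(scores)`, kappa at `x_min`, `2 x_min` and
#' `max(sizes)`; kappa bounded below by a small positive value).
#'
#' Note that pinning `alpha` to the best observed score biases the fit
#' when the observed sizes stop short of the plateau: the remaining
#' unclosed gap at the largest size is folded into `beta` and `kappa`.
#' Supply a known or externally estimated asymptote via `alpha` to remove
#' that bias.
#'
#' @param sizes training-set sizes (>= 3 distinct values).
#' @param scores observed performance scores (same length).
#' @param alpha asymptotic score; default the highest observed score.
#' @return an object of class `learning_curve_fit`: list with `alpha`,
#'   `beta`, `kappa`, `x_min`, `rss`, `fitted`.
#' @export
fit_learning_curve <- function(sizes, scores, alpha = max(scores)) {
  stopifnot(length(sizes) == length(scores))
  if (length(unique(sizes)) < 3L)
    stop("need at least 3 distinct training sizes")
  x_min <- min(sizes)
  dat <- data.frame(x = sizes, y = scores)
  starts <- expand.grid(beta = min(scores),
                        kappa = c(x_min, 2 * x_min, max(sizes)))
  best <- NULL
  diagnostics <- character(0)
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ alpha - (alpha - beta) * exp(-(x - x_min) / kappa),
        data = dat,
        start = list(beta = starts$beta[r], kappa = starts$kappa[r]),
        lower = c(beta = -Inf, kappa = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("learning-curve fit failed from every start: ",
         paste(unique(diagnostics), collapse = "; "))
  cf <- stats::coef(best$fit)
  structure(list(alpha = alpha, beta = unname(cf["beta"]),
                 kappa = unname(cf["kappa"]), x_min = x_min,
                 rss = best$rss,
                 fitted = unname(stats::fitted(best$fit))),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "learning curve: alpha = %.4f (fixed), beta = %.4f, kappa = %.1f, x_min = %g, RSS = %.3g\n",
    x$alpha, x$beta, x$kappa, x$x_min, x$rss))
  invisible(x)
}

#' Predict from a learning-curve fit
#'
#' @param object a `learning_curve_fit`.
#' @param newdata numeric vector of training sizes (default: none; returns
#'   fitted values).
#' @param ... unused.
#' @return predicted scores.
#' @export
predict.learning_curve_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  learning_curve(newdata, object$alpha, object$beta, object$kappa,
                 object$x_min)
}

#' Augment a profile tensor
#'
#' Operates on a samples x nodes x channels array (one channel per
#' tract-metric pair). All three operators are parametrized by a single
#' magnitude `m` scaled to each channel's value range:
#' \describe{
#'   \item{jitter}{add i.i.d. Gaussian noise with SD `m * range(channel)`.}
#'   \item{scaling}{per sample and channel, multiply deviations from the
#'     channel mean by a factor drawn from Normal(1, m), truncated at 0.}
#'   \item{timewarp}{per sample, displace 4 interior knots of the node axis
#'     by Normal(0, m), re-interpolate along the warped (monotone,
#'     endpoint-fixed) axis; one warp per sample, shared across channels.}
#' }
#' `m = 0` is the identity for all three.
#'
#' @param tensor 3-D numeric array (samples x nodes x channels).
#' @param op `"jitter"`, `"scaling"` or `"timewarp"`.
#' @param m non-negative magnitude.
#' @param seed integer seed (mandatory; no global RNG state is consumed).
#' @return augmented array, same shape.
#' @export
augment <- function(tensor, op = c("jitter", "scaling", "timewarp"), m,
                    seed) {
  op <- match.arg(op)
  if (!is.numeric(m) || length(m) != 1L || m < 0)
    stop("magnitude m must be a single non-negative number")
  stopifnot(length(dim(tensor)) == 3L)
  if (m == 0) return(tensor)
  dims <- dim(tensor)
  out <- with_seed(seed, {
    res <- tensor
    if (op == "jitter") {
      for (ch in seq_len(dims[3])) {
        rng <- diff(range(tensor[, , ch]))
        res[, , ch] <- tensor[, , ch] +
          stats::rnorm(dims[1] * dims[2], sd = m * rng)
      }
    } else if (op == "scaling") {
      for (ch in seq_len(dims[3])) {
        mu <- mean(tensor[, , ch])
        fac <- stats::rnorm(dims[1], mean = 1, sd = m)
        while (any(fac <= 0))
          fac[fac <= 0] <- stats::rnorm(sum(fac <= 0), mean = 1, sd = m)
        res[, , ch] <- mu + (tensor[, , ch] - mu) * fac
      }
    } else {
      n <- dims[2]
      t_nodes <- seq(0, 1, length.out = n)
      knots <- seq(0, 1, length.out = 6L)  # 4 interior knots
      for (s in seq_len(dims[1])) {
        disp <- stats::rnorm(4L, sd = m)
        v <- knots
        v[2:5] <- sort(pmin(pmax(knots[2:5] + disp, 1e-6), 1 - 1e-6))
        warped <- stats::approx(knots, v, xout = t_nodes,
                                ties = "ordered")$y
        for (ch in seq_len(dims[3])) {
          res[s, , ch] <- stats::approx(t_nodes, tensor[s, , ch],
                                        xout = warped, rule = 2,
                                        ties = "ordered")$y
        }
      }
    }
    res
  })
  out
}
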