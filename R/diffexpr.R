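# Negative-binomial GLM time-course testing.
#
# The model for feature i in sample j is
#   log(mu_ij) = beta_i0 + beta_iRIN * x_jRIN + beta_iTP * x_jTP + log(s_j)
# with NB variance mu + alpha_i * mu^2 and size factor s_j as an offset.
# Temporal differential expression is assessed by a likelihood-ratio test of
# this full model against a reduced model that keeps only the RIN covariate,
# so the time effect is isolated from sample-quality variation.
#
# Dispersion is estimated per feature by profile maximum likelihood under the
# full model and shared by both fits, which keeps the models strictly nested.
# This deliberately omits empirical-Bayes dispersion shrinkage; the test's
# calibration is checked by null simulation instead.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' whose counts are positive in every sample, of the ratio between the
#' sample's count and the feature's geometric mean across samples.
#'
#' @param counts nonnegative integer matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no feature has positive counts in every sample; size factors are undefined")
  sf <- apply(counts, 2, function(cnt) {
    exp(median(log(cnt[usable]) - log_geo[usable]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("size factor estimation produced a non-positive factor")
  sf
}

#' Counts per million after size-factor normalization
#'
#' Counts are divided by their sample's size factor and rescaled so every
#' column sums to one million.
#'
#' @param counts feature x sample count matrix.
#' @param sf per-sample size factors (defaults to [size_factors()]).
#' @return numeric matrix of CPM values, columns summing to 1e6.
#' @export
cpm <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  norm <- sweep(counts, 2, sf, "/")
  tot <- colSums(norm)
  if (any(tot == 0)) stop("sample with zero total count cannot be CPM-scaled")
  sweep(norm, 2, tot, "/") * 1e6
}

#' Design matrices for the full and reduced time-course models
#'
#' Timepoints are reference-coded with the earliest timepoint as baseline.
#'
#' @param samples sample sheet data.frame with `timepoint` and, when
#'   `use_rin`, a numeric `rin` column.
#' @param use_rin include the RIN blocking covariate.
#' @return list with `full` and `reduced` design matrices.
#' @export
build_design <- function(samples, use_rin = TRUE) {
  tp <- samples$timepoint
  if (!is.factor(tp)) tp <- order_timepoints(tp)
  tp <- factor(as.character(tp), levels = levels(tp))  # drop ordered coding
  if (use_rin) {
    stop_if_not_cols(samples, "rin", "sample sheet")
    full <- stats::model.matrix(~ rin + tp, data = data.frame(rin = samples$rin, tp = tp))
    reduced <- stats::model.matrix(~ rin, data = data.frame(rin = samples$rin))
  } else {
    full <- stats::model.matrix(~ tp, data = data.frame(tp = tp))
    reduced <- stats::model.matrix(~ 1, data = data.frame(x = seq_along(tp)))
  }
  if (qr(full)$rank < ncol(full)) stop("full design matrix is rank deficient")
  list(full = full, reduced = reduced, timepoint = tp)
}

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

fit_nb_theta <- function(y, X, offset, theta) {
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, offset = offset,
    family = MASS::negative.binomial(theta = theta, link = "log"),
    control = list(maxit = 50)
  ))
  fit$loglik <- nb_loglik(y, fit$fitted.values, theta)
  fit
}

#' Fit a negative-binomial GLM with log link and offsets
#'
#' Coefficients are maximum-likelihood for fixed dispersion; when
#' `dispersion` is `NULL` it is estimated by profile likelihood (golden
#' section search over log dispersion). Non-convergence is flagged, never
#' silently ignored.
#'
#' @param y per-sample counts for one feature.
#' @param design design matrix (full column rank).
#' @param offset per-sample offset, normally `log(size_factors)`.
#' @param dispersion fixed NB dispersion alpha (variance mu + alpha mu^2), or
#'   `NULL` to estimate it.
#' @return object of class `nb_fit`: coefficients, dispersion, log-likelihood,
#'   fitted values, coefficient covariance, convergence flag.
#' @export
fit_nb_glm <- function(y, design, offset = rep(0, length(y)), dispersion = NULL) {
  if (any(y < 0)) stop("counts must be nonnegative")
  if (all(y == 0)) {
    return(structure(list(coefficients = setNames(rep(NA_real_, ncol(design)),
                                                  colnames(design)),
                          dispersion = NA_real_, loglik = NA_real_,
                          fitted = rep(0, length(y)), vcov = NULL,
                          converged = FALSE, all_zero = TRUE,
                          design = design),
                     class = "nb_fit"))
  }
  if (is.null(dispersion)) {
    # Cox-Reid adjusted profile likelihood: the plain profile MLE of the
    # dispersion is biased downward by the coefficients fitted alongside it
    # (anticonservative LRTs); subtracting half the log determinant of the
    # Fisher information corrects this.
    prof <- function(log_theta) {
      f <- fit_nb_theta(y, design, offset, exp(log_theta))
      xtwx <- crossprod(design * sqrt(f$weights))
      cr <- as.numeric(determinant(xtwx, logarithm = TRUE)$modulus) / 2
      f$loglik - cr
    }
    opt <- optimize(prof, interval = c(log(1e-2), log(1e6)), maximum = TRUE,
                    tol = 1e-2)
    theta <- exp(opt$maximum)
  } else {
    if (dispersion <= 0) stop("dispersion must be positive")
    theta <- 1 / dispersion
  }
  fit <- fit_nb_theta(y, design, offset, theta)
  w <- fit$weights
  xtwx <- crossprod(design * sqrt(w))
  vc <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(colnames(design), colnames(design))
  structure(list(coefficients = setNames(fit$coefficients, colnames(design)),
                 dispersion = 1 / theta, loglik = fit$loglik,
                 fitted = fit$fitted.values, vcov = vc,
                 converged = isTRUE(fit$converged), all_zero = FALSE,
                 design = design),
            class = "nb_fit")
}

#' Moderate per-feature dispersions toward the cross-feature median
#'
#' Per-feature NB dispersion estimates from few residual degrees of freedom
#' are noisy, and a downward-noisy estimate inflates the LRT far more than
#' an upward-noisy one deflates it, so raw per-feature estimates give an
#' anticonservative test. Estimates are therefore shrunk toward the median
#' estimate across features on the log scale, with weight
#' `resid_df / (resid_df + prior_df)` on the per-feature value: designs with
#' many replicates keep mostly their own estimate, minimal two-replicate
#' designs borrow mostly from the ensemble.
#'
#' @param disp_hat per-feature dispersion estimates (NA allowed).
#' @param resid_df residual degrees of freedom of the fit that produced
#'   them (samples minus model parameters).
#' @param prior_df weight of the ensemble median (default 10).
#' @return moderated dispersions, same length as `disp_hat`.
#' @export
moderate_dispersion <- function(disp_hat, resid_df, prior_df = 10) {
  ok <- !is.na(disp_hat)
  if (!any(ok)) return(disp_hat)
  center <- median(disp_hat[ok])
  w <- max(0, resid_df) / (max(0, resid_df) + prior_df)
  out <- disp_hat
  out[ok] <- exp(w * log(disp_hat[ok]) + (1 - w) * log(center))
  out
}

#' Likelihood-ratio test between nested NB fits
#'
#' @param full,reduced `nb_fit` objects fitted on the same counts with the
#'   same dispersion; the reduced design's columns must be a subset of the
#'   full design's.
#' @return list with `stat` (2 * delta log-likelihood, clipped at zero),
#'   `df` (difference in parameter count) and `p` (upper chi-square tail).
#' @export
nb_lrt <- function(full, reduced) {
  if (!inherits(full, "nb_fit") || !inherits(reduced, "nb_fit"))
    stop("nb_lrt expects nb_fit objects")
  if (!all(colnames(reduced$design) %in% colnames(full$design)))
    stop("models are not nested: reduced design has covariates absent from the full design")
  df <- ncol(full$design) - ncol(reduced$design)
  if (df <= 0) stop("models are not nested: full model has no extra parameters")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Independent filtering of low-count features
#'
#' Scans mean-normalized-count quantile thresholds (0 to 0.95 in steps of
#' 0.01), applies BH adjustment only to features above each threshold, and
#' selects the threshold that maximizes the number of adjusted rejections at
#' `alpha` after smoothing the rejection curve with a centered moving average
#' (window 5). Filtered-out features receive `NA` adjusted p-values.
#'
#' @param pvalue raw p-values, one per feature.
#' @param base_mean mean normalized count per feature.
#' @param alpha adjusted-p significance threshold used to count rejections.
#' @return list with `padj`, logical `keep`, the chosen `threshold` quantile
#'   and the underlying `rejections` curve.
#' @export
independent_filter <- function(pvalue, base_mean, alpha = 0.05) {
  stopifnot(length(pvalue) == length(base_mean))
  qs <- seq(0, 0.95, by = 0.01)
  cuts <- quantile(base_mean, qs, na.rm = TRUE, names = FALSE)
  rej <- vapply(cuts, function(ct) {
    idx <- base_mean >= ct & !is.na(pvalue)
    if (!any(idx)) return(0L)
    sum(adjust_bh(pvalue[idx]) < alpha, na.rm = TRUE)
  }, integer(1))
  sm <- stats::filter(rej, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- rej[is.na(sm)]  # edges: fall back to raw counts
  best <- which.max(sm)            # ties resolve to the smallest threshold
  keep <- base_mean >= cuts[best]
  padj <- rep(NA_real_, length(pvalue))
  padj[keep & !is.na(pvalue)] <- adjust_bh(pvalue[keep & !is.na(pvalue)])
  list(padj = padj, keep = keep, threshold = qs[best], rejections = rej)
}

#' Time-course differential testing by nested NB likelihood-ratio test
#'
#' For every feature, fits the full (covariate + timepoint) and reduced
#' (covariate only) NB GLMs with a shared profile-MLE dispersion and tests
#' the timepoint effect with a chi-square LRT (df = timepoints - 1). BH
#' adjustment is applied after independent filtering on mean normalized
#' counts.
#'
#' @param counts feature x sample count matrix.
#' @param samples sample sheet with `timepoint` (and `rin` if `use_rin`).
#' @param use_rin include RIN as a blocking covariate (RNA-seq design); set
#'   `FALSE` for assays without a quality covariate (ATAC-seq design, where
#'   the reduced model is intercept-only).
#' @param alpha adjusted-p threshold reported in the `significant` column.
#' @param filter apply independent filtering before BH adjustment.
#' @param prior_df ensemble weight for dispersion moderation (see
#'   [moderate_dispersion()]).
#' @param test reference distribution for the LRT statistic: `"ftest"`
#'   (default) divides by its df and uses an F distribution whose
#'   denominator df is the residual df plus `prior_df`, which accounts for
#'   the dispersion being estimated rather than known; `"chisq"` is the
#'   asymptotic chi-square reference.
#' @return data.frame with feature, baseMean, dispersion, stat, df, pvalue,
#'   padj, filtered, significant and converged columns.
#' @export
de_timecourse <- function(counts, samples, use_rin = TRUE, alpha = 0.05,
                          filter = TRUE, prior_df = 10,
                          test = c("ftest", "chisq")) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(samples))
    stop("sample sheet does not match count matrix columns")
  if (length(unique(samples$timepoint)) < 2)
    stop("time-course testing needs at least two timepoints")
  des <- build_design(samples, use_rin = use_rin)
  sf <- size_factors(counts)
  offset <- log(sf)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  n <- nrow(counts)
  stat <- p <- disp <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  df_lrt <- ncol(des$full) - ncol(des$reduced)
  nonzero <- rowSums(counts) > 0  # all-zero rows: likelihood undefined
  ## pass 1: per-feature CR-adjusted dispersion under the full model
  disp_hat <- rep(NA_real_, n)
  for (i in which(nonzero))
    disp_hat[i] <- fit_nb_glm(counts[i, ], des$full, offset)$dispersion
  resid_df <- ncol(counts) - ncol(des$full)
  disp <- moderate_dispersion(disp_hat, resid_df = resid_df,
                              prior_df = prior_df)
  ## pass 2: nested fits sharing the moderated dispersion
  for (i in which(nonzero)) {
    y <- counts[i, ]
    full <- fit_nb_glm(y, des$full, offset, dispersion = disp[i])
    red <- fit_nb_glm(y, des$reduced, offset, dispersion = disp[i])
    lr <- nb_lrt(full, red)
    stat[i] <- lr$stat
    p[i] <- if (test == "ftest")
      stats::pf(lr$stat / df_lrt, df_lrt, resid_df + prior_df,
                lower.tail = FALSE)
    else lr$p
    conv[i] <- full$converged
  }
  if (filter) {
    fl <- independent_filter(p, base_mean, alpha = alpha)
    padj <- fl$padj; filtered <- !fl$keep
  } else {
    padj <- rep(NA_real_, n)
    padj[!is.na(p)] <- adjust_bh(p[!is.na(p)])
    filtered <- rep(FALSE, n)
  }
  data.frame(feature = rownames(counts) %||% as.character(seq_len(n)),
             baseMean = base_mean, dispersion = disp,
             stat = stat, df = df_lrt, pvalue = p, padj = padj,
             filtered = filtered,
             significant = !is.na(padj) & padj < alpha,
             converged = conv, row.names = NULL)
}

#' Pairwise Wald tests between two timepoints
#'
#' Fits the full time-course model and tests the contrast between two
#' timepoint coefficients with a Wald z statistic (coefficient difference
#' over its standard error). BH adjustment is applied within the contrast.
#'
#' @inheritParams de_timecourse
#' @param tp_a,tp_b timepoint labels to contrast (`tp_b` minus `tp_a`).
#' @return data.frame with feature, log2FoldChange, stat, pvalue, padj.
#' @export
wald_pairwise <- function(counts, samples, tp_a, tp_b, use_rin = TRUE) {
  if (identical(as.character(tp_a), as.character(tp_b)))
    stop("invalid contrast: the two timepoints are identical")
  tp_chr <- as.character(samples$timepoint)
  for (tp in c(tp_a, tp_b)) {
    if (!tp %in% tp_chr) stop(sprintf("timepoint %s absent from sample sheet", tp))
    if (sum(tp_chr == tp) < 2)
      stop(sprintf("timepoint %s has a single sample; variance not estimable", tp))
  }
  counts <- as.matrix(counts)
  des <- build_design(samples, use_rin = use_rin)
  X <- des$full
  sf <- size_factors(counts); offset <- log(sf)
  lev <- levels(des$timepoint)
  cvec <- setNames(rep(0, ncol(X)), colnames(X))
  for (tp in list(c(tp_b, 1), c(tp_a, -1))) {
    nm <- paste0("tp", tp[1])
    if (nm %in% names(cvec)) cvec[nm] <- as.numeric(tp[2])
    # reference level contributes 0
  }
  n <- nrow(counts)
  est <- z <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, offset)
    if (is.null(fit$vcov) || anyNA(fit$coefficients)) next
    b <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    est[i] <- b / log(2)
    z[i] <- b / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  padj <- rep(NA_real_, n)
  padj[!is.na(p)] <- adjust_bh(p[!is.na(p)])
  data.frame(feature = rownames(counts) %||% as.character(seq_len(n)),
             log2FoldChange = est, stat = z, pvalue = p, padj = padj,
             row.names = NULL)
}
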