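#' Parallel analysis for component retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen percentile of eigenvalues from random data of identical shape
#' and retains leading components whose observed eigenvalue exceeds the
#' null percentile (counting stops at the first failure). The null model
#' is i.i.d. standard-normal data by default; a permutation-of-columns
#' null is available.
#'
#' Rows with missing values are dropped (listwise deletion) with a
#' message; a constant variable is an error.
#'
#' @param x numeric data.frame or matrix (rows = notes, columns =
#'   measurements).
#' @param n_iterations random datasets for the null.
#' @param percentile percentile of the null eigenvalue distribution.
#' @param seed integer seed for the null draws.
#' @param null `"normal"` or `"permute"`.
#' @return integer: number of components to retain (>= 0), with the
#'   observed eigenvalues and null thresholds as attributes.
#' @export
parallel_analysis <- function(x, n_iterations = 1000, percentile = 95,
                              seed = 1L, null = c("normal", "permute")) {
  null <- match.arg(null)
  x <- drop_missing_rows(as.matrix(x))
  n <- nrow(x); p <- ncol(x)
  stopifnot(p >= 2, n >= 3)
  check_nonconstant(x)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_eig <- matrix(0, n_iterations, p)
  for (i in seq_len(n_iterations)) {
    r <- if (null == "normal") matrix(stats::rnorm(n * p), n, p)
         else apply(x, 2, sample)
    null_eig[i, ] <- eigen(stats::cor(r), symmetric = TRUE,
                           only.values = TRUE)$values
  }
  thresh <- apply(null_eig, 2, stats::quantile, probs = percentile / 100)
  keep <- obs > thresh
  n_retained <- if (!keep[1]) 0L else
    (which(!keep)[1] %||% (p + 1L)) - 1L
  structure(as.integer(n_retained), eigenvalues = obs, thresholds = thresh)
}

`%||%` <- function(a, b) if (length(a)) a else b

drop_missing_rows <- function(x) {
  bad <- !stats::complete.cases(x)
  if (any(bad)) {
    message(sum(bad), " row(s) with missing values dropped")
    x <- x[!bad, , drop = FALSE]
  }
  x
}

check_nonconstant <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  invisible(TRUE)
}

#' Principal components with varimax rotation and Bartlett scores
#'
#' Correlation-matrix PCA (variables standardized): the first
#' `n_retained` component loadings are varimax-rotated with Kaiser
#' normalization, and per-note component scores are computed by the
#' Bartlett weighted-least-squares method using uniquenesses from the
#' rotated solution. With one retained component the rotation is the
#' identity. Communalities, and hence the total retained variance, are
#' invariant under the rotation.
#'
#' @param x numeric data.frame or matrix.
#' @param n_retained number of components to retain (e.g. from
#'   [parallel_analysis()]).
#' @return object of class `pc_model`: list with `n_retained`, `loadings`
#'   (variables x components, rotated), `varprop` (proportion of total
#'   variance per component), `scores` (rows x components), `center`,
#'   `scale`.
#' @export
pca_varimax <- function(x, n_retained) {
  x <- drop_missing_rows(as.matrix(x))
  p <- ncol(x)
  stopifnot(n_retained >= 1, n_retained <= p)
  check_nonconstant(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  z <- scale(x, ctr, scl)
  R <- stats::cor(x)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    v <- abs(ev$vectors[, which.min(ev$values)])
    stop("singular correlation matrix; near-collinear variables: ",
         paste(colnames(x)[v > 0.3], collapse = ", "))
  }
  m <- n_retained
  L <- ev$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(m)]), m)
  if (m >= 2) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
  }
  # order rotated components by explained variance, sign so the largest
  # loading is positive
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(m)) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  dimnames(L) <- list(colnames(x), paste0("PC", seq_len(m)))
  psi <- pmax(1 - rowSums(L^2), 1e-6)      # uniquenesses
  PL <- L / psi                            # Psi^-1 L
  scores <- z %*% PL %*% solve(crossprod(L, PL))
  colnames(scores) <- colnames(L)
  structure(list(n_retained = m, loadings = L,
                 varprop = colSums(L^2) / p,
                 scores = scores, center = ctr, scale = scl),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d components, %.1f%% of total variance\n",
              x$n_retained, 100 * sum(x$varprop)))
  invisible(x)
}

#' REML variance components of nested random factors
#'
#' For each component's scores, fits a random-intercept model with the
#' declared random factors by restricted maximum likelihood and returns
#' the variance attributed to each factor plus the residual
#' (within-individual) variance. Factors are treated as nested in the
#' order given (e.g. species, colony within species, individual within
#' colony); grouping variables are combined accordingly before fitting.
#' REML constrains components to be >= 0; estimates at the zero boundary
#' are flagged as truncated.
#'
#' For a balanced one-way design the REML estimate coincides with the
#' ANOVA moment estimator `(MS_between - MS_within) / n0` whenever the
#' latter is nonnegative.
#'
#' @param scores numeric matrix (rows x components) or vector.
#' @param data data.frame holding the factor columns, same rows.
#' @param factors character: random-factor column names, outermost first.
#' @param nested logical; treat `factors` as hierarchically nested.
#' @return object of class `vce`: data.frame with columns `component`,
#'   `factor` (each factor plus `"residual"`), `variance`, `truncated`.
#' @export
estimate_vce <- function(scores, data, factors, nested = TRUE) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  stopifnot(nrow(scores) == nrow(data), length(factors) >= 1)
  for (f in factors) {
    if (!f %in% names(data)) stop("factor column not found: ", f)
    if (length(unique(data[[f]])) < 2)
      stop("factor '", f, "' has fewer than 2 levels")
  }
  groups <- data.frame(row.names = seq_len(nrow(data)))
  for (i in seq_along(factors)) {
    groups[[factors[i]]] <- if (nested && i > 1)
      interaction(groups[[factors[i - 1]]], data[[factors[i]]], drop = TRUE)
    else factor(data[[factors[i]]])
  }
  form <- stats::as.formula(paste(
    "y ~ 1 +", paste(sprintf("(1 | %s)", factors), collapse = " + ")))
  out <- list()
  for (j in seq_len(ncol(scores))) {
    d <- cbind(data.frame(y = scores[, j]), groups)
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        check.nobs.vs.nlev = "ignore",
                        check.nobs.vs.nRE = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc$vcov, vc$grp)
    resid <- v[["Residual"]]
    for (f in factors)
      out[[length(out) + 1L]] <- data.frame(
        component = colnames(scores)[j], factor = f,
        variance = v[[f]], truncated = v[[f]] < 1e-10)
    out[[length(out) + 1L]] <- data.frame(
      component = colnames(scores)[j], factor = "residual",
      variance = resid, truncated = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("vce", "data.frame")
  res
}

#' ANOVA moment estimator of a balanced one-way variance component
#'
#' Closed-form method-of-moments estimate used as an independent check of
#' REML on balanced one-way designs: `S_B^2 = (MS_between - MS_within) /
#' n0` with `n0` the common group size, and `S_w^2 = MS_within`.
#'
#' @param y numeric response.
#' @param group grouping factor (balanced).
#' @return list with `between` (possibly negative) and `within`.
#' @export
anova_vce <- function(y, group) {
  group <- factor(group)
  n0 <- unique(table(group))
  if (length(n0) != 1) stop("design is not balanced")
  g <- nlevels(group)
  means <- tapply(y, group, mean)
  ms_b <- n0 * sum((means - mean(y))^2) / (g - 1)
  ms_w <- sum((y - means[group])^2) / (length(y) - g)
  list(between = (ms_b - ms_w) / n0, within = ms_w)
}

#' Signature information capacity in bits
#'
#' Following Beecher's information analysis: for each component, the
#' between-signaler variance `S_B^2` is the sum of the variance
#' components of the declared signature factors (by default colony and
#' individual), the within variance `S_w^2` is the residual, and the
#' total is `S_T^2 = S_B^2 + S_w^2`. The information carried by the
#' component is `H_i = log2(S_T / S_w)` (a ratio of standard deviations,
#' i.e. half the log2 variance ratio) and the total signature information
#' is `H_s = sum(H_i)`. Repeatability per component is
#' `r_i = S_B^2 / (S_B^2 + S_w^2)`.
#'
#' @param vce an [estimate_vce()] result.
#' @param signature_factors factors whose variance counts as signature
#'   (between-signaler) variance.
#' @return object of class `signature_info`: list with `per_component`
#'   (data.frame: component, S_B2, S_w2, S_T2, H_i, repeatability),
#'   `H_s_bits`, `mean_repeatability`.
#' @export
signature_information <- function(vce,
                                  signature_factors = c("colony", "individual")) {
  stopifnot(inherits(vce, "vce"))
  comps <- unique(vce$component)
  per <- do.call(rbind, lapply(comps, function(cp) {
    sub <- vce[vce$component == cp, ]
    sw <- sub$variance[sub$factor == "residual"]
    if (sw <= 0) stop("residual variance is zero for ", cp,
                      ": information would be infinite")
    sb <- sum(sub$variance[sub$factor %in% signature_factors])
    st <- sb + sw
    data.frame(component = cp, S_B2 = sb, S_w2 = sw, S_T2 = st,
               H_i = 0.5 * log2(st / sw),
               repeatability = sb / (sb + sw))
  }))
  rownames(per) <- NULL
  structure(list(per_component = per,
                 H_s_bits = sum(per$H_i),
                 mean_repeatability = mean(per$repeatability)),
            class = "signature_info")
}

#' @export
print.signature_info <- function(x, ...) {
  cat(sprintf("<signature_info> H_s = %.2f bits over %d components; mean repeatability %.2f (range %.3f-%.3f)\n",
              x$H_s_bits, nrow(x$per_component), x$mean_repeatability,
              min(x$per_component$repeatability),
              max(x$per_component$repeatability)))
  invisible(x)
}

#' Percentage of variance attributed to each random factor
#'
#' Weights each factor's per-component variance share by the percentage
#' of total variance explained by that component: `percent(f) =
#' 100 * sum_i [S_f^2(i) / S_T^2(i)] * w_i / sum_i w_i` with `w_i` the
#' component's variance proportion. Factor shares plus the residual share
#' sum to 100.
#'
#' @param vce an [estimate_vce()] result.
#' @param model the matching [pca_varimax()] model.
#' @return named numeric: percent per factor plus `residual`.
#' @export
weighted_variance_attribution <- function(vce, model) {
  stopifnot(inherits(vce, "vce"), inherits(model, "pc_model"))
  comps <- unique(vce$component)
  if (!setequal(comps, colnames(model$loadings)))
    stop("vce and model cover different components")
  w <- model$varprop[match(comps, colnames(model$loadings))]
  factors <- setdiff(unique(vce$factor), "residual")
  shares <- sapply(c(factors, "residual"), function(f) {
    per_comp <- vapply(comps, function(cp) {
      sub <- vce[vce$component == cp, ]
      sub$variance[sub$factor == f] / sum(sub$variance)
    }, numeric(1))
    100 * sum(per_comp * w) / sum(w)
  })
  shares
}
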