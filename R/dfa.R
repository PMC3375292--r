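#' Linear discriminant function analysis with leave-one-out rates
#'
#' Fits linear discriminant functions (equal priors, pooled within-class
#' covariance) and reports per-class and overall correct classification
#' rates for both resubstitution (training notes) and leave-one-out
#' cross-validation (testing notes), together with Wilks' lambda
#' `det(W)/det(T)` and Bartlett's chi-square approximation
#' `X^2 = -(n - 1 - (p + g)/2) * ln(lambda)` on `p*(g-1)` degrees of
#' freedom.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param grouping class labels (one per row).
#' @return object of class `dfa_result`: list with `scaling`
#'   (discriminant coefficients), `means`, rate tables (`class_rates`,
#'   `overall_training_pct`, `overall_loo_pct`), `wilks_lambda`,
#'   `chi_sq`, `df`, `p_value`, and the stored `predictions`.
#' @export
lda_fit <- function(x, grouping) {
  x <- as.matrix(x)
  grouping <- factor(grouping)
  g <- nlevels(grouping)
  n <- nrow(x); p <- ncol(x)
  if (g < 2) stop("need at least 2 classes")
  counts <- table(grouping)
  if (any(counts < 2))
    stop("class(es) with a single note: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (n <= p)
    stop("more variables (", p, ") than notes (", n,
         "); reduce dimensionality first")
  W <- pooled_sscp(x, grouping)
  Tm <- crossprod(scale(x, center = TRUE, scale = FALSE))
  ldW <- determinant(W, logarithm = TRUE)   # log scale: p can be large
  ldT <- determinant(Tm, logarithm = TRUE)
  if (ldW$sign <= 0 || !is.finite(ldW$modulus)) {
    sds <- apply(x, 2, stats::sd)
    stop("singular pooled within-class covariance; check variables: ",
         paste(colnames(x)[rank(sds) <= 3], collapse = ", "))
  }
  lambda <- exp(as.numeric(ldW$modulus) - as.numeric(ldT$modulus))
  chi <- -(n - 1 - (p + g) / 2) * log(lambda)
  df <- as.integer(p * (g - 1))
  # slopes/concavities are derived from the contour frequencies, so mild
  # collinearity is inherent to the full variable set; hard singularity
  # was ruled out on det(W) above
  degenerate <- tryCatch({
    fit <- suppressWarnings(MASS::lda(x, grouping, prior = rep(1 / g, g)))
    FALSE
  }, error = function(e) {
    if (grepl("identical", conditionMessage(e))) TRUE else stop(e)
  })
  if (degenerate) {
    # all class means coincide: no discriminant direction exists and any
    # assignment is chance; report chance-level predictions
    nd <- min(p, g - 1L)
    scl <- matrix(0, p, nd,
                  dimnames = list(colnames(x), paste0("LD", seq_len(nd))))
    fit <- list(scaling = scl,
                means = do.call(rbind, lapply(levels(grouping), function(k)
                  colMeans(x[grouping == k, , drop = FALSE]))))
    train_pred <- loo_pred <- factor(rep(levels(grouping)[1], n),
                                     levels = levels(grouping))
  } else {
    train_pred <- stats::predict(fit, x)$class
    loo_pred <- suppressWarnings(
      MASS::lda(x, grouping, prior = rep(1 / g, g), CV = TRUE))$class
  }
  cls <- levels(grouping)
  class_rates <- data.frame(
    class = cls,
    n = as.integer(counts),
    training_pct = 100 * vapply(cls, function(k)
      mean(train_pred[grouping == k] == k), numeric(1)),
    loo_pct = 100 * vapply(cls, function(k)
      mean(loo_pred[grouping == k] == k), numeric(1)),
    row.names = NULL)
  structure(list(scaling = fit$scaling, means = fit$means,
                 class_rates = class_rates,
                 overall_training_pct = 100 * mean(train_pred == grouping),
                 overall_loo_pct = 100 * mean(loo_pred == grouping),
                 wilks_lambda = lambda, chi_sq = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 n = n, predictions = list(training = train_pred,
                                           loo = loo_pred)),
            class = "dfa_result")
}

pooled_sscp <- function(x, grouping) {
  W <- matrix(0, ncol(x), ncol(x))
  for (k in levels(grouping)) {
    xi <- x[grouping == k, , drop = FALSE]
    W <- W + crossprod(scale(xi, center = TRUE, scale = FALSE))
  }
  W
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> %d notes, %d classes\n", x$n,
              nrow(x$class_rates)))
  cat(sprintf("  training %.0f%%, leave-one-out %.0f%% correct\n",
              x$overall_training_pct, x$overall_loo_pct))
  cat(sprintf("  Wilks' lambda = %.3g, X2 = %.1f, df = %d, p = %.3g\n",
              x$wilks_lambda, x$chi_sq, x$df, x$p_value))
  invisible(x)
}

#' Canonical structure matrix
#'
#' Pooled within-group correlations of each original variable with each
#' discriminant score; the conventional table reports, per discriminant
#' function, the variables with the highest absolute correlations.
#'
#' @param fit a [lda_fit()] result.
#' @param x,grouping the data the fit was computed on.
#' @param top how many top-ranked variables to report per function.
#' @return list with `correlations` (variables x functions) and `top`
#'   (data.frame: function, variable, loading, ranked by |loading|).
#' @export
structure_matrix <- function(fit, x, grouping, top = 5) {
  x <- as.matrix(x)
  grouping <- factor(grouping)
  scores <- x %*% fit$scaling
  xc <- x; sc <- scores
  for (k in levels(grouping)) {
    i <- grouping == k
    xc[i, ] <- scale(x[i, , drop = FALSE], center = TRUE, scale = FALSE)
    sc[i, ] <- scale(scores[i, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  corr <- stats::cor(xc, sc)
  tops <- do.call(rbind, lapply(seq_len(ncol(corr)), function(j) {
    ord <- order(abs(corr[, j]), decreasing = TRUE)[seq_len(min(top, nrow(corr)))]
    data.frame(fn = colnames(corr)[j], variable = rownames(corr)[ord],
               loading = corr[ord, j], row.names = NULL)
  }))
  list(correlations = corr, top = tops)
}

#' Permuted discriminant function analysis for nested designs
#'
#' Tests whether notes can be assigned to the levels of a test factor
#' (species, population, colony, sex) above chance while controlling for
#' a nested control factor (typically individual), following the
#' two-stage randomization scheme for non-independent data. Observed
#' stage: `n_dfa_reps` times, an equal number of training notes is drawn
#' from every subject, discriminant functions are fitted to classify the
#' test factor, the held-out notes are classified, and the rates are
#' averaged. Null stage: `n_permutations` times, test-factor labels are
#' reshuffled across subjects (keeping each subject's notes together and
#' the number of subjects per level fixed) and the identical observed-
#' stage procedure is run. The one-tailed p-value is the proportion of
#' null rates at least as large as the observed rate (optionally with the
#' +1/(N+1) small-sample correction).
#'
#' @param x numeric matrix/data.frame of predictors.
#' @param test_factor vector of test-factor labels, one per note.
#' @param control_factor vector of subject labels nested in the test
#'   factor.
#' @param n_train_per_subject training notes drawn per subject, or
#'   `"auto"` = floor(2/3 of the smallest subject's notes).
#' @param n_dfa_reps training redraws averaged per dataset.
#' @param n_permutations permuted datasets for the null.
#' @param seed integer seed.
#' @param plus_one use the (b + 1)/(N + 1) p-value variant.
#' @return object of class `pdfa_result`: list with
#'   `observed_loo_pct`, `observed_training_pct`, `null_loo_pct`
#'   (length `n_permutations`), `p_value`, `n_notes`, `config`.
#' @export
pdfa <- function(x, test_factor, control_factor,
                 n_train_per_subject = "auto", n_dfa_reps = 100,
                 n_permutations = 1000, seed = 1L, plus_one = FALSE) {
  x <- as.matrix(x)
  test_factor <- as.character(test_factor)
  control_factor <- as.character(control_factor)
  stopifnot(nrow(x) == length(test_factor),
            nrow(x) == length(control_factor),
            n_dfa_reps >= 1, n_permutations >= 1)
  map <- unique(data.frame(subject = control_factor, level = test_factor))
  if (anyDuplicated(map$subject))
    stop("control factor is not nested in the test factor: subject(s) ",
         paste(unique(map$subject[duplicated(map$subject)]), collapse = ", "),
         " appear under several test-factor levels")
  if (length(unique(map$level)) < 2) stop("test factor needs >= 2 levels")
  notes_per_subject <- table(control_factor)
  if (identical(n_train_per_subject, "auto"))
    n_train_per_subject <- floor(2 / 3 * min(notes_per_subject))
  n_train_per_subject <- as.integer(n_train_per_subject)
  low <- names(notes_per_subject)[notes_per_subject <= n_train_per_subject]
  if (length(low))
    stop("subject(s) with too few notes to hold any out: ",
         paste(low, collapse = ", "))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subj_idx <- split(seq_len(nrow(x)), control_factor)

  run_stage <- function(level_of_subject) {
    labels <- level_of_subject[control_factor]
    loo <- numeric(n_dfa_reps); tr <- numeric(n_dfa_reps)
    for (r in seq_len(n_dfa_reps)) {
      train <- unlist(lapply(subj_idx, sample, size = n_train_per_subject))
      test <- setdiff(seq_len(nrow(x)), train)
      fit <- suppressWarnings(
        MASS::lda(x[train, , drop = FALSE], grouping = labels[train],
                  prior = rep(1 / length(unique(labels)),
                              length(unique(labels)))))
      tr[r] <- 100 * mean(stats::predict(fit)$class == labels[train])
      loo[r] <- 100 * mean(
        as.character(stats::predict(fit, x[test, , drop = FALSE])$class) ==
          labels[test])
    }
    c(loo = mean(loo), training = mean(tr))
  }

  observed_map <- stats::setNames(map$level, map$subject)
  obs <- run_stage(observed_map)
  null_rates <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm_map <- stats::setNames(sample(map$level), map$subject)
    null_rates[b] <- run_stage(perm_map)[["loo"]]
  }
  hits <- sum(null_rates >= obs[["loo"]])
  p <- if (plus_one) (hits + 1) / (n_permutations + 1)
       else hits / n_permutations
  structure(list(observed_loo_pct = obs[["loo"]],
                 observed_training_pct = obs[["training"]],
                 null_loo_pct = null_rates, p_value = p,
                 n_notes = nrow(x),
                 config = list(n_train_per_subject = n_train_per_subject,
                               n_dfa_reps = n_dfa_reps,
                               n_permutations = n_permutations,
                               seed = seed, plus_one = plus_one)),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("<pdfa_result> n = %d notes: %.0f%% of test notes correct (training %.0f%%), p = %.3g (%d permutations)\n",
              x$n_notes, x$observed_loo_pct, x$observed_training_pct,
              x$p_value, x$config$n_permutations))
  invisible(x)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down familywise error control: p-values are sorted ascending and
#' the i-th smallest is compared against `alpha / (m - i + 1)`; testing
#' stops at the first failure.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha familywise error rate.
#' @return data.frame in the input order: `p`, `adjusted` (Holm-adjusted
#'   p), `threshold` (the step-down critical value each p was compared
#'   to), `reject`.
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  thr <- numeric(m)
  thr[ord] <- alpha / (m - seq_len(m) + 1)
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p = p_values, adjusted = adj, threshold = thr,
             reject = adj <= alpha)
}

#' Compare mean classification rates of two groups
#'
#' Pooled-variance two-sample t-test on per-individual classification
#' rates, `df = n_A + n_B - 2`, two-tailed p.
#'
#' @param rates_a,rates_b numeric vectors of rates (%).
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_group_rates <- function(rates_a, rates_b) {
  stopifnot(length(rates_a) >= 2, length(rates_b) >= 2)
  if (stats::var(rates_a) + stats::var(rates_b) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(rates_a, rates_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_a = mean(rates_a), mean_b = mean(rates_b))
}

#' Chi-square outlier test for a single classification rate
#'
#' Squared standardized deviation of the candidate from the sample mean,
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param rates numeric vector of rates (%), candidate included.
#' @param candidate the rate tested as an outlier (must be an element of
#'   `rates`).
#' @return list with `chi_sq` and `p_value`.
#' @export
outlier_chisq <- function(rates, candidate) {
  stopifnot(length(rates) >= 3)
  if (!any(abs(rates - candidate) < 1e-12))
    stop("candidate must be one of the rates")
  v <- stats::var(rates)
  if (v == 0) stop("zero variance among rates")
  stat <- (candidate - mean(rates))^2 / v
  list(chi_sq = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Expected chance classification rate
#'
#' @param n_classes number of equally sampled classes.
#' @return expected correct rate in percent (100 / n_classes).
#' @export
chance_rate <- function(n_classes) {
  stopifnot(n_classes >= 1)
  100 / n_classes
}
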