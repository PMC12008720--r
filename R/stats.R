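code_binary <- function(x, positive, name) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop(name, " numeric coding must be 0/1")
    return(as.numeric(x))
  }
  as.numeric(x == positive)
}

#' Whole-group multiple linear regression of a graph measure on tau load
#'
#' Ordinary least squares of the outcome (global clustering coefficient C or
#' characteristic path length L) on regional tau PET load plus age, sex and
#' APOE-e4 carriership. Sex is coded 0 = male / 1 = female and APOE
#' 0 = noncarrier / 1 = carrier (reference levels documented here because
#' coefficient signs depend on them). Per-coefficient two-sided t-tests and
#' the overall F-test p-value are reported.
#'
#' @param table `data.frame` holding `outcome`, `tau_var`, `age`, `sex`
#'   (`"M"`/`"F"` or 0/1) and `apoe4` (`"carrier"`/`"noncarrier"` or 0/1).
#' @param outcome Name of the outcome column (e.g. `"C"` or `"L"`).
#' @param tau_var Name of the tau regressor column (e.g.
#'   `"dvr_early_metaVOI"`).
#' @param covariates Character vector of covariate columns (default
#'   `c("age","sex","apoe4")`; use `c("age","sex")` for the amyloid model).
#' @return A `regression_result` list: `outcome`, `coefficients`
#'   (term / beta / se / p), `overall_p`, `r_squared`, `n`.
#' @export
fit_primary_regression <- function(table, outcome, tau_var,
                                   covariates = c("age", "sex", "apoe4")) {
  need <- c(outcome, tau_var, covariates)
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data.frame(.y = table[[outcome]], .tau = table[[tau_var]])
  for (cv in covariates) {
    df[[cv]] <- switch(cv,
      sex = code_binary(table$sex, positive = "F", "sex"),
      apoe4 = code_binary(table$apoe4, positive = "carrier", "apoe4"),
      as.numeric(table[[cv]]))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < ncol(df) + 2) stop("too few complete rows for the design")
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)
  terms[terms == ".tau"] <- tau_var
  fstat <- sm$fstatistic
  structure(list(
    outcome = outcome,
    coefficients = data.frame(term = terms, beta = co[, 1], se = co[, 2],
                              p = co[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    overall_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE)),
    r_squared = sm$r.squared,
    n = n), class = "regression_result")
}

#' Extract one regressor's beta and p from a regression result
#' @param res A `regression_result`.
#' @param term Regressor name.
#' @return Named list `beta`, `p`.
#' @export
regression_term <- function(res, term) {
  i <- match(term, res$coefficients$term)
  if (is.na(i)) stop("no such term: ", term)
  list(beta = res$coefficients$beta[i], p = res$coefficients$p[i])
}

#' Spearman correlation, optionally partial for covariates
#'
#' Without covariates: Spearman's rho with the asymptotic t test and a 95 %
#' confidence interval through the Fisher z transform (variance 1/(n-3)).
#' With covariates: every variable is rank-transformed, ranks of x and y are
#' residualised on the covariate ranks by least squares, and the Pearson
#' correlation of the residuals is reported (the standard rank-based partial
#' correlation); the t test uses n-k-2 degrees of freedom and the Fisher-z CI
#' uses variance 1/(n-k-3), with k covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional `data.frame`/matrix of covariates (columns may
#'   include binary factors, coded internally as 0/1 via rank transform).
#' @param conf_level Confidence level (default 0.95).
#' @return A `correlation_result` list: `rho`, `ci`, `p`, `n`, `covariates`.
#' @export
spearman_partial <- function(x, y, covariates = NULL, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (ncol(covariates) == 0) covariates <- NULL
  }
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < 4 + k) stop("too few observations: need n >= 4 + #covariates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: correlation undefined")
  }
  if (k == 0) {
    rho <- stats::cor(x, y, method = "spearman")
    df_t <- n - 2
  } else {
    covariates <- covariates[ok, , drop = FALSE]
    Z <- vapply(covariates, function(col) {
      rank(if (is.numeric(col)) col else as.numeric(as.factor(col)))
    }, numeric(n))
    rx <- stats::lm.fit(cbind(1, Z), rank(x))$residuals
    ry <- stats::lm.fit(cbind(1, Z), rank(y))$residuals
    rho <- stats::cor(rx, ry)
    df_t <- n - 2 - k
  }
  tval <- rho * sqrt(df_t / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df_t, lower.tail = FALSE)
  zse <- 1 / sqrt(n - 3 - k)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12)) + c(-1, 1) * zq * zse)
  structure(list(rho = rho, ci = ci, p = min(p, 1), n = n,
                 covariates = if (k == 0) character(0) else names(covariates)),
            class = "correlation_result")
}

#' Kruskal-Wallis test with Dunn's post hoc pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value, followed by
#' Dunn's z statistics for all group pairs:
#' \deqn{z_{ab} = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} + \frac{1}{n_b}\right)}}}
#' with two-sided normal p-values adjusted by `adjust` (Holm by default).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @param adjust Multiplicity adjustment for the Dunn pairs (any
#'   [stats::p.adjust()] method; default `"holm"`).
#' @return List: `H`, `df`, `p` (Kruskal-Wallis) and `pairs`
#'   (`data.frame` group1/group2/z/p/p_adj).
#' @export
kruskal_dunn <- function(values, groups, adjust = "holm") {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  tab <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) {
    stop("every group needs n >= 2; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var0 <- N * (N + 1) / 12 - tie_term
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(var0 * (1 / tab[pr[1]] + 1 / tab[pr[2]]))
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value,
       pairs = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = as.numeric(z), p = as.numeric(p),
                          p_adj = stats::p.adjust(p, method = adjust),
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk at alpha = 0.05 on each group decides the branch: both
#' normal leads to Welch's t-test, otherwise the Wilcoxon rank-sum test. A
#' constant group falls back to the rank-sum branch with a warning. The
#' chosen branch is reported.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector, each group n >= 3.
#' @param shapiro_alpha Normality gate level (default 0.05).
#' @return List: `method` (`"t.test"`/`"wilcoxon"`), `statistic`, `p`,
#'   `shapiro_p` (per group), `n` (per group).
#' @export
two_group_compare <- function(values, groups, shapiro_alpha = 0.05) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) != 2) stop("exactly two groups required")
  split_v <- split(values, groups)
  if (any(lengths(split_v) < 3)) stop("each group needs n >= 3")
  constant <- vapply(split_v, function(v) stats::sd(v) == 0, TRUE)
  if (any(constant)) {
    warning("constant group; falling back to rank-sum test")
    sw <- c(NA_real_, NA_real_)
    use_t <- FALSE
  } else {
    sw <- vapply(split_v, function(v) stats::shapiro.test(v)$p.value, 0)
    use_t <- all(sw > shapiro_alpha)
  }
  if (use_t) {
    tt <- stats::t.test(split_v[[1]], split_v[[2]])
    res <- list(method = "t.test", statistic = unname(tt$statistic),
                p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(split_v[[1]], split_v[[2]]))
    res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                p = wt$p.value)
  }
  res$shapiro_p <- stats::setNames(sw, levels(groups))
  res$n <- lengths(split_v)
  res
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment; adjusted values are monotone and never below the
#' raw p-values.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
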