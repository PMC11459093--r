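#' @importFrom stats aov anova coef lm pf predict ptukey qtukey quantile
#'   resid rnorm runif shapiro.test
NULL

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`; for a constant vector both are `NA`
#'   with `flag = "degenerate"`.
#' @export
check_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (length(values) > 5000) stop("Shapiro-Wilk limited to n <= 5000")
  if (diff(range(values)) == 0)
    return(list(W = NA_real_, p = NA_real_, flag = "degenerate"))
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, flag = "ok")
}

#' Levene homogeneity-of-variance check (center = mean)
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @return list with `statistic`, `p`, `df`.
#' @export
check_homogeneity <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  lt <- car::leveneTest(values ~ groups, center = mean)
  list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Transform a sample toward normality
#'
#' Tries the identity, then a log, then a Box-Cox power transform, and
#' returns the first whose Shapiro-Wilk p exceeds `alpha`. When none
#' passes, the transform with the best (largest) W is returned with
#' `passed = FALSE`. Nonpositive values are shifted (so the minimum
#' becomes 1) before log/power, and the shift is reported.
#'
#' @param values numeric vector.
#' @param alpha Shapiro-Wilk acceptance level (default 0.05).
#' @return list: `values` (transformed), `method` (`"none"`, `"log"`,
#'   `"power"`), `lambda` (power only), `shift`, `W`, `p`, `passed`.
#' @export
normalize_transform <- function(values, alpha = 0.05) {
  if (any(!is.finite(values))) stop("values must be finite")
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  v_pos <- values + shift
  cand <- list(list(values = values, method = "none",
                    lambda = NA_real_, shift = 0))
  cand[[2]] <- list(values = log(v_pos), method = "log",
                    lambda = NA_real_, shift = shift)
  bc <- MASS::boxcox(v ~ 1, data = data.frame(v = v_pos),
                     lambda = seq(-2, 2, 0.05), plotit = FALSE)
  lam <- bc$x[which.max(bc$y)]
  tv <- if (abs(lam) < 1e-8) log(v_pos) else (v_pos^lam - 1) / lam
  cand[[3]] <- list(values = tv, method = "power", lambda = lam, shift = shift)
  best <- NULL
  for (cd in cand) {
    sw <- check_normality(cd$values)
    cd$W <- sw$W; cd$p <- sw$p
    if (!is.na(sw$p) && sw$p > alpha) {
      cd$passed <- TRUE
      return(cd)
    }
    if (is.null(best) || (!is.na(sw$W) && sw$W > best$W)) best <- cd
  }
  best$passed <- FALSE
  best
}

#' Polynomial chronosequence trend fit
#'
#' Least-squares polynomial of `y` on recovery time. For the default
#' quadratic, the peak recovery time is the vertex when curvature is
#' negative and the vertex lies inside the observed range; otherwise the
#' fit is reported as monotone (no interior peak).
#'
#' @param tvr recovery times (years).
#' @param y response values.
#' @param degree polynomial degree (default 2).
#' @param response name used in printing.
#' @return object of class `trend_fit`: coefficients (ascending powers),
#'   `r_squared`, `p_overall`, `peak_tvr` (NA when no interior maximum),
#'   and the underlying `lm` fit.
#' @export
fit_trend <- function(tvr, y, degree = 2, response = "y") {
  ok <- is.finite(tvr) & is.finite(y)
  tvr <- tvr[ok]; y <- y[ok]
  if (length(y) < degree + 2) stop("need at least degree + 2 points")
  fit <- lm(y ~ poly(tvr, degree, raw = TRUE))
  if (any(is.na(coef(fit)))) stop("rank-deficient polynomial design")
  cf <- unname(coef(fit))
  sm <- summary(fit)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  peak <- NA_real_
  if (degree == 2 && cf[3] < 0) {
    vertex <- -cf[2] / (2 * cf[3])
    if (vertex > min(tvr) && vertex < max(tvr)) peak <- vertex
  } else if (degree != 2) {
    # generic interior argmax on a fine grid
    gx <- seq(min(tvr), max(tvr), length.out = 512)
    gy <- predict(fit, data.frame(tvr = gx))
    i <- which.max(gy)
    if (i > 1 && i < length(gx)) peak <- gx[i]
  }
  structure(list(response = response, degree = degree, coefficients = cf,
                 r_squared = sm$r.squared, p_overall = p_overall,
                 peak_tvr = peak, fit = fit, tvr = tvr, y = y),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Polynomial trend fit:", x$response, "~ TVR (degree", x$degree, ")\n")
  cat("  coefficients:", signif(x$coefficients, 5), "\n")
  cat(sprintf("  R^2 = %.3f, overall p = %.3g\n", x$r_squared, x$p_overall))
  if (is.na(x$peak_tvr)) cat("  no interior peak (monotone trend)\n")
  else cat(sprintf("  peak at TVR = %.1f years\n", x$peak_tvr))
  invisible(x)
}

#' Predicted trend with 95% confidence band
#'
#' @param object a `trend_fit`.
#' @param newdata optional vector of recovery times.
#' @param ... unused.
#' @return data frame `tvr`, `fit`, `lwr`, `upr`.
#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  tv <- if (is.null(newdata))
    seq(min(object$tvr), max(object$tvr), length.out = 101) else newdata
  pr <- predict(object$fit, data.frame(tvr = tv), interval = "confidence")
  data.frame(tvr = tv, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' One-way ANOVA
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 non-empty groups).
#' @return list: `F`, `p`, `MSE`, `df` (between, within), `means`, `n`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("empty group")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       MSE = tab$`Mean Sq`[2], df = tab$Df,
       means = tapply(values, groups, mean),
       n = as.integer(table(groups)),
       fit = fit)
}

#' Duncan multiple-range letters
#'
#' Duncan's multiple range test on group means after a one-way ANOVA.
#' Means are sorted in decreasing order; a span of p consecutive means is
#' declared homogeneous when its range does not exceed
#' R_p = q(1 - (1 - alpha)^(p - 1); p, df_error) * sqrt(MSE / n_h), with
#' n_h the harmonic mean group size. Maximal homogeneous spans share a
#' letter, starting at "a" for the largest mean.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param alpha significance level (default 0.05).
#' @return object of class `duncan_letters`: data frame `group`, `mean`,
#'   `n`, `letters` (sorted by decreasing mean), plus ANOVA `F`, `p`,
#'   `MSE`, `df_error`, and the critical ranges.
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  av <- anova_oneway(values, groups)
  df_err <- av$df[2]
  if (df_err < 1) stop("no error degrees of freedom")
  ord <- order(av$means, decreasing = TRUE)
  means <- av$means[ord]
  ns <- av$n[ord]
  g <- length(means)
  n_h <- g / sum(1 / ns)                       # harmonic mean n
  se <- sqrt(av$MSE / n_h)
  crit <- vapply(2:max(2, g), function(p)
    qtukey(1 - (1 - alpha)^(p - 1), p, df_err) * se, numeric(1))
  crit <- c(NA_real_, crit)                    # crit[p] for span length p
  # nonsig[i, j]: means i..j (sorted) form a homogeneous span, with the
  # protection rule that a nonsignificant wide span covers all sub-pairs
  nonsig <- diag(TRUE, g)
  mark <- function(i, j) {
    if (i >= j) return(invisible())
    if (means[i] - means[j] <= crit[j - i + 1]) {
      for (a in i:j) for (b in a:j) nonsig[a, b] <<- TRUE
    } else {
      mark(i, j - 1)
      mark(i + 1, j)
    }
  }
  mark(1, g)
  # maximal homogeneous intervals -> letters
  intervals <- list()
  for (i in 1:g) {
    j <- i
    while (j < g && nonsig[i, j + 1]) j <- j + 1
    intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals))
    if (a != b && keep[b] &&
        intervals[[a]][1] <= intervals[[b]][1] &&
        intervals[[a]][2] >= intervals[[b]][2] &&
        !identical(a, b) && !all(intervals[[a]] == intervals[[b]]))
      keep[b] <- FALSE
  intervals <- unique(intervals[keep])
  letts <- character(g)
  for (ii in seq_along(intervals)) {
    rng <- intervals[[ii]][1]:intervals[[ii]][2]
    letts[rng] <- paste0(letts[rng], letters[ii])
  }
  tab <- data.frame(group = names(means), mean = unname(means),
                    n = ns, letters = letts)
  structure(list(table = tab, F = av$F, p = av$p, MSE = av$MSE,
                 df_error = df_err, alpha = alpha,
                 critical_ranges = crit, harmonic_n = n_h),
            class = "duncan_letters")
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (MSE %.4g, df error %d)\n",
              x$F, x$p, x$MSE, x$df_error))
  cat("Duncan multiple-range letters (alpha =", x$alpha, "):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
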