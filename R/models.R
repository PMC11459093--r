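#' Mixed model of AGB on diversity predictors
#'
#' Linear mixed model (identity link, Gaussian errors) of plot AGB on the
#' five evolutionary-diversity predictors, with recovery stage as a random
#' intercept. Predictors are z-standardized before fitting so t-values are
#' comparable across community levels; the response may be transformed to
#' normality upstream. Variance components come from a REML fit; the AIC
#' is taken from the matching ML fit so models with different fixed
#' effects are comparable.
#'
#' @param data data frame holding the response, predictors and stage.
#' @param response response column name (default `"total_agb"`).
#' @param predictors character vector of fixed-effect columns
#'   (default the five diversity metrics).
#' @param stage random-intercept grouping column (default `"stage_years"`).
#' @param standardize z-score the predictors first (default TRUE).
#' @return object of class `agb_mixed`: coefficient table (estimate, SE,
#'   t), `AIC`, `r2_marginal`, `r2_conditional`, variance components,
#'   `singular` flag and the underlying `lmerMod` fits.
#' @export
fit_mixed <- function(data, response = "total_agb",
                      predictors = c("PD", "PSR", "PSE", "NRI", "NTI"),
                      stage = "stage_years", standardize = TRUE) {
  cols <- c(response, predictors, stage)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols]
  if (nrow(d) < 10) stop("need at least 10 complete plots")
  if (length(unique(d[[stage]])) < 2) stop("need at least 2 stages")
  if (standardize)
    for (p in predictors) {
      s <- sd(d[[p]])
      if (s == 0) stop("constant predictor: ", p)
      d[[p]] <- (d[[p]] - mean(d[[p]])) / s
    }
  d$.stage <- factor(d[[stage]])
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = " + "),
                                  "+ (1 | .stage)"))
  fit_reml <- lme4::lmer(form, data = d, REML = TRUE,
                         control = lme4::lmerControl(check.conv.singular =
                           lme4::.makeCC(action = "ignore", tol = 1e-4)))
  fit_ml <- lme4::lmer(form, data = d, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular =
                         lme4::.makeCC(action = "ignore", tol = 1e-4)))
  cf <- as.data.frame(summary(fit_reml)$coefficients)
  names(cf) <- c("estimate", "se", "t")
  cf$predictor <- rownames(cf)
  cf <- cf[, c("predictor", "estimate", "se", "t")]
  vc <- as.data.frame(lme4::VarCorr(fit_reml))
  sigma2_stage <- vc$vcov[vc$grp == ".stage"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  r2 <- r2_nakagawa(fit_reml)
  structure(list(coefficients = cf, AIC = stats::AIC(fit_ml),
                 r2_marginal = r2$r2_marginal,
                 r2_conditional = r2$r2_conditional,
                 sigma2_stage = sigma2_stage, sigma2_resid = sigma2_resid,
                 singular = lme4::isSingular(fit_reml),
                 n = nrow(d), response = response, fit = fit_reml,
                 fit_ml = fit_ml),
            class = "agb_mixed")
}

#' @export
print.agb_mixed <- function(x, ...) {
  cat("Linear mixed model:", x$response,
      "~ diversity + (1 | stage), n =", x$n, "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("AIC (ML) = %.3f   R2m = %.3f   R2c = %.3f\n",
              x$AIC, x$r2_marginal, x$r2_conditional))
  cat(sprintf("variance components: stage %.4g, residual %.4g%s\n",
              x$sigma2_stage, x$sigma2_resid,
              if (x$singular) "  [boundary (singular) fit]" else ""))
  invisible(x)
}

#' Marginal and conditional R-squared for a Gaussian mixed model
#'
#' R2m = var(fixed predictor) / (var(fixed) + sum(random variances) +
#' residual variance); R2c adds the random variances to the numerator.
#'
#' @param fit an `lmerMod` (Gaussian) or `agb_mixed` object.
#' @return list with `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "agb_mixed")) fit <- fit$fit
  fe <- lme4::fixef(fit)
  X <- lme4::getME(fit, "X")
  var_fixed <- var(as.numeric(X %*% fe))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  denom <- var_fixed + var_rand + var_resid
  if (denom <= 0) return(list(r2_marginal = NA_real_,
                              r2_conditional = NA_real_))
  list(r2_marginal = var_fixed / denom,
       r2_conditional = (var_fixed + var_rand) / denom)
}

adj_r2 <- function(y, X) {
  if (length(X) == 0 || ncol(X) == 0) return(0)
  fit <- lm(y ~ ., data = as.data.frame(X))
  if (any(is.na(coef(fit))))
    stop("collinear-to-singular design; offending columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  summary(fit)$adj.r.squared
}

#' Variance partitioning between two predictor sets
#'
#' Adjusted-R2 partition of the variance of `y` explained uniquely by each
#' predictor set and jointly by both: unique1 = adjR2(both) - adjR2(set2),
#' unique2 = adjR2(both) - adjR2(set1), shared = adjR2(set1) + adjR2(set2)
#' - adjR2(both), residual = 1 - adjR2(both). Fractions can be slightly
#' negative (an adjusted-R2 artifact) and are reported unclipped.
#'
#' @param y response vector.
#' @param set1 data frame / matrix of the first predictor set (e.g.
#'   phylogenetic-diversity indicators).
#' @param set2 second predictor set (e.g. phylogenetic-structure
#'   indicators).
#' @return list of class `vpa_result`: `unique1`, `unique2`, `shared`,
#'   `residual`, `adj_r2_full`, plus the same fractions normalized by the
#'   full-model adjusted R2 (`*_of_explained`).
#' @export
variance_partition <- function(y, set1, set2) {
  set1 <- as.data.frame(set1); set2 <- as.data.frame(set2)
  if (length(y) <= ncol(set1) + ncol(set2) + 2)
    stop("too few observations for the partition")
  r_full <- adj_r2(y, cbind(set1, set2))
  r_1 <- adj_r2(y, set1)
  r_2 <- adj_r2(y, set2)
  u1 <- r_full - r_2
  u2 <- r_full - r_1
  sh <- r_1 + r_2 - r_full
  structure(list(unique1 = u1, unique2 = u2, shared = sh,
                 residual = 1 - r_full, adj_r2_full = r_full,
                 unique1_of_explained = if (r_full != 0) u1 / r_full else NA,
                 unique2_of_explained = if (r_full != 0) u2 / r_full else NA,
                 shared_of_explained = if (r_full != 0) sh / r_full else NA),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, clip = FALSE, ...) {
  f <- function(v) if (clip) max(v, 0) else v
  cat("Variance partitioning (adjusted R2 fractions of total variance):\n")
  cat(sprintf("  unique set1 : %.3f\n", f(x$unique1)))
  cat(sprintf("  unique set2 : %.3f\n", f(x$unique2)))
  cat(sprintf("  shared      : %.3f\n", f(x$shared)))
  cat(sprintf("  residual    : %.3f\n", x$residual))
  cat(sprintf("  full-model adjusted R2 = %.3f\n", x$adj_r2_full))
  invisible(x)
}

#' Partial least squares path model
#'
#' PLS-PM over latent blocks (mode A / reflective outer model, path inner
#' weighting scheme). Indicators are z-standardized; outer weights iterate
#' against inner proxies until the maximum absolute weight change is below
#' `tol`. Inner path coefficients are OLS regressions of each endogenous
#' latent score on its predecessors. Communality is the mean squared
#' loading per block and GOF = sqrt(mean communality x mean R2 of the
#' endogenous blocks). Path significance comes from a seeded bootstrap.
#'
#' @param data data frame of indicators.
#' @param blocks named list: latent name -> character vector of indicator
#'   columns.
#' @param paths matrix (latent x latent, lower triangular) with 1 where a
#'   column latent is predicted by a row latent; order defines the causal
#'   ordering.
#' @param n_boot bootstrap resamples for path significance (default 500;
#'   0 disables).
#' @param seed bootstrap seed.
#' @param tol convergence tolerance on outer weights (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @return object of class `plspm_fit`: `path_coefficients` (data frame
#'   from, to, estimate, boot_se, p), `r2` per endogenous block,
#'   `communality` per block, `gof`, `scores`, `loadings`, `iterations`.
#' @export
fit_plspm <- function(data, blocks, paths, n_boot = 500L, seed = 1L,
                      tol = 1e-6, max_iter = 300L) {
  core <- plspm_core(data, blocks, paths, tol, max_iter)
  pc <- core$path_coefficients
  if (n_boot > 0) {
    set.seed(seed)
    n <- nrow(data)
    boots <- matrix(NA_real_, n_boot, nrow(pc))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bc <- tryCatch(plspm_core(data[idx, , drop = FALSE], blocks, paths,
                                tol, max_iter)$path_coefficients$estimate,
                     error = function(e) rep(NA_real_, nrow(pc)))
      boots[b, ] <- bc
    }
    pc$boot_se <- apply(boots, 2, sd, na.rm = TRUE)
    tstat <- pc$estimate / pc$boot_se
    pc$p <- 2 * stats::pt(-abs(tstat), df = nrow(data) - 1)
  } else {
    pc$boot_se <- NA_real_
    pc$p <- NA_real_
  }
  core$path_coefficients <- pc
  core$n_boot <- n_boot
  class(core) <- "plspm_fit"
  core
}

plspm_core <- function(data, blocks, paths, tol = 1e-6, max_iter = 300L) {
  lat <- names(blocks)
  if (is.null(lat) || is.null(rownames(paths)))
    stopifnot(!is.null(lat))
  if (is.null(dimnames(paths))) dimnames(paths) <- list(lat, lat)
  X <- lapply(blocks, function(cols) {
    m <- as.matrix(data[, cols, drop = FALSE])
    scale(m) * sqrt(nrow(m) / (nrow(m) - 1))   # population-sd standardization
  })
  n <- nrow(data)
  # initial outer weights: equal
  W <- lapply(X, function(m) rep(1 / sqrt(ncol(m)), ncol(m)))
  std <- function(v) (v - mean(v)) / (sd(v) * sqrt((n - 1) / n))
  scores <- mapply(function(m, w) std(drop(m %*% w)), X, W, SIMPLIFY = FALSE)
  adjacency <- (paths != 0)
  linked <- adjacency | t(adjacency)
  it <- 0L
  repeat {
    it <- it + 1L
    # inner approximation, path weighting scheme
    inner <- list()
    for (j in seq_along(lat)) {
      z <- rep(0, n)
      preds <- which(adjacency[, j])   # latents pointing into j
      succs <- which(adjacency[j, ])   # latents j points into
      if (length(preds)) {
        Zp <- do.call(cbind, scores[preds])
        b <- tryCatch(solve(crossprod(Zp), crossprod(Zp, scores[[j]])),
                      error = function(e) stop("non-convergence: singular inner regression at iteration ", it))
        z <- z + drop(Zp %*% b)
      }
      if (length(succs))
        for (s in succs) z <- z + stats::cor(scores[[j]], scores[[s]]) * scores[[s]]
      if (!length(preds) && !length(succs))
        stop("latent '", lat[j], "' is isolated in the inner model")
      inner[[j]] <- std(z)
    }
    # outer weights, mode A: correlation of indicators with inner proxy
    W_new <- lapply(seq_along(lat), function(j)
      drop(crossprod(X[[j]], inner[[j]])) / n)
    delta <- max(unlist(mapply(function(a, b) abs(abs(a) - abs(b)),
                               W_new, W, SIMPLIFY = FALSE)))
    W <- W_new
    scores <- mapply(function(m, w) std(drop(m %*% w)), X, W, SIMPLIFY = FALSE)
    converged <- delta < tol
    if (converged || it >= max_iter) break
  }
  if (!converged)
    stop("PLS-PM did not converge in ", max_iter,
         " iterations (last max weight change ", signif(delta, 3), ")")
  names(scores) <- lat
  # sign-align scores with their first indicator
  for (j in seq_along(lat)) {
    r <- stats::cor(scores[[j]], X[[j]][, 1])
    if (r < 0) scores[[j]] <- -scores[[j]]
  }
  loadings <- mapply(function(m, s) drop(crossprod(m, s)) / n, X, scores,
                     SIMPLIFY = FALSE)
  names(loadings) <- lat
  communality <- vapply(loadings, function(l) mean(l^2), numeric(1))
  # inner paths by OLS
  pc <- list(); r2 <- c()
  for (j in seq_along(lat)) {
    preds <- which(adjacency[, j])
    if (!length(preds)) next
    Zp <- do.call(cbind, scores[preds])
    b <- drop(solve(crossprod(Zp), crossprod(Zp, scores[[j]])))
    yhat <- drop(Zp %*% b)
    r2[lat[j]] <- sum(yhat * scores[[j]]) / sum(scores[[j]]^2)
    pc[[length(pc) + 1L]] <- data.frame(from = lat[preds], to = lat[j],
                                        estimate = b)
  }
  pc <- do.call(rbind, pc)
  rownames(pc) <- NULL
  gof <- sqrt(mean(communality) * mean(r2))
  list(path_coefficients = pc, r2 = r2, communality = communality,
       gof = gof, scores = do.call(cbind, scores),
       loadings = loadings, iterations = it, blocks = blocks, paths = paths)
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat("PLS path model (mode A, path scheme),", x$iterations, "iterations\n")
  cat("Inner paths:\n")
  print(x$path_coefficients, row.names = FALSE, digits = 3)
  cat("R2 of endogenous blocks:",
      paste(sprintf("%s = %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  cat(sprintf("GOF = %.3f\n", x$gof))
  invisible(x)
}

#' Goodness of fit from communalities and endogenous R2
#'
#' GOF = sqrt(mean communality x mean R2).
#'
#' @param communality numeric vector of block communalities.
#' @param r2 numeric vector of endogenous-block R2.
#' @return GOF value.
#' @export
plspm_gof <- function(communality, r2) sqrt(mean(communality) * mean(r2))
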