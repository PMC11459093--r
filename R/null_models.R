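# Deterministic per-plot seed stream: hash of (master seed, plot id, level,
# metric) so results do not depend on the order plots are processed in.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "\r")
  h <- as.double(master %% 2147483647L)
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Null distribution of a phylogenetic distance metric
#'
#' Draws `n_reps` communities of `k` distinct species uniformly without
#' replacement from the pool (the whole phylogeny by default) and evaluates
#' MPD or MNTD on each: the richness-preserving "phylogeny pool" null that
#' NRI and NTI are standardized against.
#'
#' @param dist patristic distance matrix.
#' @param k community richness to preserve (>= 2).
#' @param pool character vector of pool species (tip labels).
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_reps number of null replicates (default 999).
#' @param seed integer seed; fixed seed gives a reproducible sample.
#' @return numeric vector of `n_reps` null metric values.
#' @export
null_metric_distribution <- function(dist, k, pool, metric = c("mpd", "mntd"),
                                     n_reps = 999L, seed = NULL) {
  metric <- match.arg(metric)
  pool <- unique(normalize_labels(pool))
  missing <- setdiff(pool, rownames(dist))
  if (length(missing))
    stop("pool species not in distance matrix: ",
         paste(missing, collapse = ", "))
  if (k < 2) stop("k must be >= 2")
  if (k > length(pool))
    stop("k (", k, ") exceeds pool size (", length(pool), ")")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dp <- dist[pool, pool, drop = FALSE]
  n <- length(pool)
  vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n, k)
    d <- dp[idx, idx, drop = FALSE]
    if (metric == "mpd") {
      sum(d) / (k * (k - 1))
    } else {
      diag(d) <- Inf
      mean(apply(d, 1, min))
    }
  }, numeric(1))
}

ses_score <- function(dist, present, pool, metric, n_reps, seed,
                      weights = NULL, sd_tol = 1e-12) {
  present <- unique(normalize_labels(present))
  k <- length(present)
  obs <- if (metric == "mpd") mpd_obs(dist, present, weights)
         else mntd_obs(dist, present, weights)
  if (k < 2) {
    return(data.frame(metric = toupper(metric), observed = NA_real_,
                      null_mean = NA_real_, null_sd = NA_real_,
                      score = NA_real_, n_reps = n_reps,
                      flag = "undefined_k_lt_2"))
  }
  null <- null_metric_distribution(dist, k, pool, metric, n_reps, seed)
  mu <- mean(null)
  s <- sd(null)                      # sample sd, n - 1 denominator
  degenerate <- !is.finite(s) || s < sd_tol
  data.frame(metric = toupper(metric), observed = obs, null_mean = mu,
             null_sd = s,
             score = if (degenerate) NA_real_ else -(obs - mu) / s,
             n_reps = n_reps,
             flag = if (degenerate) "degenerate_null" else "ok")
}

#' Net relatedness index (NRI)
#'
#' NRI = -(MPDobs - mean(MPDnull)) / sd(MPDnull), standardized against the
#' richness-preserving pool null. Positive values indicate phylogenetic
#' aggregation (environmental filtering), negative values dispersion
#' (competitive exclusion), zero a stochastic structure. When the null has
#' (numerically) zero spread the score is flagged undefined, never
#' silently zero.
#'
#' @inheritParams null_metric_distribution
#' @param present character vector of present species.
#' @param weights optional named abundance vector for abundance-weighted MPD.
#' @return one-row data frame: `metric`, `observed`, `null_mean`,
#'   `null_sd`, `score`, `n_reps`, `flag`.
#' @export
nri <- function(dist, present, pool, n_reps = 999L, seed = NULL,
                weights = NULL) {
  ses_score(dist, present, pool, "mpd", n_reps, seed, weights)
}

#' Net nearest taxon index (NTI)
#'
#' As [nri()] with MNTD in place of MPD.
#'
#' @inheritParams nri
#' @return one-row data frame as in [nri()].
#' @export
nti <- function(dist, present, pool, n_reps = 999L, seed = NULL,
                weights = NULL) {
  ses_score(dist, present, pool, "mntd", n_reps, seed, weights)
}

#' Exhaustive null moments for small pools
#'
#' Enumerates every k-subset of the pool and returns the exact mean and
#' (population) standard deviation of MPD or MNTD under uniform draws.
#' Intended for validating the Monte-Carlo null on small problems.
#'
#' @inheritParams null_metric_distribution
#' @param max_subsets guard on choose(|pool|, k) (default 1e5).
#' @return list with `mean`, `sd` (population), and `values`.
#' @export
exhaustive_null_moments <- function(dist, k, pool, metric = c("mpd", "mntd"),
                                    max_subsets = 1e5) {
  metric <- match.arg(metric)
  pool <- unique(normalize_labels(pool))
  if (choose(length(pool), k) > max_subsets)
    stop("too many subsets to enumerate")
  subs <- combn(pool, k, simplify = FALSE)
  vals <- vapply(subs, function(s) {
    if (metric == "mpd") mpd_obs(dist, s) else mntd_obs(dist, s)
  }, numeric(1))
  list(mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       values = vals)
}

#' Standardized phylogenetic structure for every plot
#'
#' Computes NRI and NTI per plot at the requested community levels, using
#' 999 richness-preserving draws from the whole-phylogeny pool by default.
#' The pool is level-specific when `pool_by_level` is TRUE (herb and woody
#' scores drawn from the corresponding life-form subtree pools); otherwise
#' every level is scored against the full pool.
#'
#' @param tree regional phylogeny.
#' @param survey survey data frame (see [validate_survey()]).
#' @param levels community levels, subset of `c("total","herb","woody")`.
#' @param n_reps null replicates per plot (default 999).
#' @param seed master seed; per-plot streams are derived from it by
#'   hashing, so plot order never changes a score.
#' @param pool_by_level use life-form subpools for herb/woody levels.
#' @param null_model `"pool"` (richness-preserving draws from the
#'   phylogeny pool, the default) or `"shuffle"` (tip-label shuffle within
#'   the distance matrix, an alternative null).
#' @return data frame with one row per plot x level x metric.
#' @export
ses_table <- function(tree, survey, levels = c("total", "herb", "woody"),
                      n_reps = 999L, seed = 1L, pool_by_level = TRUE,
                      null_model = c("pool", "shuffle")) {
  null_model <- match.arg(null_model)
  survey <- validate_survey(survey, tree)
  dist <- patristic_distances(tree)
  species_level <- unique(survey[, c("species", "level")])
  out <- list()
  for (lev in levels) {
    sv <- if (lev == "total") survey else survey[survey$level == lev, ]
    pool <- if (lev == "total" || !pool_by_level) tree$tip.label
            else intersect(tree$tip.label,
                           species_level$species[species_level$level == lev])
    for (pid in unique(survey$plot_id)) {
      rows <- sv[sv$plot_id == pid & sv$abundance > 0, ]
      stage <- survey$stage_years[survey$plot_id == pid][1]
      spp <- unique(rows$species)
      for (met in c("mpd", "mntd")) {
        sd_i <- derive_seed(seed, pid, lev, met)
        res <- if (null_model == "pool") {
          ses_score(dist, spp, pool, met, n_reps, sd_i)
        } else {
          shuffle_score(dist, spp, met, n_reps, sd_i)
        }
        res$score_name <- if (met == "mpd") "NRI" else "NTI"
        res$plot_id <- pid
        res$stage_years <- stage
        res$level <- lev
        res$seed <- sd_i
        out[[length(out) + 1L]] <- res
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("plot_id", "stage_years", "level", "metric", "score_name",
          "observed", "null_mean", "null_sd", "score", "n_reps", "seed",
          "flag")]
}

# Alternative null: shuffle tip labels of the distance matrix, keep the
# observed richness and identity structure.
shuffle_score <- function(dist, present, metric, n_reps, seed,
                          sd_tol = 1e-12) {
  present <- unique(normalize_labels(present))
  k <- length(present)
  obs <- if (metric == "mpd") mpd_obs(dist, present)
         else mntd_obs(dist, present)
  if (k < 2)
    return(data.frame(metric = toupper(metric), observed = NA_real_,
                      null_mean = NA_real_, null_sd = NA_real_,
                      score = NA_real_, n_reps = n_reps,
                      flag = "undefined_k_lt_2"))
  set.seed(seed)
  labs <- rownames(dist)
  null <- vapply(seq_len(n_reps), function(i) {
    perm <- setNames(sample(labs), labs)
    s <- perm[present]
    if (metric == "mpd") mpd_obs(dist, s) else mntd_obs(dist, s)
  }, numeric(1))
  mu <- mean(null)
  s <- sd(null)
  degenerate <- !is.finite(s) || s < sd_tol
  data.frame(metric = toupper(metric), observed = obs, null_mean = mu,
             null_sd = s,
             score = if (degenerate) NA_real_ else -(obs - mu) / s,
             n_reps = n_reps,
             flag = if (degenerate) "degenerate_null" else "ok")
}
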