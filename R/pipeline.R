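round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Largest-remainder percentages to 2 decimals: each share is floored to
# cents and the leftover cents go to the largest remainders (ties to the
# larger count), so the group always totals exactly 100.00.
percent_lr <- function(counts) {
  cents <- 10000 * counts / sum(counts)
  base <- floor(cents + 1e-9)
  left <- round(10000 - sum(base))
  if (left > 0) {
    ord <- order(cents - base, counts, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base / 100
}

#' Composition summary of a species checklist
#'
#' Counts species per category and reports percentages to two decimals
#' via largest-remainder allocation (so each category group sums to
#' exactly 100.00), for each requested categorical column present in the
#' checklist (absent columns are skipped with a warning).
#'
#' @param checklist data frame with one row per species and categorical
#'   columns such as `ecological_type` or `life_form`.
#' @param columns category columns to summarize.
#' @return data frame: `variable`, `category`, `count`, `percent`.
#' @export
summarize_composition <- function(checklist,
                                  columns = c("ecological_type",
                                              "life_form")) {
  out <- list()
  for (col in columns) {
    if (!col %in% names(checklist)) {
      warning("category column absent, skipped: ", col)
      next
    }
    tab <- table(checklist[[col]])
    tab <- sort(tab, decreasing = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      variable = col,
      category = names(tab),
      count = as.integer(tab),
      percent = percent_lr(as.integer(tab)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one analysis table per level: diversity metrics + NRI/NTI + AGB per plot
level_model_frame <- function(diversity, ses, agb, level) {
  dv <- diversity[diversity$level == level, ]
  nri_t <- ses[ses$level == level & ses$score_name == "NRI",
               c("plot_id", "score")]
  names(nri_t)[2] <- "NRI"
  nti_t <- ses[ses$level == level & ses$score_name == "NTI",
               c("plot_id", "score")]
  names(nti_t)[2] <- "NTI"
  d <- merge(dv, nri_t, by = "plot_id")
  d <- merge(d, nti_t, by = "plot_id")
  merge(d, agb[, c("plot_id", "total_agb")], by = "plot_id")
}

#' Run the full chronosequence analysis
#'
#' End-to-end pipeline: per-plot phylogenetic diversity, NRI/NTI against
#' 999-draw pool nulls, plot AGB, polynomial trends over recovery time,
#' one-way ANOVA with Duncan letters, mixed models of AGB on the five
#' diversity predictors per level, variance partitioning (diversity vs
#' structure sets) and a PLS path model at the woody level.
#'
#' @param study a `chrono_study` from [simulate_study()], or a list with
#'   `tree`, `survey`, `stems`, `harvest`, `registry` (e.g. from
#'   [read_study()]).
#' @param levels community levels to analyze.
#' @param n_reps null-model replicates (default 999).
#' @param seed master seed for all stochastic stages.
#' @param n_boot PLS-PM bootstrap resamples (default 500).
#' @param transform_agb transform AGB toward normality before the mixed
#'   models (default TRUE).
#' @param tvr_agb_path include a direct recovery-time -> AGB inner path in
#'   the PLS-PM (default FALSE).
#' @param out_dir optional directory: writes all result tables as CSV plus
#'   a JSON run manifest.
#' @return list of class `chrono_run`: `diversity`, `ses`, `agb`,
#'   `model_frames`, `trends`, `group_tests`, `mixed_models` (+
#'   `mixed_table`, the AIC/R2m/R2c/t-value summary), `vpa`, `plspm`,
#'   `manifest`.
#' @export
run_study <- function(study, levels = c("total", "herb", "woody"),
                      n_reps = 999L, seed = 1L, n_boot = 500L,
                      transform_agb = TRUE, tvr_agb_path = FALSE,
                      out_dir = NULL) {
  tree <- validate_phylogeny(study$tree)
  survey <- validate_survey(study$survey, tree)
  diversity <- diversity_table(tree, survey, levels)
  ses <- ses_table(tree, survey, levels, n_reps = n_reps, seed = seed)
  agb <- agb_table(survey, study$stems, study$harvest, study$registry)

  frames <- lapply(levels, function(lv)
    level_model_frame(diversity, ses, agb, lv))
  names(frames) <- levels

  trends <- list()
  for (lv in levels)
    for (v in c("PD", "PSR", "PSE")) {
      d <- frames[[lv]]
      ok <- is.finite(d[[v]])
      if (sum(ok) >= 4)
        trends[[paste(lv, v, sep = ".")]] <-
          fit_trend(d$stage_years[ok], d[[v]][ok],
                    response = paste(lv, v))
    }
  trends[["AGB"]] <- fit_trend(agb$stage_years, agb$total_agb,
                               response = "total AGB")

  group_tests <- list()
  group_tests[["AGB"]] <- duncan_letters(agb$total_agb,
                                         factor(agb$stage_years))
  for (lv in levels)
    for (v in c("NRI", "NTI")) {
      d <- frames[[lv]]
      ok <- is.finite(d[[v]])
      if (length(unique(d$stage_years[ok])) >= 2 &&
          all(table(d$stage_years[ok]) >= 2))
        group_tests[[paste(lv, v, sep = ".")]] <-
          duncan_letters(d[[v]][ok], factor(d$stage_years[ok]))
    }

  mixed <- list(); mixed_rows <- list()
  for (lv in levels) {
    d <- frames[[lv]]
    d <- d[complete.cases(d[, c("PD", "PSR", "PSE", "NRI", "NTI",
                                "total_agb")]), ]
    if (nrow(d) < 10 || length(unique(d$stage_years)) < 2) {
      warning("level ", lv, ": too few complete plots for the mixed model")
      next
    }
    if (transform_agb) {
      tr <- normalize_transform(d$total_agb)
      d$agb_model <- tr$values
    } else d$agb_model <- d$total_agb
    fm <- fit_mixed(d, response = "agb_model")
    mixed[[lv]] <- fm
    cf <- fm$coefficients
    row <- data.frame(level = lv, AIC = fm$AIC, R2m = fm$r2_marginal,
                      R2c = fm$r2_conditional)
    for (p in c("PD", "PSR", "PSE", "NRI", "NTI"))
      row[[paste0("t_", p)]] <- cf$t[cf$predictor == p]
    mixed_rows[[lv]] <- row
  }
  mixed_table <- if (length(mixed_rows)) do.call(rbind, mixed_rows) else NULL
  if (!is.null(mixed_table)) rownames(mixed_table) <- NULL

  vpa <- NULL; pls <- NULL
  dw <- frames[["woody"]]
  if (!is.null(dw)) {
    dw <- dw[complete.cases(dw[, c("PD", "PSE", "NRI", "total_agb")]), ]
    if (nrow(dw) > 8) {
      y <- if (transform_agb) normalize_transform(dw$total_agb)$values
           else dw$total_agb
      vpa <- variance_partition(y, dw[, c("PD", "PSE")],
                                dw[, "NRI", drop = FALSE])
      pdat <- data.frame(tvr = dw$stage_years, PD = dw$PD, PSE = dw$PSE,
                         NRI = dw$NRI, agb = y)
      lat <- c("TVR", "WPD", "WPS", "AGB")
      paths <- matrix(0, 4, 4, dimnames = list(lat, lat))
      paths["TVR", "WPD"] <- 1
      paths["TVR", "WPS"] <- 1
      paths["WPD", "AGB"] <- 1
      paths["WPS", "AGB"] <- 1
      if (tvr_agb_path) paths["TVR", "AGB"] <- 1
      pls <- fit_plspm(pdat,
                       blocks = list(TVR = "tvr", WPD = c("PD", "PSE"),
                                     WPS = "NRI", AGB = "agb"),
                       paths = paths, n_boot = n_boot,
                       seed = derive_seed(seed, "plspm"))
    }
  }

  manifest <- list(
    seed = seed, n_reps = n_reps, n_boot = n_boot, levels = levels,
    n_plots = length(unique(survey$plot_id)),
    n_species = length(unique(survey$species)),
    package_version = as.character(utils::packageVersion("chronophylo")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))

  run <- structure(list(diversity = diversity, ses = ses, agb = agb,
                        model_frames = frames, trends = trends,
                        group_tests = group_tests, mixed_models = mixed,
                        mixed_table = mixed_table, vpa = vpa, plspm = pls,
                        manifest = manifest),
                   class = "chrono_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.chrono_run <- function(x, ...) {
  m <- x$manifest
  cat("Chronosequence analysis run:", m$n_plots, "plots,",
      m$n_species, "species; null reps =", m$n_reps,
      "; seed =", m$seed, "\n")
  if (!is.null(x$mixed_table)) {
    cat("\nMixed-model summary (AIC, R2m, R2c, t-values):\n")
    print(x$mixed_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$vpa)) {
    cat("\n"); print(x$vpa)
  }
  if (!is.null(x$plspm)) {
    cat("\n"); print(x$plspm)
  }
  invisible(x)
}

#' Write run outputs as CSV + JSON manifest
#'
#' @param run a `chrono_run`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(run$diversity, file.path(dir, "diversity.csv"),
            row.names = FALSE)
  write.csv(run$ses, file.path(dir, "ses.csv"), row.names = FALSE)
  write.csv(run$agb, file.path(dir, "agb.csv"), row.names = FALSE)
  if (!is.null(run$mixed_table))
    write.csv(run$mixed_table, file.path(dir, "mixed_models.csv"),
              row.names = FALSE)
  trend_tab <- do.call(rbind, lapply(names(run$trends), function(nm) {
    tf <- run$trends[[nm]]
    data.frame(response = nm,
               intercept = tf$coefficients[1],
               linear = tf$coefficients[2],
               quadratic = if (length(tf$coefficients) > 2)
                 tf$coefficients[3] else NA_real_,
               r_squared = tf$r_squared, p = tf$p_overall,
               peak_tvr = tf$peak_tvr)
  }))
  write.csv(trend_tab, file.path(dir, "trends.csv"), row.names = FALSE)
  letters_tab <- do.call(rbind, lapply(names(run$group_tests), function(nm) {
    gt <- run$group_tests[[nm]]
    cbind(variable = nm, gt$table, F = gt$F, p = gt$p)
  }))
  write.csv(letters_tab, file.path(dir, "group_letters.csv"),
            row.names = FALSE)
  if (!is.null(run$vpa))
    write.csv(data.frame(fraction = c("unique_diversity",
                                      "unique_structure", "shared",
                                      "residual"),
                         value = c(run$vpa$unique1, run$vpa$unique2,
                                   run$vpa$shared, run$vpa$residual)),
              file.path(dir, "vpa.csv"), row.names = FALSE)
  if (!is.null(run$plspm)) {
    write.csv(run$plspm$path_coefficients,
              file.path(dir, "plspm_paths.csv"), row.names = FALSE)
    jsonlite::write_json(list(gof = run$plspm$gof, r2 = as.list(run$plspm$r2),
                              communality = as.list(run$plspm$communality)),
                         file.path(dir, "plspm_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
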