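#' @importFrom stats rlnorm complete.cases
NULL

#' Simulate a regional phylogeny
#'
#' Pure-birth (Yule) ultrametric tree, rescaled to unit root depth, tips
#' labeled `sp001`, `sp002`, ... Stands in for the pruned regional
#' megatree in synthetic studies.
#'
#' @param pool_size number of species (>= 2; default 130).
#' @param seed RNG seed.
#' @param birth speciation rate (default 1; shape only, depth is rescaled).
#' @return ultrametric `"phylo"` object.
#' @export
simulate_phylogeny <- function(pool_size = 130L, seed = 1L, birth = 1) {
  if (pool_size < 2) stop("pool_size must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(pool_size, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(pool_size))
  tr
}

#' Assign Brownian traits and life forms to a phylogeny
#'
#' One continuous niche trait evolves by Brownian motion along the tree
#' (this is what stage-wise environmental filtering acts on); a second,
#' independent Brownian trait is thresholded so that a fixed fraction of
#' species is woody, making life forms clade-clumped as in real floras.
#'
#' @param tree `"phylo"` object.
#' @param brownian_sigma Brownian rate of the niche trait (default 1, so
#'   tip trait SD is about 1 on a unit-depth tree).
#' @param woody_fraction fraction of woody species (default 49/128, the
#'   herb/woody split typical of temperate secondary succession floras).
#' @param seed RNG seed.
#' @return data frame: `species`, `trait`, `life_form`
#'   (`"herb"`/`"woody"`).
#' @export
assign_traits <- function(tree, brownian_sigma = 1, woody_fraction = 49/128,
                          seed = 1L) {
  set.seed(seed)
  niche <- ape::rTraitCont(tree, model = "BM", sigma = brownian_sigma)
  habit <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  n <- length(tree$tip.label)
  n_woody <- round(woody_fraction * n)
  woody <- rank(-habit, ties.method = "first") <= n_woody
  data.frame(species = tree$tip.label, trait = unname(niche),
             life_form = ifelse(woody, "woody", "herb"))
}

#' Default synthetic-study scenario
#'
#' Encodes the study design the generator emulates: 8 recovery stages
#' (0-150 years) x 6 plots, a 130-species pool, herb-dominated early
#' stages and woody-dominated late stages, environmental filtering in the
#' early/middle stages giving way to limiting-similarity competition late,
#' and an AGB trajectory peaking at stage 135 (mixed forest, two
#' codominants) then declining at stage 150 (pure forest, one dominant).
#'
#' @param seed master seed stored in the config.
#' @return named list of schedules and parameters (one entry per stage
#'   where applicable).
#' @export
default_scenario <- function(seed = 1L) {
  list(
    seed = seed,
    pool_size = 130L,
    stages = c(0L, 10L, 20L, 40L, 70L, 120L, 135L, 150L),
    plots_per_stage = 6L,
    plot_area = c(1, 1, 1, 100, 400, 400, 400, 400),
    richness = c(6L, 10L, 18L, 24L, 26L, 20L, 14L, 10L),
    woody_fraction_stage = c(0, 0, 0.1, 0.35, 0.5, 0.6, 0.65, 0.7),
    # Gaussian filter width on the niche trait (tip SD ~ 1): narrow =
    # strong environmental filtering
    filter_sigma = c(0.8, 0.7, 0.5, 0.3, 0.3, 0.35, 1.5, 3),
    # probability scale of limiting-similarity replacements
    competition = c(0, 0, 0, 0, 0, 0.1, 0.5, 0.8),
    # niche optimum as a quantile of the pool's realized trait
    # distribution, drifting toward the upper (late-successional) tail;
    # tail optima select clade-clumped species, so filtering aggregates
    # in the middle stages regardless of the particular simulated tree
    optimum_quantile = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.92, 0.95, 0.97),
    abundance_meanlog = log(15), abundance_sdlog = 1,
    stems_per_plot = c(0, 0, 3, 40, 60, 70, 80, 55),
    mean_dbh = c(NA, NA, 1.5, 3, 10, 18, 22, 24),
    dbh_sdlog = 0.2,
    # two codominant woody species at stage 135, one dominant at 150
    dominance_boost = c(1, 1, 1, 1, 1, 1, 8, 20),
    n_dominants = c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 1L),
    herb_density = c(150, 300, 400, 250, 150, 100, 80, 80),    # g/m2
    litter_density = c(0, 20, 50, 100, 200, 350, 400, 380),    # g/m2
    boxes_per_kind = 3L,
    herb_box_area = 1, litter_box_area = 0.317^2,
    agb_noise_cv = 0.2,
    brownian_sigma = 1, woody_fraction = 49/128,
    # ground-truth inner paths used by simulate_path_data()
    path_coefficients = c(TVR_WPD = 0.6, TVR_WPS = -0.4,
                          WPD_AGB = 0.6, WPS_AGB = -0.3)
  )
}

validate_scenario <- function(config) {
  ns <- length(config$stages)
  sched <- c("plot_area", "richness", "woody_fraction_stage", "filter_sigma",
             "competition", "optimum_quantile", "stems_per_plot", "mean_dbh",
             "dominance_boost", "n_dominants", "herb_density",
             "litter_density")
  for (s in sched)
    if (length(config[[s]]) != ns)
      stop("schedule '", s, "' must have one entry per stage")
  if (config$pool_size < max(config$richness))
    stop("pool_size smaller than maximum richness")
  config
}

#' Assemble one community under filtering and competition
#'
#' Species of each life form are drawn without replacement with weights
#' proportional to exp(-(trait - optimum)^2 / (2 sigma_f^2)) — Gaussian
#' environmental filtering on the Brownian niche trait. Abundances are
#' lognormal (rounded, >= 1). A limiting-similarity competition step then
#' repeatedly (with probability `competition` per candidate pair) removes
#' the less-abundant member of the phylogenetically closest pair and
#' replaces it with a pool species drawn with weight increasing in its
#' distance from the community.
#'
#' @param stage_idx stage index into the config schedules.
#' @param tree regional phylogeny.
#' @param traits trait/life-form table from [assign_traits()].
#' @param config scenario list (see [default_scenario()]).
#' @param seed RNG seed for this community.
#' @return data frame: `species`, `abundance`, `level`.
#' @export
assemble_community <- function(stage_idx, tree, traits, config, seed) {
  set.seed(seed)
  dist <- patristic_distances(tree)
  k_total <- config$richness[stage_idx]
  k_woody <- round(k_total * config$woody_fraction_stage[stage_idx])
  k_herb <- k_total - k_woody
  sig <- config$filter_sigma[stage_idx]
  opt <- unname(stats::quantile(traits$trait,
                                config$optimum_quantile[stage_idx]))
  comp <- config$competition[stage_idx]
  out <- list()
  for (lev in c("herb", "woody")) {
    k <- if (lev == "herb") k_herb else k_woody
    if (k == 0) next
    pool <- traits[traits$life_form == lev, ]
    if (k > nrow(pool)) stop("richness ", k, " exceeds ", lev, " pool")
    w <- exp(-(pool$trait - opt)^2 / (2 * sig^2))
    w <- w / sum(w)
    spp <- sample(pool$species, k, prob = w)
    ab <- pmax(1, round(rlnorm(k, config$abundance_meanlog,
                               config$abundance_sdlog)))
    names(ab) <- spp
    if (comp > 0 && k >= 2) {
      for (round_i in seq_len(k)) {
        if (runif(1) > comp) next
        d <- dist[names(ab), names(ab)]
        diag(d) <- Inf
        ij <- which(d == min(d), arr.ind = TRUE)[1, ]
        pair <- rownames(d)[ij]
        loser <- pair[which.min(ab[pair])]
        cand <- setdiff(pool$species, names(ab))
        if (!length(cand)) break
        # limiting similarity: the replacement maximizes the nearest-
        # neighbor distance to the remaining community
        keepers <- setdiff(names(ab), loser)
        nnd <- apply(dist[cand, keepers, drop = FALSE], 1, min)
        repl <- cand[which.max(nnd)]
        ab_new <- ab[names(ab) != loser]
        ab_new[repl] <- unname(ab[loser])
        ab <- ab_new
      }
    }
    out[[lev]] <- data.frame(species = names(ab), abundance = unname(ab),
                             level = lev)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic chronosequence study
#'
#' Generates every input the analysis pipeline consumes — regional
#' phylogeny, plot surveys, woody stem lists, harvest-box masses and the
#' allometric registry — plus the ground truth needed to score parameter
#' recovery. Deterministic: the same config and seed give byte-identical
#' outputs.
#'
#' @param config scenario list from [default_scenario()].
#' @param seed master seed (overrides `config$seed` when given).
#' @param dir optional directory; when given, writes `tree.nwk`,
#'   `survey.csv`, `stems.csv`, `harvest.csv`, `registry.csv`.
#' @return list of class `chrono_study`: `tree`, `traits`, `survey`,
#'   `stems`, `harvest`, `registry`, `truth`, `config`.
#' @export
simulate_study <- function(config = default_scenario(), seed = NULL,
                           dir = NULL) {
  config <- validate_scenario(config)
  if (!is.null(seed)) config$seed <- seed
  master <- config$seed
  tree <- simulate_phylogeny(config$pool_size, derive_seed(master, "tree"),
                             birth = 1)
  traits <- assign_traits(tree, config$brownian_sigma,
                          config$woody_fraction,
                          derive_seed(master, "traits"))
  registry <- synthetic_registry()
  survey <- list(); stems <- list(); harvest <- list()
  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    for (rep_i in seq_len(config$plots_per_stage)) {
      pid <- sprintf("S%03d_P%d", stage, rep_i)
      comm <- assemble_community(si, tree, traits, config,
                                 derive_seed(master, "comm", stage, rep_i))
      set.seed(derive_seed(master, "plot", stage, rep_i))
      woody <- comm[comm$level == "woody", , drop = FALSE]
      # distribute the stage's stem count over woody species; boost the
      # configured number of dominants (mixed- vs pure-forest contrast)
      if (nrow(woody)) {
        wgt <- rlnorm(nrow(woody), 0, 1)
        nd <- min(config$n_dominants[si], nrow(woody))
        if (nd > 0) {
          top <- order(wgt, decreasing = TRUE)[seq_len(nd)]
          wgt[top] <- wgt[top] * config$dominance_boost[si]
        }
        stems_n <- pmax(1, round(config$stems_per_plot[si] * wgt / sum(wgt)))
        dbh <- lapply(seq_len(nrow(woody)), function(i)
          config$mean_dbh[si] * rlnorm(stems_n[i], -config$dbh_sdlog^2 / 2,
                                       config$dbh_sdlog))
        stems[[length(stems) + 1L]] <- data.frame(
          plot_id = pid,
          species = rep(woody$species, stems_n),
          dbh_cm = unlist(dbh))
        comm$abundance[comm$level == "woody"] <- stems_n
      }
      comm$plot_id <- pid
      comm$stage_years <- stage
      comm$plot_area_m2 <- config$plot_area[si]
      survey[[length(survey) + 1L]] <- comm
      # harvest boxes: herb standing crop and surface litter
      for (kind in c("herb", "litter")) {
        dens <- if (kind == "herb") config$herb_density[si]
                else config$litter_density[si]
        area <- if (kind == "herb") config$herb_box_area
                else config$litter_box_area
        noise <- rlnorm(config$boxes_per_kind, -config$agb_noise_cv^2 / 2,
                        config$agb_noise_cv)
        harvest[[length(harvest) + 1L]] <- data.frame(
          plot_id = pid, kind = kind,
          dry_mass_g = dens * area * noise,
          box_area_m2 = area)
      }
    }
  }
  survey <- do.call(rbind, survey)
  survey <- survey[, c("plot_id", "stage_years", "plot_area_m2", "species",
                       "abundance", "level")]
  rownames(survey) <- NULL
  stems <- if (length(stems)) do.call(rbind, stems) else
    data.frame(plot_id = character(), species = character(),
               dbh_cm = numeric())
  rownames(stems) <- NULL
  harvest <- do.call(rbind, harvest)
  rownames(harvest) <- NULL
  truth <- list(
    optimum_quantile = config$optimum_quantile,
    filter_sigma = config$filter_sigma,
    competition = config$competition,
    assembly_mode = ifelse(config$competition >= 0.5, "competition",
                           ifelse(config$filter_sigma <= 0.5, "filtering",
                                  "weak_filtering")),
    path_coefficients = config$path_coefficients,
    agb_peak_stage = config$stages[which.max(config$stems_per_plot *
      ifelse(is.na(config$mean_dbh), 0, config$mean_dbh)^2.5)])
  study <- structure(list(tree = tree, traits = traits, survey = survey,
                          stems = stems, harvest = harvest,
                          registry = registry, truth = truth,
                          config = config),
                     class = "chrono_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.chrono_study <- function(x, ...) {
  cat("Synthetic chronosequence study:",
      length(unique(x$survey$plot_id)), "plots,",
      length(x$config$stages), "stages,",
      length(x$tree$tip.label), "species pool\n")
  invisible(x)
}

# Placeholder life-form-level allometric coefficients (kg from D in cm);
# the generator and the analysis share this registry, so synthetic AGB is
# internally consistent. Documented as synthetic, not literature values.
synthetic_registry <- function() {
  validate_registry(data.frame(
    taxon = c("woody", "herb"),
    form = c("power_D", "power_D"),
    a = c(0.05, 0.01),
    b = c(2.5, 2.0),
    component = "total",
    source = "synthetic_default"))
}

#' Write a synthetic study to disk
#'
#' @param study a `chrono_study`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write.csv(study$survey, file.path(dir, "survey.csv"), row.names = FALSE)
  write.csv(study$stems, file.path(dir, "stems.csv"), row.names = FALSE)
  write.csv(study$harvest, file.path(dir, "harvest.csv"), row.names = FALSE)
  write.csv(as.data.frame(study$registry), file.path(dir, "registry.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read study inputs from disk
#'
#' @param dir directory holding `tree.nwk`, `survey.csv`, `stems.csv`,
#'   `harvest.csv`, `registry.csv`.
#' @return list with `tree`, `survey`, `stems`, `harvest`, `registry`.
#' @export
read_study <- function(dir) {
  list(tree = read_newick(file.path(dir, "tree.nwk")),
       survey = read.csv(file.path(dir, "survey.csv"),
                         stringsAsFactors = FALSE),
       stems = read.csv(file.path(dir, "stems.csv"),
                        stringsAsFactors = FALSE),
       harvest = read.csv(file.path(dir, "harvest.csv"),
                          stringsAsFactors = FALSE),
       registry = validate_registry(read.csv(file.path(dir, "registry.csv"),
                                             stringsAsFactors = FALSE)))
}

#' Simulate indicator data from a known latent path structure
#'
#' Generates data matching the recovery-time -> diversity -> biomass path
#' diagram with known standardized inner coefficients, for scoring PLS-PM
#' parameter recovery: TVR (single indicator) drives WPD (indicators PD,
#' PSE) and WPS (indicator NRI), which drive AGB.
#'
#' @param n sample size.
#' @param coefs named vector `TVR_WPD`, `TVR_WPS`, `WPD_AGB`, `WPS_AGB`.
#' @param loadings loadings of PD and PSE on the WPD latent (default 0.9).
#' @param seed RNG seed.
#' @return data frame with columns `tvr`, `PD`, `PSE`, `NRI`, `agb`.
#' @export
simulate_path_data <- function(n = 48L,
                               coefs = c(TVR_WPD = 0.6, TVR_WPS = -0.4,
                                         WPD_AGB = 0.6, WPS_AGB = -0.3),
                               loadings = c(0.9, 0.9), seed = 1L) {
  set.seed(seed)
  tvr <- rnorm(n)
  wpd <- coefs["TVR_WPD"] * tvr + rnorm(n, 0, sqrt(1 - coefs["TVR_WPD"]^2))
  wps <- coefs["TVR_WPS"] * tvr + rnorm(n, 0, sqrt(1 - coefs["TVR_WPS"]^2))
  res_var <- max(0.05, 1 - (coefs["WPD_AGB"]^2 + coefs["WPS_AGB"]^2 +
    2 * coefs["WPD_AGB"] * coefs["WPS_AGB"] *
      coefs["TVR_WPD"] * coefs["TVR_WPS"]))
  agb <- coefs["WPD_AGB"] * wpd + coefs["WPS_AGB"] * wps +
    rnorm(n, 0, sqrt(res_var))
  data.frame(tvr = tvr,
             PD = loadings[1] * wpd + rnorm(n, 0, sqrt(1 - loadings[1]^2)),
             PSE = loadings[2] * wpd + rnorm(n, 0, sqrt(1 - loadings[2]^2)),
             NRI = wps,
             agb = agb)
}
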