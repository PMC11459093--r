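#' Areal dry-mass density from harvest boxes
#'
#' Complete-harvest boxes (herbaceous standing crop or surface litter) are
#' converted to g/m2 per box and averaged. The default field design is
#' three boxes per plot per kind: 1 x 1 m for herbs, 31.7 x 31.7 cm
#' (0.100489 m2) for litter.
#'
#' @param samples data frame with columns `plot_id`, `kind`
#'   (`"herb"`/`"litter"`), `dry_mass_g`, `box_area_m2`.
#' @return mean density in g/m2.
#' @export
density_from_boxes <- function(samples) {
  if (nrow(samples) < 1) stop("no harvest samples")
  if (length(unique(samples$kind)) > 1)
    stop("mixed harvest kinds: ", paste(unique(samples$kind), collapse = ", "))
  if (length(unique(samples$plot_id)) > 1)
    stop("samples from several plots")
  if (any(samples$box_area_m2 <= 0)) stop("box area must be > 0")
  if (any(samples$dry_mass_g < 0)) stop("negative dry mass")
  mean(samples$dry_mass_g / samples$box_area_m2)
}

#' Read / validate an allometric-coefficient registry
#'
#' The registry maps taxa (or fallback groups) to the allometric form and
#' coefficients used to predict individual dry biomass (kg) from stem
#' diameter D (cm) and optionally height H (m). Supported forms:
#' `power_D` (B = a D^b), `power_D2H` (B = a (D^2 H)^b) and
#' `log_linear` (B = exp(a + b ln D)). Multi-component models (stem,
#' branch, leaf rows sharing a taxon) are summed.
#'
#' @param path CSV with columns `taxon`, `form`, `a`, `b`, `component`.
#' @return data frame of class `allometry_registry`.
#' @export
read_registry <- function(path) {
  reg <- read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
}

#' @rdname read_registry
#' @param reg a registry data frame.
#' @export
validate_registry <- function(reg) {
  need <- c("taxon", "form", "a", "b")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry missing columns: ", paste(miss, collapse = ", "))
  if (!"component" %in% names(reg)) reg$component <- "total"
  ok <- reg$form %in% c("power_D", "power_D2H", "log_linear")
  if (any(!ok))
    stop("unknown allometric forms: ", paste(unique(reg$form[!ok]), collapse = ", "))
  if (any(!is.finite(reg$a)) || any(!is.finite(reg$b)))
    stop("non-finite allometric coefficients")
  reg$taxon <- normalize_labels(reg$taxon)
  class(reg) <- c("allometry_registry", class(reg))
  reg
}

eval_allometry <- function(form, a, b, D, H) {
  switch(form,
         power_D = a * D^b,
         power_D2H = {
           if (is.null(H) || is.na(H))
             stop("height required for D2H allometric form")
           a * (D^2 * H)^b
         },
         log_linear = exp(a + b * log(D)),
         stop("unknown allometric form: ", form))
}

# species -> genus -> life-form default lookup chain
registry_rows <- function(registry, taxon, level = "woody") {
  taxon <- normalize_labels(taxon)
  rows <- registry[registry$taxon == taxon, , drop = FALSE]
  if (nrow(rows)) return(rows)
  genus <- sub("_.*$", "", taxon)
  rows <- registry[registry$taxon == genus, , drop = FALSE]
  if (nrow(rows)) return(rows)
  rows <- registry[registry$taxon == level, , drop = FALSE]
  if (nrow(rows)) return(rows)
  stop("no allometric model (species, genus or life-form fallback) for taxon: ",
       taxon)
}

#' Individual woody biomass from an allometric model
#'
#' @param registry registry from [read_registry()]/[validate_registry()].
#' @param taxon species name; lookup falls back species -> genus ->
#'   life-form default.
#' @param D stem diameter, cm (> 0).
#' @param H height, m (required only for `power_D2H` forms).
#' @param level life form used for the final fallback (default woody).
#' @return predicted dry biomass, kg per individual (components summed).
#' @export
individual_biomass <- function(registry, taxon, D, H = NA_real_,
                               level = "woody") {
  if (!is.finite(D) || D <= 0) stop("stem diameter must be > 0 (taxon ",
                                    taxon, ")")
  rows <- registry_rows(registry, taxon, level)
  b <- sum(vapply(seq_len(nrow(rows)), function(i)
    eval_allometry(rows$form[i], rows$a[i], rows$b[i], D, H), numeric(1)))
  if (b < 0) stop("negative predicted biomass for taxon ", taxon)
  b
}

#' Plot-level aboveground biomass
#'
#' AGB (g/m2) is the sum of herbaceous biomass, woody biomass and surface
#' litter. Herb and litter densities come from harvest boxes
#' ([density_from_boxes()]); woody density is the sum of individual
#' allometric biomasses (kg) over stems, converted by x1000 / plot area.
#'
#' @param stems data frame of woody individuals for one plot: columns
#'   `species`, `dbh_cm`, optional `height_m`. May have zero rows.
#' @param harvest harvest data frame for one plot: columns `plot_id`,
#'   `kind`, `dry_mass_g`, `box_area_m2`.
#' @param registry allometric registry.
#' @param plot_area_m2 plot area in m2 (> 0).
#' @param plot_id,stage_years identifiers copied into the record.
#' @return one-row data frame: `plot_id`, `stage_years`, `herb_density`,
#'   `woody_density`, `litter_density`, `total_agb` (all g/m2),
#'   `plot_area_m2`.
#' @export
plot_agb <- function(stems, harvest, registry, plot_area_m2,
                     plot_id = NA, stage_years = NA) {
  if (plot_area_m2 <= 0) stop("plot area must be > 0")
  herb <- harvest[harvest$kind == "herb", , drop = FALSE]
  litter <- harvest[harvest$kind == "litter", , drop = FALSE]
  herb_d <- if (nrow(herb)) density_from_boxes(herb) else 0
  litter_d <- if (nrow(litter)) density_from_boxes(litter) else 0
  woody_d <- 0
  if (!is.null(stems) && nrow(stems)) {
    H <- if ("height_m" %in% names(stems)) stems$height_m
         else rep(NA_real_, nrow(stems))
    kg <- vapply(seq_len(nrow(stems)), function(i)
      individual_biomass(registry, stems$species[i], stems$dbh_cm[i], H[i]),
      numeric(1))
    woody_d <- sum(kg) * 1000 / plot_area_m2
  }
  total <- herb_d + woody_d + litter_d
  if (total == 0) warning("plot ", plot_id, ": zero aboveground biomass")
  data.frame(plot_id = plot_id, stage_years = stage_years,
             herb_density = herb_d, woody_density = woody_d,
             litter_density = litter_d, total_agb = total,
             plot_area_m2 = plot_area_m2)
}

#' AGB records for every plot in a study
#'
#' @param survey survey data frame (for plot ids, stages and areas);
#'   must carry a `plot_area_m2` column or `areas` must be supplied.
#' @param stems woody-stem table (`plot_id`, `species`, `dbh_cm`,
#'   optional `height_m`); may be NULL when no woody plants exist.
#' @param harvest harvest table for all plots.
#' @param registry allometric registry.
#' @param areas optional named vector plot_id -> area (m2), overriding the
#'   survey column.
#' @return data frame of per-plot AGB records.
#' @export
agb_table <- function(survey, stems, harvest, registry, areas = NULL) {
  plots <- unique(survey$plot_id)
  out <- vector("list", length(plots))
  for (i in seq_along(plots)) {
    pid <- plots[i]
    area <- if (!is.null(areas)) unname(areas[as.character(pid)])
            else survey$plot_area_m2[survey$plot_id == pid][1]
    if (is.null(area) || is.na(area)) stop("no plot area for plot ", pid)
    st <- if (is.null(stems)) NULL else stems[stems$plot_id == pid, , drop = FALSE]
    hv <- harvest[harvest$plot_id == pid, , drop = FALSE]
    out[[i]] <- plot_agb(st, hv, registry, area, pid,
                         survey$stage_years[survey$plot_id == pid][1])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
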