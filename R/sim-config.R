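# Configuration for the synthetic-data generators. One object carries the
# "true" effects behind all four experimental designs so every downstream
# analysis has a parameter-recovery surface. Defaults emulate a two-species
# contrast between an invasive (ERCI) and a native (ERTE) desert winter
# annual measured across a warm and a cool growing season.

sy_matrix <- function(values, species, years) {
  matrix(values, nrow = 2, byrow = TRUE,
         dimnames = list(species, years))
}

#' Build a simulation configuration
#'
#' Collects the true parameters for the four synthetic experiment designs:
#' diurnal stomatal-conductance measurements, sequential destructive
#' harvests, a neighbour-manipulation competition trial, and a blocked
#' herbivore-exclusion experiment (plus a small leaf-chemistry sample).
#' All per-species-by-year parameters are 2x2 matrices with species codes
#' as rows and year labels as columns.
#'
#' @param seed Integer seed; identical configurations (including the seed)
#'   yield byte-identical generated tables.
#' @param species Length-2 character vector, invasive species first.
#' @param n_individuals Conductance individuals per species.
#' @param times Clock times (h) of porometer measurements.
#' @param dawn,dusk Window endpoints (h); the diurnal curve is zero at both.
#' @param conductance_peak Named per-species peak conductance
#'   (mmol m-2 s-1).
#' @param conductance_peak_time Named per-species clock time (h) of the
#'   conductance peak; must lie strictly inside (dawn, dusk).
#' @param conductance_noise_sd Gaussian noise SD on conductance readings
#'   (mmol m-2 s-1), truncated so readings stay non-negative.
#' @param years Length-2 character vector of year labels (warm, cool).
#' @param rgr_true Species-by-year intrinsic relative growth rate (day-1).
#' @param leaf_frac,root_frac Species-by-year leaf and root fractions of
#'   total dry mass; each in (0, 1) and summing to < 1.
#' @param sla_true Species-by-year specific leaf area (cm2 g-1).
#' @param seed_mass Dry mass (g) at age 0 used as the exponential-growth
#'   intercept.
#' @param mass_noise_cv Coefficient of variation of multiplicative
#'   lognormal noise on total dry mass.
#' @param allocation_noise_cv CV of per-plant lognormal noise on the leaf
#'   and root fractions and on SLA (keeps within-cell variance in the
#'   allocation components); 0 makes every plant carry the exact
#'   configured fractions.
#' @param harvest_ages Strictly increasing plant ages (days) at which
#'   destructive harvests occur.
#' @param n_plots Field plots per year (plots are nested in years; both
#'   species occur in every plot).
#' @param plot_sd Between-plot SD on log total mass.
#' @param n_harvest Plants harvested per species x year x plot x age.
#' @param comp_baseline Response-by-species matrix of expected outcomes for
#'   plants grown alone; rows `seeds`, `total_mass`, `above_mass`,
#'   `root_mass` with `above + root = total`.
#' @param suppression Focal-species-by-neighbour matrix of multiplicative
#'   suppression factors in (0, 1] (columns `conspecific`,
#'   `heterospecific`); 1 means no competition.
#' @param n_alone,n_with Replicate pots per species grown alone / per
#'   focal-x-neighbour combination.
#' @param comp_noise_cv CV of lognormal noise on competition biomass; 0
#'   makes every outcome (seeds included) equal its expectation exactly.
#' @param seed_dispersion Negative-binomial size parameter for seed counts
#'   (larger = less overdispersed).
#' @param n_blocks Blocks in the exclusion experiment; each block holds one
#'   control and one exclusion plot.
#' @param excl_species_mean Response-by-species matrix of plot-level means
#'   (rows `n_individuals`, `mean_fruits`, `mean_mass`).
#' @param excl_treatment_effect,excl_interaction_effect Named per-response
#'   additive shifts for exclusion plots (the interaction applies to the
#'   invasive species in exclusion plots only); both default to zero.
#' @param excl_block_sd,excl_residual_sd Named per-response SDs of the
#'   block random effect and the plot-level residual.
#' @param n_isotope Leaf-chemistry samples per species x year.
#' @param d13c_plant_mean Species-by-year mean leaf delta-13C (per mil).
#' @param d13c_sd,leaf_n_mean,leaf_n_sd Leaf-chemistry noise SD and leaf
#'   nitrogen mean (percent) and SD.
#' @param d13c_air delta-13C of source air (per mil).
#'
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' nrow(gen_conductance(cfg))  # 2 species x 5 individuals x 4 times = 40
sim_config <- function(seed = 1L,
                       species = c("ERCI", "ERTE"),
                       n_individuals = 5L,
                       times = c(8.5, 10.5, 13.5, 16.5),
                       dawn = 6.5,
                       dusk = 18.5,
                       conductance_peak = c(ERCI = 300, ERTE = 475),
                       conductance_peak_time = c(ERCI = 12.5, ERTE = 12.5),
                       conductance_noise_sd = 30,
                       years = c("2004-05", "2007-08"),
                       rgr_true = sy_matrix(c(0.075, 0.090,
                                              0.055, 0.085), species, years),
                       leaf_frac = sy_matrix(c(0.45, 0.42,
                                               0.40, 0.42), species, years),
                       root_frac = sy_matrix(c(0.16, 0.20,
                                               0.11, 0.15), species, years),
                       sla_true = sy_matrix(c(210, 160,
                                              150, 155), species, years),
                       seed_mass = 0.001,
                       mass_noise_cv = 0.2,
                       allocation_noise_cv = 0.1,
                       harvest_ages = c(33, 53, 95, 116),
                       n_plots = 5L,
                       plot_sd = 0.1,
                       n_harvest = 5L,
                       comp_baseline = matrix(
                         c(60, 40,
                           2.0, 1.5,
                           1.65, 1.25,
                           0.35, 0.25),
                         nrow = 4, byrow = TRUE,
                         dimnames = list(c("seeds", "total_mass",
                                           "above_mass", "root_mass"),
                                         species)),
                       suppression = matrix(
                         c(0.50, 0.65,
                           0.60, 0.40),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(species,
                                         c("conspecific", "heterospecific"))),
                       n_alone = 20L,
                       n_with = 20L,
                       comp_noise_cv = 0.25,
                       seed_dispersion = 5,
                       n_blocks = 16L,
                       excl_species_mean = matrix(
                         c(30, 18,
                           12, 7,
                           0.8, 0.55),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(c("n_individuals", "mean_fruits",
                                           "mean_mass"),
                                         species)),
                       excl_treatment_effect = c(n_individuals = 0,
                                                 mean_fruits = 0,
                                                 mean_mass = 0),
                       excl_interaction_effect = c(n_individuals = 0,
                                                   mean_fruits = 0,
                                                   mean_mass = 0),
                       excl_block_sd = c(n_individuals = 3,
                                         mean_fruits = 1.5,
                                         mean_mass = 0.1),
                       excl_residual_sd = c(n_individuals = 6,
                                            mean_fruits = 3,
                                            mean_mass = 0.2),
                       n_isotope = 5L,
                       d13c_plant_mean = sy_matrix(c(-27.6, -27.4,
                                                     -27.8, -27.5),
                                                   species, years),
                       d13c_sd = 0.6,
                       leaf_n_mean = 2.6,
                       leaf_n_sd = 0.55,
                       d13c_air = -8.0) {
  cfg <- list(
    seed = as.integer(seed), species = species,
    n_individuals = as.integer(n_individuals), times = times,
    dawn = dawn, dusk = dusk,
    conductance_peak = conductance_peak,
    conductance_peak_time = conductance_peak_time,
    conductance_noise_sd = conductance_noise_sd,
    years = years, rgr_true = rgr_true,
    leaf_frac = leaf_frac, root_frac = root_frac, sla_true = sla_true,
    seed_mass = seed_mass, mass_noise_cv = mass_noise_cv,
    allocation_noise_cv = allocation_noise_cv,
    harvest_ages = harvest_ages, n_plots = as.integer(n_plots),
    plot_sd = plot_sd, n_harvest = as.integer(n_harvest),
    comp_baseline = comp_baseline, suppression = suppression,
    n_alone = as.integer(n_alone), n_with = as.integer(n_with),
    comp_noise_cv = comp_noise_cv, seed_dispersion = seed_dispersion,
    n_blocks = as.integer(n_blocks),
    excl_species_mean = excl_species_mean,
    excl_treatment_effect = excl_treatment_effect,
    excl_interaction_effect = excl_interaction_effect,
    excl_block_sd = excl_block_sd, excl_residual_sd = excl_residual_sd,
    n_isotope = as.integer(n_isotope),
    d13c_plant_mean = d13c_plant_mean, d13c_sd = d13c_sd,
    leaf_n_mean = leaf_n_mean, leaf_n_sd = leaf_n_sd,
    d13c_air = d13c_air
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$species) == 2L, !anyDuplicated(cfg$species),
            length(cfg$years) == 2L)
  if (cfg$n_individuals < 1L || cfg$n_plots < 1L || cfg$n_harvest < 1L ||
      cfg$n_alone < 1L || cfg$n_with < 1L || cfg$n_blocks < 1L ||
      cfg$n_isotope < 1L)
    stop("all counts must be >= 1")
  if (!(cfg$dawn < cfg$dusk))
    stop("dawn must precede dusk")
  if (any(cfg$times <= cfg$dawn | cfg$times >= cfg$dusk))
    stop("measurement times must lie strictly inside the dawn-dusk window")
  pt <- cfg$conductance_peak_time[cfg$species]
  if (anyNA(pt) || any(pt <= cfg$dawn | pt >= cfg$dusk))
    stop("conductance peak time outside the dawn-dusk window")
  if (anyNA(cfg$conductance_peak[cfg$species]) ||
      any(cfg$conductance_peak < 0))
    stop("conductance peaks must be named, non-negative values per species")
  sds <- c(cfg$conductance_noise_sd, cfg$mass_noise_cv,
           cfg$allocation_noise_cv, cfg$plot_sd,
           cfg$comp_noise_cv, cfg$excl_block_sd, cfg$excl_residual_sd,
           cfg$d13c_sd, cfg$leaf_n_sd)
  if (any(sds < 0)) stop("sd/cv parameters must be >= 0")
  for (m in list(cfg$rgr_true, cfg$leaf_frac, cfg$root_frac, cfg$sla_true,
                 cfg$d13c_plant_mean)) {
    if (!identical(dim(m), c(2L, 2L)) ||
        !identical(rownames(m), cfg$species) ||
        !identical(colnames(m), cfg$years))
      stop("species-by-year parameters must be 2x2 matrices with species ",
           "rows and year columns")
  }
  if (any(cfg$leaf_frac <= 0 | cfg$leaf_frac >= 1) ||
      any(cfg$root_frac <= 0 | cfg$root_frac >= 1))
    stop("allocation fractions must lie in (0, 1)")
  if (any(cfg$leaf_frac + cfg$root_frac >= 1))
    stop("leaf and root fractions must sum to < 1")
  if (length(cfg$harvest_ages) == 0L || any(cfg$harvest_ages <= 0) ||
      is.unsorted(cfg$harvest_ages, strictly = TRUE))
    stop("harvest ages must be positive and strictly increasing")
  if (cfg$seed_mass <= 0) stop("seed_mass must be positive")
  if (any(cfg$suppression <= 0 | cfg$suppression > 1))
    stop("suppression factors must lie in (0, 1]")
  if (!identical(rownames(cfg$suppression), cfg$species) ||
      !identical(colnames(cfg$suppression),
                 c("conspecific", "heterospecific")))
    stop("suppression must have species rows and ",
         "conspecific/heterospecific columns")
  cb <- cfg$comp_baseline
  if (!identical(rownames(cb),
                 c("seeds", "total_mass", "above_mass", "root_mass")) ||
      any(cb <= 0))
    stop("comp_baseline must be positive with rows seeds/total_mass/",
         "above_mass/root_mass")
  if (any(abs(cb["above_mass", ] + cb["root_mass", ] -
              cb["total_mass", ]) > 1e-8))
    stop("comp_baseline above_mass + root_mass must equal total_mass")
  resp <- c("n_individuals", "mean_fruits", "mean_mass")
  for (v in list(cfg$excl_treatment_effect, cfg$excl_interaction_effect,
                 cfg$excl_block_sd, cfg$excl_residual_sd)) {
    if (!all(resp %in% names(v)))
      stop("exclusion effect/sd vectors must be named by response")
  }
  if (!identical(rownames(cfg$excl_species_mean), resp) ||
      any(cfg$excl_species_mean < 0))
    stop("excl_species_mean must be non-negative with response rows")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "),
      " | years: ", paste(x$years, collapse = ", "), "\n", sep = "")
  cat("  conductance: ", x$n_individuals, "/species at ",
      paste(x$times, collapse = ", "), " h; peaks ",
      paste(x$conductance_peak, collapse = "/"), "\n", sep = "")
  cat("  harvests: ages ", paste(x$harvest_ages, collapse = ", "),
      " d; ", x$n_plots, " plots/year; cv ", x$mass_noise_cv, "\n", sep = "")
  cat("  competition: ", x$n_alone, " alone + ", x$n_with,
      "/combination; exclusion: ", x$n_blocks, " blocks\n", sep = "")
  invisible(x)
}

# ---- YAML interchange -------------------------------------------------

serialize_value <- function(x) {
  if (is.matrix(x)) {
    list(`.matrix` = TRUE, data = as.vector(x), dimnames = dimnames(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # YAML keeps names only for maps, not sequences
  } else x
}

deserialize_value <- function(x) {
  if (is.list(x) && isTRUE(x$`.matrix`)) {
    matrix(unlist(x$data), nrow = length(x$dimnames[[1]]),
           dimnames = lapply(x$dimnames, unlist))
  } else if (is.list(x) && !is.null(names(x))) {
    unlist(x)  # named vectors round-trip through YAML as named lists
  } else if (is.list(x)) {
    unlist(x)
  } else x
}

#' Read a simulation configuration from YAML
#'
#' The file may specify any subset of [sim_config()] arguments; omitted
#' fields take their defaults. Species-by-year matrices are written as
#' `{.matrix: true, data: [...], dimnames: [[...], [...]]}` (the format
#' emitted into the provenance sidecar by [write_datasets()]).
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$config)) raw <- raw$config  # accept a provenance sidecar
  args <- lapply(raw, deserialize_value)
  keep <- intersect(names(args), names(formals(sim_config)))
  do.call(sim_config, args[keep])
}

#' Generate and write all synthetic datasets for one configuration
#'
#' Writes the conductance, harvest, competition, exclusion and
#' leaf-chemistry CSVs plus a `provenance.yaml` sidecar recording the seed
#' and the full configuration. Column units are documented in `#` comment
#' lines at the top of each CSV; read them back with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_datasets <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- list(
    conductance = "# clock_time: h since midnight; g_s: mmol m-2 s-1",
    harvests = "# age: days since germination; masses: g dry; leaf_area: cm2",
    competition = "# seeds: count; masses: g dry",
    exclusion = "# n_individuals: count/plot; mean_fruits: count; mean_mass: g",
    isotopes = "# d13c_plant, delta: per mil; leaf_n: percent dry mass"
  )
  tables <- list(
    conductance = gen_conductance(config),
    harvests = gen_harvests(config),
    competition = gen_competition(config),
    exclusion = gen_exclusion(config),
    isotopes = gen_isotopes(config)
  )
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(units[[nm]], con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  prov <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(
    list(seed = config$seed,
         generator = "invasiontraits::write_datasets",
         config = lapply(unclass(config), serialize_value)),
    prov)
  invisible(c(paths, prov))
}
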