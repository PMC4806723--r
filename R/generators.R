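# Seed-reproducible generators for the four experimental designs (plus the
# small leaf-chemistry sample). Each generator seeds its own stream from
# config$seed plus a fixed offset, so the tables are independent of the
# order in which they are generated, and identical configurations yield
# byte-identical tables. Setting every noise/random-effect parameter to 0
# makes every generated value equal to its stated expectation.

# Smooth unimodal diurnal template: 0 at dawn and dusk, 1 at the peak time.
# Two quarter-sine arcs joined at the peak; downstream code only consumes
# sampled points, so any unimodal shape would serve.
diurnal_bump <- function(t, dawn, dusk, peak) {
  out <- ifelse(t <= peak,
                sin(pi / 2 * (t - dawn) / (peak - dawn)),
                sin(pi / 2 * (dusk - t) / (dusk - peak)))
  out[t <= dawn | t >= dusk] <- 0
  out
}

# Lognormal log-scale sd for a target coefficient of variation.
sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Generate instantaneous stomatal-conductance observations
#'
#' One porometer reading per individual per measurement time, drawn around
#' a unimodal diurnal curve (species-specific peak height and peak time)
#' with Gaussian noise truncated at zero.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `individual_id`, `species`,
#'   `clock_time` (h) and `g_s` (mmol m-2 s-1).
#' @export
gen_conductance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  rows <- expand.grid(clock_time = config$times,
                      ind = seq_len(config$n_individuals),
                      species = config$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- config$conductance_peak[rows$species] *
    diurnal_bump(rows$clock_time, config$dawn, config$dusk,
                 config$conductance_peak_time[rows$species])
  g <- pmax(0, mu + stats::rnorm(nrow(rows), 0, config$conductance_noise_sd))
  data.frame(
    individual_id = sprintf("%s_%02d", rows$species, rows$ind),
    species = rows$species,
    clock_time = rows$clock_time,
    g_s = unname(g),
    stringsAsFactors = FALSE
  )
}

#' Generate sequential destructive-harvest records
#'
#' Total dry mass grows exponentially with age at the configured intrinsic
#' relative growth rate for each species-by-year cell, with multiplicative
#' lognormal individual noise (`mass_noise_cv`) and a shared plot-level
#' random effect (`plot_sd`, log scale; plots are nested within years and
#' contain both species). Leaf and root masses are fixed fractions of
#' total; leaf area is SLA times leaf mass; shoot mass is total minus root.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per harvested plant: `plant_id`,
#'   `species`, `year`, `plot`, `age` (days), `total_mass`, `leaf_mass`,
#'   `root_mass`, `shoot_mass` (g dry) and `leaf_area` (cm2).
#' @export
gen_harvests <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  sdlog <- sdlog_from_cv(config$mass_noise_cv)
  plot_ids <- outer(config$years, seq_len(config$n_plots),
                    function(y, p) paste0(y, "_p", p))
  rownames(plot_ids) <- config$years
  plot_eff <- matrix(stats::rnorm(length(plot_ids), 0, config$plot_sd),
                     nrow = nrow(plot_ids), dimnames = dimnames(plot_ids))
  rows <- expand.grid(rep = seq_len(config$n_harvest),
                      age = config$harvest_ages,
                      plot = seq_len(config$n_plots),
                      species = config$species,
                      year = config$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(rows$species, rows$year)
  yi <- match(rows$year, config$years)
  log_total <- log(config$seed_mass) +
    config$rgr_true[idx] * rows$age +
    plot_eff[cbind(yi, rows$plot)] +
    stats::rnorm(nrow(rows), 0, sdlog)
  total <- exp(log_total)
  # Per-plant allocation noise keeps within-cell variance in SLA/LMR/RMR
  # (and hence a non-degenerate ln(mass/area) trajectory); 0 recovers the
  # exact configured fractions. Fractions are rescaled in the rare draw
  # where leaf + root would reach 1.
  if (config$allocation_noise_cv > 0) {
    asd <- sdlog_from_cv(config$allocation_noise_cv)
    lf <- config$leaf_frac[idx] * stats::rlnorm(nrow(rows), 0, asd)
    rf <- config$root_frac[idx] * stats::rlnorm(nrow(rows), 0, asd)
    over <- lf + rf >= 0.98
    scl <- ifelse(over, 0.98 / (lf + rf), 1)
    lf <- lf * scl
    rf <- rf * scl
    sla <- config$sla_true[idx] * stats::rlnorm(nrow(rows), 0, asd)
  } else {
    lf <- config$leaf_frac[idx]
    rf <- config$root_frac[idx]
    sla <- config$sla_true[idx]
  }
  leaf <- lf * total
  root <- rf * total
  data.frame(
    plant_id = sprintf("h_%04d", seq_len(nrow(rows))),
    species = rows$species,
    year = rows$year,
    plot = plot_ids[cbind(yi, rows$plot)],
    age = rows$age,
    total_mass = total,
    leaf_mass = leaf,
    root_mass = root,
    shoot_mass = total - root,
    leaf_area = sla * leaf,
    stringsAsFactors = FALSE
  )
}

#' Generate competition-pot outcomes
#'
#' The six planting combinations: each species grown alone, with four
#' conspecific neighbours, or with four heterospecific neighbours. The
#' expected outcome of a focal plant is its species baseline times the
#' suppression factor for its neighbour identity (1 for plants grown
#' alone). Above-ground and root mass get multiplicative lognormal noise
#' (total is their sum); seed counts are negative-binomial around the
#' expected mean. With `comp_noise_cv = 0` every response, seeds included,
#' equals its expectation exactly (noiseless calibration mode).
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `pot_id`, `focal_species`,
#'   `neighbor_identity` (`none`/`conspecific`/`heterospecific`), `seeds`,
#'   `total_mass`, `above_mass`, `root_mass`.
#' @export
gen_competition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  blocks <- list()
  for (sp in config$species) {
    for (nb in c("none", "conspecific", "heterospecific")) {
      n <- if (nb == "none") config$n_alone else config$n_with
      blocks[[length(blocks) + 1L]] <- data.frame(
        focal_species = sp, neighbor_identity = nb,
        rep = seq_len(n), stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, blocks)
  supp <- rep(1, nrow(rows))
  nb <- rows$neighbor_identity != "none"
  supp[nb] <- config$suppression[cbind(rows$focal_species[nb],
                                       rows$neighbor_identity[nb])]
  mu_above <- config$comp_baseline["above_mass", rows$focal_species] * supp
  mu_root <- config$comp_baseline["root_mass", rows$focal_species] * supp
  mu_seeds <- config$comp_baseline["seeds", rows$focal_species] * supp
  n <- nrow(rows)
  if (config$comp_noise_cv == 0) {
    above <- mu_above
    root <- mu_root
    seeds <- mu_seeds
  } else {
    sdlog <- sdlog_from_cv(config$comp_noise_cv)
    above <- stats::rlnorm(n, log(mu_above), sdlog)
    root <- stats::rlnorm(n, log(mu_root), sdlog)
    seeds <- stats::rnbinom(n, mu = mu_seeds, size = config$seed_dispersion)
  }
  data.frame(
    pot_id = sprintf("pot_%03d", seq_len(n)),
    focal_species = rows$focal_species,
    neighbor_identity = rows$neighbor_identity,
    seeds = unname(seeds),
    total_mass = unname(above + root),
    above_mass = unname(above),
    root_mass = unname(root),
    stringsAsFactors = FALSE
  )
}

#' Generate herbivore-exclusion plot summaries
#'
#' Each block contains one control and one exclusion plot; each plot
#' contributes one summary row per species. Every response is species mean
#' + treatment effect (exclusion plots) + species-by-treatment interaction
#' (invasive species in exclusion plots) + a block random effect + residual
#' noise. Individual counts are rounded to non-negative integers; means are
#' truncated at zero.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `block`, `plot`, `treatment`
#'   (`control`/`exclusion`), `species`, `n_individuals`, `mean_fruits`,
#'   `mean_mass`.
#' @export
gen_exclusion <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  resp <- rownames(config$excl_species_mean)
  block_eff <- sapply(resp, function(r)
    stats::rnorm(config$n_blocks, 0, config$excl_block_sd[r]))
  if (is.null(dim(block_eff))) block_eff <- t(block_eff)  # n_blocks == 1
  rows <- expand.grid(species = config$species,
                      treatment = c("control", "exclusion"),
                      block = seq_len(config$n_blocks),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  invasive <- config$species[1]
  vals <- sapply(resp, function(r) {
    config$excl_species_mean[r, rows$species] +
      config$excl_treatment_effect[r] * (rows$treatment == "exclusion") +
      config$excl_interaction_effect[r] *
        (rows$treatment == "exclusion" & rows$species == invasive) +
      block_eff[rows$block, r] +
      stats::rnorm(nrow(rows), 0, config$excl_residual_sd[r])
  })
  data.frame(
    block = sprintf("b%02d", rows$block),
    plot = sprintf("b%02d_%s", rows$block, substr(rows$treatment, 1, 4)),
    treatment = rows$treatment,
    species = rows$species,
    n_individuals = pmax(0L, as.integer(round(vals[, "n_individuals"]))),
    mean_fruits = pmax(0, unname(vals[, "mean_fruits"])),
    mean_mass = pmax(0, unname(vals[, "mean_mass"])),
    stringsAsFactors = FALSE
  )
}

#' Generate leaf-chemistry (isotope and nitrogen) samples
#'
#' `n_isotope` leaf samples per species x year; leaf delta-13C is Gaussian
#' around the configured cell mean and converted to discrimination with
#' [delta_from_d13c()]; leaf nitrogen is Gaussian truncated at zero.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `sample_id`, `species`, `year`,
#'   `d13c_plant`, `d13c_air`, `delta` (per mil) and `leaf_n` (percent).
#' @export
gen_isotopes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 505L)
  rows <- expand.grid(rep = seq_len(config$n_isotope),
                      species = config$species,
                      year = config$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d13c <- config$d13c_plant_mean[cbind(rows$species, rows$year)] +
    stats::rnorm(nrow(rows), 0, config$d13c_sd)
  leaf_n <- pmax(0, config$leaf_n_mean +
                   stats::rnorm(nrow(rows), 0, config$leaf_n_sd))
  data.frame(
    sample_id = sprintf("iso_%03d", seq_len(nrow(rows))),
    species = rows$species,
    year = rows$year,
    d13c_plant = unname(d13c),
    d13c_air = config$d13c_air,
    delta = delta_from_d13c(unname(d13c), config$d13c_air),
    leaf_n = unname(leaf_n),
    stringsAsFactors = FALSE
  )
}
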