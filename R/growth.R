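# Sequential-harvest growth analysis: allocation components per harvested
# plant, group-wise growth rates from log-linear regression, the
# mid-season relative change in LAR, carbon isotope discrimination, and
# the ANCOVA/ANOVA battery over species x year with plot as the random
# blocking factor.

#' Allocation components for each harvest record
#'
#' Adds SLA (leaf area / leaf mass, cm2 g-1), LAR (leaf area / total mass,
#' cm2 g-1), LMR (leaf mass / total mass), RMR (root mass / total mass)
#' and root:shoot (root mass / shoot mass) to each record. The identity
#' `LAR = SLA * LMR` holds by construction. Records with a non-positive
#' denominator are flagged (`flagged = TRUE`, affected components `NA`)
#' rather than silently producing NaN.
#'
#' @param records Harvest data frame with columns `total_mass`,
#'   `leaf_mass`, `root_mass`, `shoot_mass` (g dry) and `leaf_area` (cm2).
#' @return `records` with columns `SLA`, `LAR`, `LMR`, `RMR`, `root_shoot`
#'   and `flagged` appended.
#' @export
#' @examples
#' rec <- data.frame(total_mass = 2, leaf_mass = 1, root_mass = 0.5,
#'                   shoot_mass = 1.5, leaf_area = 200)
#' compute_components(rec)  # SLA 200, LAR 100, LMR 0.5, RMR 0.25, r:s 1/3
compute_components <- function(records) {
  rec <- as.data.frame(records)
  need <- c("total_mass", "leaf_mass", "root_mass", "shoot_mass",
            "leaf_area")
  if (!all(need %in% names(rec)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(rec[need] < 0, na.rm = TRUE))
    stop("masses and areas must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  rec$SLA <- safe_div(rec$leaf_area, rec$leaf_mass)
  rec$LAR <- safe_div(rec$leaf_area, rec$total_mass)
  rec$LMR <- safe_div(rec$leaf_mass, rec$total_mass)
  rec$RMR <- safe_div(rec$root_mass, rec$total_mass)
  rec$root_shoot <- safe_div(rec$root_mass, rec$shoot_mass)
  rec$flagged <- rec$leaf_mass <= 0 | rec$total_mass <= 0 |
    rec$shoot_mass <= 0
  if (any(rec$flagged))
    warning(sum(rec$flagged),
            " record(s) flagged: zero denominator in a component")
  rec
}

#' Growth rates per group from log-linear regression across harvests
#'
#' For each group (by default species x year) fits three ordinary
#' least-squares regressions against plant age: ln(total mass) (slope =
#' RGR, day-1), ln(total mass / leaf area) (slope = NAR on this
#' operational log-slope definition) and ln(leaf area) (slope = leaf-area
#' growth rate). Because ln W = ln(W/A) + ln A and least squares is
#' linear, RGR = NAR slope + leaf-area slope exactly on any shared set of
#' plants.
#'
#' @param records Harvest data frame with `total_mass`, `leaf_area`, `age`
#'   and the grouping columns.
#' @param groups Character vector of grouping columns.
#' @return A data frame with one row per group: slopes `rgr`, `nar_slope`,
#'   `lar_rgr` (day-1), their standard errors, and `n`.
#' @export
fit_growth_rates <- function(records, groups = c("species", "year")) {
  rec <- as.data.frame(records)
  need <- c("total_mass", "leaf_area", "age", groups)
  if (!all(need %in% names(rec)))
    stop("records must have columns ", paste(need, collapse = ", "))
  key <- interaction(rec[groups], drop = TRUE, sep = "\r")
  out <- lapply(split(rec, key), function(sub) {
    if (length(unique(sub$age)) < 2L)
      stop("a group has a single harvest age; slope is undefined")
    if (any(sub$total_mass <= 0) || any(sub$leaf_area <= 0))
      stop("non-positive mass or leaf area; cannot log-transform")
    slope_se <- function(y) {
      cf <- summary(stats::lm(y ~ sub$age))$coefficients
      cf["sub$age", c("Estimate", "Std. Error")]
    }
    a <- slope_se(log(sub$total_mass))
    b <- slope_se(log(sub$total_mass / sub$leaf_area))
    d <- slope_se(log(sub$leaf_area))
    cbind(sub[1L, groups, drop = FALSE],
          data.frame(rgr = a[1], rgr_se = a[2],
                     nar_slope = b[1], nar_se = b[2],
                     lar_rgr = d[1], lar_rgr_se = d[2],
                     n = nrow(sub)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative change in leaf area ratio between two ages
#'
#' `(late - early) / early`: positive when plants shift allocation toward
#' leaf display between the two anchor ages, negative when LAR declines.
#'
#' @param mean_lar_early,mean_lar_late Mean LAR at the early and late
#'   anchor age; the early mean must be positive.
#' @return A dimensionless value in `(-1, Inf)`.
#' @export
relative_change_lar <- function(mean_lar_early, mean_lar_late) {
  if (any(mean_lar_early <= 0))
    stop("early LAR mean must be positive")
  (mean_lar_late - mean_lar_early) / mean_lar_early
}

#' Relative change in LAR per species x year from harvest records
#'
#' Computes mean LAR at the two anchor ages (default 53 and 95 days after
#' germination) within each species-by-year cell and applies
#' [relative_change_lar()].
#'
#' @param records Harvest data frame.
#' @param early_age,late_age Anchor ages (days) that must both appear in
#'   `records` for every cell.
#' @return A data frame with columns `species`, `year`, `lar_early`,
#'   `lar_late` and `lar_change`.
#' @export
lar_change_table <- function(records, early_age = 53, late_age = 95) {
  rec <- compute_components(records)
  cells <- unique(rec[c("species", "year")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- rec[rec$species == cells$species[i] & rec$year == cells$year[i], ]
    early <- sub$LAR[sub$age == early_age]
    late <- sub$LAR[sub$age == late_age]
    if (length(early) == 0L || length(late) == 0L)
      stop("no records at an anchor age for ", cells$species[i], " / ",
           cells$year[i])
    data.frame(cells[i, ], lar_early = mean(early), lar_late = mean(late),
               lar_change = relative_change_lar(mean(early), mean(late)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Carbon isotope discrimination from delta-13C values
#'
#' `Delta = (d_air - d_plant) / (1 + d_plant / 1000)`, with both deltas on
#' the per-mil scale; strictly decreasing in `d_plant` and zero when plant
#' and air match.
#'
#' @param d_plant Leaf tissue delta-13C (per mil).
#' @param d_air Source-air delta-13C (per mil); -8 is the standard
#'   atmospheric value.
#' @return Discrimination Delta, per mil.
#' @export
#' @examples
#' delta_from_d13c(-28, -8)  # 20 / 0.972 = 20.576
delta_from_d13c <- function(d_plant, d_air = -8.0) {
  if (any(1 + d_plant / 1000 == 0))
    stop("d_plant = -1000 per mil is outside the domain")
  (d_air - d_plant) / (1 + d_plant / 1000)
}

#' Invert the discrimination formula
#'
#' Recovers leaf delta-13C from a discrimination value and the air value;
#' exact inverse of [delta_from_d13c()].
#'
#' @param delta Discrimination (per mil).
#' @param d_air Source-air delta-13C (per mil).
#' @return Leaf delta-13C, per mil.
#' @export
d13c_from_delta <- function(delta, d_air = -8.0) {
  (d_air - delta) / (1 + delta / 1000)
}

#' Mixed-model ANCOVA of relative growth rate
#'
#' ln(total mass) against plant age (covariate), species, year and their
#' interaction, with the field plot as the random blocking factor. The
#' species-by-year term is the test of differential growth across growing
#' seasons. Plots are nested in years, so the year main effect is tested
#' in the plot stratum.
#'
#' @param records Harvest data frame.
#' @param method,ss_type Passed to the ANOVA engine (see [fit_anova()]).
#' @return An `anova_table`.
#' @export
rgr_ancova <- function(records, method = c("strata", "reml"),
                       ss_type = "II") {
  fit_ancova(records,
             model_spec("total_mass", covariates = "age",
                        factors = c("species", "year"), random = "plot",
                        transform = "log", ss_type = ss_type),
             method = match.arg(method))
}

#' Mixed-model ANCOVA of net assimilation rate
#'
#' Same structure as [rgr_ancova()] with ln(total mass / leaf area) as the
#' response (the log-slope operational definition of NAR).
#'
#' @inheritParams rgr_ancova
#' @return An `anova_table`.
#' @export
nar_ancova <- function(records, method = c("strata", "reml"),
                       ss_type = "II") {
  rec <- as.data.frame(records)
  rec$mass_per_area <- rec$total_mass / rec$leaf_area
  fit_ancova(rec,
             model_spec("mass_per_area", covariates = "age",
                        factors = c("species", "year"), random = "plot",
                        transform = "log", ss_type = ss_type),
             method = match.arg(method))
}

#' Mixed-model ANOVA of a mid-season allocation component
#'
#' Restricts the harvests to one age (default 95 days after germination,
#' just prior to reproduction), computes the requested component, and fits
#' ln(component) ~ species * year with plot random.
#'
#' @param records Harvest data frame.
#' @param component One of `"SLA"`, `"LAR"`, `"root_shoot"`, `"LMR"`,
#'   `"RMR"`.
#' @param age Mid-season anchor age (days).
#' @inheritParams rgr_ancova
#' @return An `anova_table`.
#' @export
midseason_anova <- function(records,
                            component = c("SLA", "LAR", "root_shoot",
                                          "LMR", "RMR"),
                            age = 95, method = c("strata", "reml"),
                            ss_type = "II") {
  component <- match.arg(component)
  rec <- as.data.frame(records)
  sub <- rec[rec$age == age, ]
  cells <- table(sub$species, sub$year)
  if (length(cells) < 4L || any(cells == 0L))
    stop("no records at age ", age, " for some species x year cell")
  sub <- compute_components(sub)
  fit_anova(sub,
            model_spec(component, factors = c("species", "year"),
                       random = "plot", transform = "log",
                       ss_type = ss_type),
            method = match.arg(method))
}

#' Fixed-effects two-way ANOVA of leaf chemistry
#'
#' Leaf nitrogen or carbon isotope discrimination against species, year
#' and their interaction; no random factor (one laboratory batch), so the
#' error df is N - 4 for a complete two-by-two design.
#'
#' @param isotope_records Data frame from [gen_isotopes()] or with columns
#'   `species`, `year` and the response.
#' @param response `"leaf_n"` or `"delta"`.
#' @param ss_type Sums-of-squares type.
#' @return An `anova_table`.
#' @export
leafchem_anova <- function(isotope_records, response = c("leaf_n", "delta"),
                           ss_type = "II") {
  response <- match.arg(response)
  rec <- as.data.frame(isotope_records)
  cells <- table(rec$species, rec$year)
  if (length(cells) < 4L || any(cells < 2L))
    stop("need at least 2 records per species x year cell")
  fit_anova(rec,
            model_spec(response, factors = c("species", "year"),
                       ss_type = ss_type))
}
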