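# Allocation components, log-linear growth rates, LAR change, isotope
# discrimination and the ANCOVA/ANOVA battery.

test_that("components follow their definitions on a worked record", {
  rec <- data.frame(total_mass = 2, leaf_mass = 1, root_mass = 0.5,
                    shoot_mass = 1.5, leaf_area = 200)
  out <- compute_components(rec)
  expect_equal(out$SLA, 200)
  expect_equal(out$LAR, 100)
  expect_equal(out$LMR, 0.5)
  expect_equal(out$RMR, 0.25)
  expect_equal(out$root_shoot, 1 / 3)
  expect_false(out$flagged)
})

test_that("component identities hold record-wise on random records", {
  set.seed(15)
  n <- 500
  rec <- data.frame(total_mass = runif(n, 0.1, 10))
  rec$leaf_mass <- rec$total_mass * runif(n, 0.1, 0.6)
  rec$root_mass <- rec$total_mass * runif(n, 0.05, 0.35)
  rec$shoot_mass <- rec$total_mass - rec$root_mass
  rec$leaf_area <- rec$leaf_mass * runif(n, 50, 400)
  out <- compute_components(rec)
  expect_equal(out$LAR, out$SLA * out$LMR, tolerance = 1e-12)
  expect_equal(out$RMR + out$shoot_mass / out$total_mass,
               rep(1, n), tolerance = 1e-12)
  expect_true(all(out$LMR >= 0 & out$LMR <= 1))
  expect_true(all(out$RMR >= 0 & out$RMR <= 1))
})

test_that("zero denominators are flagged, not silent NaN", {
  rec <- data.frame(total_mass = c(2, 0), leaf_mass = c(1, 0),
                    root_mass = c(0.5, 0), shoot_mass = c(1.5, 0),
                    leaf_area = c(200, 0))
  expect_warning(out <- compute_components(rec), "flagged")
  expect_true(out$flagged[2])
  expect_true(is.na(out$SLA[2]))
  expect_false(anyNA(out[1, c("SLA", "LAR", "LMR", "RMR", "root_shoot")]))
  neg <- rec[1, ]; neg$leaf_mass <- -1
  expect_error(compute_components(neg), "non-negative")
})

test_that("growth-rate slopes reproduce an exact line", {
  rec <- data.frame(species = "s", year = "y",
                    age = c(0, 10, 20),
                    total_mass = exp(c(0, 1, 2)),
                    leaf_area = exp(c(0, 1, 2)))
  fit <- suppressWarnings(fit_growth_rates(rec))
  expect_equal(fit$rgr, 0.1, tolerance = 1e-12)
  expect_equal(fit$lar_rgr, 0.1, tolerance = 1e-12)
  expect_equal(fit$nar_slope, 0, tolerance = 1e-12)
})

test_that("noiseless generator growth is recovered exactly", {
  cfg <- sim_config(seed = 6, mass_noise_cv = 0, plot_sd = 0,
                    allocation_noise_cv = 0,
                    rgr_true = sy_mat(0.1))
  fit <- suppressWarnings(fit_growth_rates(gen_harvests(cfg)))
  expect_equal(fit$rgr, rep(0.1, 4), tolerance = 1e-12)
  # constant LAR: leaf area tracks mass, so the NAR slope is zero and the
  # leaf-area slope carries the whole growth rate
  expect_equal(fit$nar_slope, rep(0, 4), tolerance = 1e-12)
  expect_equal(fit$lar_rgr, rep(0.1, 4), tolerance = 1e-12)
})

test_that("slopes match the closed-form centred least-squares formula", {
  set.seed(25)
  rec <- data.frame(species = "s", year = "y",
                    age = rep(c(20, 50, 80, 110), each = 6))
  rec$total_mass <- exp(0.002 + 0.07 * rec$age + rnorm(24, sd = 0.3))
  rec$leaf_area <- rec$total_mass * exp(rnorm(24, sd = 0.2)) * 100
  fit <- fit_growth_rates(rec)
  x <- rec$age - mean(rec$age)
  slope <- function(y) sum(x * (y - mean(y))) / sum(x^2)
  expect_equal(fit$rgr, slope(log(rec$total_mass)), tolerance = 1e-12)
  expect_equal(fit$nar_slope, slope(log(rec$total_mass / rec$leaf_area)),
               tolerance = 1e-12)
})

test_that("slope additivity RGR = NAR + leaf-area slope is exact", {
  for (s in c(7, 8)) {
    fit <- fit_growth_rates(gen_harvests(sim_config(seed = s)))
    expect_equal(fit$rgr, fit$nar_slope + fit$lar_rgr, tolerance = 1e-10)
  }
})

test_that("growth-rate fitting rejects degenerate groups", {
  one_age <- data.frame(species = "s", year = "y", age = 50,
                        total_mass = c(1, 2), leaf_area = c(10, 20))
  expect_error(fit_growth_rates(one_age), "single harvest age")
  bad_mass <- data.frame(species = "s", year = "y", age = c(10, 20),
                         total_mass = c(0, 2), leaf_area = c(10, 20))
  expect_error(fit_growth_rates(bad_mass), "log")
})

test_that("relative change in LAR is definitional", {
  expect_equal(relative_change_lar(100, 150), 0.5)
  expect_equal(relative_change_lar(100, 100), 0)
  expect_equal(relative_change_lar(100, 60), -0.4)
  expect_error(relative_change_lar(0, 50), "positive")
  tab <- lar_change_table(gen_harvests(sim_config(seed = 9)))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$lar_change,
               (tab$lar_late - tab$lar_early) / tab$lar_early)
})

test_that("isotope discrimination follows the ratio formula", {
  expect_equal(delta_from_d13c(-8, -8), 0)
  expect_equal(delta_from_d13c(-28, -8), 20 / 0.972)
  grid <- seq(-35, -5, by = 0.5)
  d <- delta_from_d13c(grid, -8)
  expect_true(all(diff(d) < 0))  # strictly decreasing in d_plant
  expect_equal(d13c_from_delta(d, -8), grid, tolerance = 1e-12)
  expect_error(delta_from_d13c(-1000), "domain")
})

test_that("the RGR ANCOVA has the published term structure", {
  h <- gen_harvests(sim_config(seed = 10))
  tab <- rgr_ancova(h)
  for (trm in c("age", "species", "year", "species:year"))
    expect_true(trm %in% tab$term)
  expect_equal(tab$df[tab$term == "age"], 1)
  expect_identical(tab$stratum[tab$term == "year"], "block")
  expect_identical(tab$stratum[tab$term == "species:year"], "within")
  nar <- nar_ancova(h)
  expect_true(all(c("age", "species:year") %in% nar$term))
})

test_that("a true species-by-year growth crossover is detected", {
  cfg <- sim_config(seed = 11,
                    rgr_true = matrix(c(0.08, 0.12, 0.12, 0.08), 2,
                                      byrow = TRUE,
                                      dimnames = list(c("ERCI", "ERTE"),
                                                      c("2004-05",
                                                        "2007-08"))))
  tab <- rgr_ancova(gen_harvests(cfg))
  expect_lt(tab$p[tab$term == "species:year"], 1e-6)
})

test_that("mid-season ANOVAs use the log scale and detect SLA offsets", {
  cfg <- sim_config(seed = 12)
  h <- gen_harvests(cfg)
  tab <- midseason_anova(h, "SLA", age = 95)
  # oracle: same engine fed manually logged mid-season values
  sub <- compute_components(h[h$age == 95, ])
  sub$lnSLA <- log(sub$SLA)
  ref <- fit_anova(sub, model_spec("lnSLA", factors = c("species", "year"),
                                   random = "plot"))
  expect_equal(tab$F[tab$term == "species"],
               ref$F[ref$term == "species"], tolerance = 1e-12)
  raw <- fit_anova(sub, model_spec("SLA", factors = c("species", "year"),
                                   random = "plot"))
  expect_false(isTRUE(all.equal(tab$F[tab$term == "species"],
                                raw$F[raw$term == "species"])))
  # default config has a species SLA offset in the warm year
  expect_lt(tab$p[tab$term == "species:year"], 0.05)
  expect_error(midseason_anova(h, "SLA", age = 77), "no records")
})

test_that("leaf-chemistry ANOVA matches the complete-design df", {
  iso <- gen_isotopes(sim_config(seed = 13))  # 5 per species x year
  tab <- leafchem_anova(iso, "leaf_n")
  expect_equal(tab$df[tab$term == "Residuals"], 16)
  expect_equal(tab$den_df[tab$term == "species"], 16)
  d <- leafchem_anova(iso, "delta")
  expect_equal(d$df[d$term == "Residuals"], 16)
  few <- iso[iso$sample_id != "iso_001", ]
  few <- few[!(few$species == "ERCI" & few$year == "2004-05"), ]
  expect_error(leafchem_anova(few, "leaf_n"), "2 records")
})

test_that("leaf-chemistry ANOVA agrees with hand sums of squares (n=2)", {
  iso <- data.frame(species = rep(c("ERCI", "ERTE"), each = 4),
                    year = rep(c("y1", "y1", "y2", "y2"), 2),
                    leaf_n = c(2.1, 2.3, 2.6, 2.4, 1.9, 2.0, 2.2, 2.5))
  tab <- leafchem_anova(iso, "leaf_n")
  orc <- balanced_twoway_oracle(iso, "species", "year", "leaf_n")
  expect_equal(tab$F[match(c("species", "year", "species:year"), tab$term)],
               unname(orc$f), tolerance = 1e-10)
})
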