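# Relative interaction intensity (RII) for the neighbour-manipulation
# competition experiment. RII = (Bw - B0) / (Bw + B0), where Bw is a focal
# plant's performance with neighbours and B0 the mean performance of its
# species grown alone; bounded in [-1, 1], negative under competition,
# positive under facilitation.

COMP_RESPONSES <- c("seeds", "total_mass", "above_mass", "root_mass")

#' Mean performance of alone-grown plants per species and response
#'
#' The species-level baseline used as the denominator reference in RII.
#'
#' @param records Competition data frame with `focal_species`,
#'   `neighbor_identity` and the response columns.
#' @param responses Response columns to average.
#' @return Long data frame: `species`, `response`, `baseline` (the alone
#'   mean) and `n_alone`. A species represented by a single alone-grown
#'   plant triggers a warning (its "mean" is one observation).
#' @export
baseline_means <- function(records, responses = COMP_RESPONSES) {
  rec <- as.data.frame(records)
  alone <- rec[rec$neighbor_identity == "none", ]
  species <- unique(rec$focal_species)
  missing <- setdiff(species, alone$focal_species)
  if (length(missing))
    stop("no alone-grown plants for species: ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(species, function(sp) {
    sub <- alone[alone$focal_species == sp, ]
    if (nrow(sub) == 1L)
      warning("species ", sp, " has a single alone-grown plant")
    data.frame(species = sp, response = responses,
               baseline = vapply(responses, function(r) mean(sub[[r]]),
                                 numeric(1)),
               n_alone = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Relative interaction intensity
#'
#' `(b_with - b_alone_mean) / (b_with + b_alone_mean)`: 0 when performance
#' with neighbours equals the alone mean, -1 when the focal plant produced
#' nothing, bounded in `[-1, 1]` for non-negative performance.
#'
#' @param b_with Performance of a focal plant grown with neighbours
#'   (vectorised, must be >= 0).
#' @param b_alone_mean Mean performance of its species grown alone
#'   (must be > 0).
#' @return RII, dimensionless in `[-1, 1]`.
#' @export
#' @examples
#' rii(3, 1)    # 0.5
#' rii(0.5, 1)  # -1/3
rii <- function(b_with, b_alone_mean) {
  if (any(b_with < 0)) stop("performance with neighbours must be >= 0")
  if (any(b_alone_mean <= 0)) stop("alone-grown mean must be positive")
  (b_with - b_alone_mean) / (b_with + b_alone_mean)
}

#' RII for every focal plant and response
#'
#' One RII value per focal plant grown with neighbours per response
#' (alone-grown plants define the baselines and are excluded from the
#' output). Zero-performing focal plants are retained with RII = -1 by
#' default; `drop_zero = TRUE` removes them.
#'
#' @param records Competition data frame.
#' @param responses Response columns.
#' @param drop_zero Drop rows where the focal plant's performance is zero.
#' @return Long data frame: `pot_id`, `focal_species`, `neighbor_identity`
#'   (conspecific/heterospecific), `competitor` (the neighbour's species
#'   identity, used as the ANOVA factor), `response`, `rii`.
#' @export
rii_table <- function(records, responses = COMP_RESPONSES,
                      drop_zero = FALSE) {
  rec <- as.data.frame(records)
  base <- baseline_means(rec, responses)
  with_nb <- rec[rec$neighbor_identity != "none", ]
  species <- unique(rec$focal_species)
  if (length(species) != 2L) stop("exactly two species are required")
  other <- stats::setNames(rev(species), species)
  competitor <- ifelse(with_nb$neighbor_identity == "conspecific",
                       with_nb$focal_species,
                       other[with_nb$focal_species])
  out <- do.call(rbind, lapply(responses, function(r) {
    b0 <- base$baseline[base$response == r]
    names(b0) <- base$species[base$response == r]
    data.frame(pot_id = with_nb$pot_id,
               focal_species = with_nb$focal_species,
               neighbor_identity = with_nb$neighbor_identity,
               competitor = unname(competitor),
               response = r,
               rii = rii(with_nb[[r]], b0[with_nb$focal_species]),
               stringsAsFactors = FALSE)
  }))
  if (drop_zero) out <- out[out$rii > -1, ]
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA of RII for one response
#'
#' Fixed-effects ANOVA of RII against focal species, competitor species
#' identity and their interaction, preceded by an overall model row (all
#' fixed df pooled against the residual). Competitor identity (which
#' species the neighbours were), not conspecific/heterospecific status, is
#' the factor: "neighbours of the invader suppress everyone harder" is a
#' competitor main effect in this coding. Per-individual RII values within
#' a species share the alone-grown baseline, so they are not strictly
#' independent; the ANOVA treats them as independent, as is conventional
#' for this index.
#'
#' @param rii_values Output of [rii_table()].
#' @param response Which response's RII values to analyse.
#' @param ss_type Sums-of-squares type.
#' @return An `anova_table` whose first row is the overall model test.
#' @export
rii_anova <- function(rii_values, response = "total_mass",
                      ss_type = "II") {
  sub <- rii_values[rii_values$response == response, ]
  if (nrow(sub) == 0L) stop("no RII values for response ", response)
  cells <- table(sub$focal_species, sub$competitor)
  if (length(cells) < 4L || any(cells == 0L))
    stop("empty focal-species x competitor cell")
  spec <- model_spec("rii", factors = c("focal_species", "competitor"),
                     ss_type = ss_type)
  tab <- fit_anova(sub, spec)
  res <- tab[tab$term == "Residuals", ]
  fixed <- tab[tab$term != "Residuals", ]
  model_df <- sum(fixed$df)
  model_ss <- sum((sub$rii - mean(sub$rii))^2) - res$sumsq
  model_f <- (model_ss / model_df) / res$meansq
  model_row <- data.frame(
    term = "Model", df = model_df, den_df = res$df,
    sumsq = model_ss, meansq = model_ss / model_df, F = model_f,
    p = stats::pf(model_f, model_df, res$df, lower.tail = FALSE),
    stratum = "within", stringsAsFactors = FALSE)
  out <- rbind(model_row, as.data.frame(tab))
  attrs <- attributes(tab)
  structure(out, class = c("anova_table", "data.frame"),
            response = paste0("RII(", response, ")"),
            transform = attrs$transform, ss_type = attrs$ss_type,
            random = NULL, method = attrs$method)
}

#' Mean RII with standard errors by focal species and competitor
#'
#' The summary behind the usual RII figure: means and SEM per focal
#' species x competitor identity x response.
#'
#' @param rii_values Output of [rii_table()].
#' @return Data frame with `focal_species`, `competitor`,
#'   `neighbor_identity`, `response`, `mean_rii`, `sem` and `n`.
#' @export
rii_summary <- function(rii_values) {
  key <- interaction(rii_values$focal_species,
                     rii_values$competitor,
                     rii_values$response, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(rii_values, key), function(sub) {
    data.frame(focal_species = sub$focal_species[1],
               competitor = sub$competitor[1],
               neighbor_identity = sub$neighbor_identity[1],
               response = sub$response[1],
               mean_rii = mean(sub$rii),
               sem = stats::sd(sub$rii) / sqrt(nrow(sub)),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$response, out$focal_species, out$competitor), ]
  rownames(out) <- NULL
  out
}
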