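# Herbivore-exclusion factorial analysis and the enemy release hypothesis
# (ERH) verdict. The ERH predicts that the invader gains more from enemy
# presence removal than the native does, which in a species x treatment
# factorial is a species-by-treatment interaction.

EXCL_RESPONSES <- c("n_individuals", "mean_fruits", "mean_mass")

#' Mixed-model ANOVA of one exclusion-experiment response
#'
#' Plot-level response against species, treatment and their interaction,
#' with block as the random factor. Both fixed factors vary within blocks
#' (each block holds a control and an exclusion plot, each with both
#' species), so every fixed term is tested against the residual after the
#' block mean square absorbs its degrees of freedom.
#'
#' @param records Exclusion data frame ([gen_exclusion()] schema).
#' @param response One of `"n_individuals"`, `"mean_fruits"`,
#'   `"mean_mass"`.
#' @param transform `"none"` (default, matching conventional analysis of
#'   plot summaries) or `"log"`.
#' @param method,ss_type Passed to [fit_anova()].
#' @return An `anova_table`.
#' @export
exclusion_anova <- function(records, response = EXCL_RESPONSES,
                            transform = c("none", "log"),
                            method = c("strata", "reml"),
                            ss_type = "II") {
  response <- match.arg(response)
  rec <- as.data.frame(records)
  if (length(unique(rec$species)) < 2L ||
      length(unique(rec$treatment)) < 2L)
    stop("both species and both treatments must be present")
  if (length(unique(rec$block)) < 2L) stop("need at least two blocks")
  fit_anova(rec,
            model_spec(response, factors = c("species", "treatment"),
                       random = "block", transform = match.arg(transform),
                       ss_type = ss_type),
            method = match.arg(method))
}

#' Enemy-release verdict from exclusion ANOVA tables
#'
#' Extracts the species-by-treatment interaction row from each table and
#' declares enemy release supported when the interaction is significant at
#' `alpha` for at least one response (`rule = "any"`, default) or for all
#' responses (`rule = "all"`).
#'
#' @param anova_tables A single `anova_table` or a (preferably named) list
#'   of them, each containing a `species:treatment` term.
#' @param alpha Significance level for the interaction test.
#' @param rule `"any"` or `"all"`.
#' @return An `erh_result` list: `erh_supported`, `interaction` (the
#'   extracted rows with a `response` column), `alpha`, `rule`.
#' @export
erh_test <- function(anova_tables, alpha = 0.05, rule = c("any", "all")) {
  rule <- match.arg(rule)
  stopifnot(alpha >= 0, alpha <= 1)
  if (inherits(anova_tables, "anova_table"))
    anova_tables <- list(anova_tables)
  if (is.null(names(anova_tables)))
    names(anova_tables) <- paste0("response_", seq_along(anova_tables))
  rows <- lapply(names(anova_tables), function(nm) {
    tab <- anova_tables[[nm]]
    hit <- tab$term %in% c("species:treatment", "treatment:species")
    if (!any(hit))
      stop("table '", nm, "' has no species-by-treatment interaction term")
    cbind(response = nm, as.data.frame(tab)[hit, , drop = FALSE])
  })
  inter <- do.call(rbind, rows)
  rownames(inter) <- NULL
  sig <- inter$p < alpha
  structure(
    list(erh_supported = if (rule == "any") any(sig) else all(sig),
         interaction = inter, alpha = alpha, rule = rule),
    class = "erh_result")
}

#' @export
print.erh_result <- function(x, ...) {
  cat("Enemy release hypothesis test (species x treatment interaction)\n")
  cat("  rule: significant at alpha =", x$alpha, "for",
      if (x$rule == "any") "at least one response" else "all responses",
      "\n")
  show <- x$interaction[c("response", "df", "den_df", "F", "p")]
  show[-1] <- lapply(show[-1], function(v) signif(v, 4))
  print(show, row.names = FALSE)
  cat("  ERH supported:", x$erh_supported, "\n")
  invisible(x)
}

#' Means and standard errors by species and treatment
#'
#' The summary behind the usual exclusion-experiment figure: mean and SEM
#' of each response per species x treatment cell.
#'
#' @param records Exclusion data frame.
#' @param responses Response columns to summarise.
#' @return Data frame with `species`, `treatment`, `response`, `mean`,
#'   `sem`, `n`.
#' @export
exclusion_summary <- function(records, responses = EXCL_RESPONSES) {
  rec <- as.data.frame(records)
  cells <- unique(rec[c("species", "treatment")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- rec[rec$species == cells$species[i] &
                 rec$treatment == cells$treatment[i], ]
    do.call(rbind, lapply(responses, function(r) {
      data.frame(species = cells$species[i],
                 treatment = cells$treatment[i], response = r,
                 mean = mean(sub[[r]]),
                 sem = stats::sd(sub[[r]]) / sqrt(nrow(sub)),
                 n = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$response, out$species, out$treatment), ]
  rownames(out) <- NULL
  out
}
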