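# Shared least-squares engine: fixed-effects factorial ANOVA/ANCOVA and a
# one-random-blocking-factor mixed ANOVA, returning uniform term tables.
#
# Fixed-effects tables use Type-II sums of squares by default (car::Anova).
# A single random blocking factor is handled classically by error strata:
# fixed terms that are constant within levels of the blocking factor
# ("between-block" terms, e.g. year when field plots are nested in years)
# are tested against the block-stratum mean square; all other terms against
# the within-stratum residual. An REML backend (lmerTest, Satterthwaite df)
# is available for users who prefer modern mixed-model denominator df.

#' Describe a linear model for the ANOVA engine
#'
#' @param response Name of the response column.
#' @param covariates Character vector of continuous covariates; covariate
#'   terms are entered (and reported) before the factors.
#' @param factors Character vector of categorical fixed factors.
#' @param interactions `TRUE` for the full factorial among `factors`,
#'   `FALSE` for main effects only, or a character vector of explicit
#'   interaction terms such as `"species:year"`.
#' @param random Optional name of a single random blocking factor (a plot or
#'   block identifier). Must not also appear in `factors`.
#' @param transform `"none"` or `"log"`: natural-log transform of the
#'   response before fitting.
#' @param ss_type Sums-of-squares type for fixed-effects tables: `"II"`
#'   (default, marginal to interactions), `"I"` (sequential) or `"III"`.
#'
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("mean_mass", factors = c("species", "treatment"),
#'            random = "block")
model_spec <- function(response,
                       covariates = character(),
                       factors = character(),
                       interactions = TRUE,
                       random = NULL,
                       transform = c("none", "log"),
                       ss_type = c("II", "I", "III")) {
  transform <- match.arg(transform)
  ss_type <- match.arg(ss_type)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(covariates), is.character(factors))
  if (!is.null(random)) {
    stopifnot(is.character(random), length(random) == 1L)
    if (random %in% factors)
      stop("the random blocking factor must not also be listed as fixed")
  }
  if (is.character(interactions)) {
    parts <- unique(unlist(strsplit(interactions, ":", fixed = TRUE)))
    if (!all(parts %in% factors))
      stop("interactions may only involve listed factors")
  }
  structure(
    list(response = response, covariates = covariates, factors = factors,
         interactions = interactions, random = random,
         transform = transform, ss_type = ss_type),
    class = "model_spec"
  )
}

# Right-hand side of the fixed part of the model formula.
build_fixed_rhs <- function(spec) {
  fac_part <- if (length(spec$factors) == 0L) {
    character()
  } else if (isTRUE(spec$interactions) && length(spec$factors) > 1L) {
    paste(spec$factors, collapse = " * ")
  } else if (is.character(spec$interactions)) {
    paste(c(spec$factors, spec$interactions), collapse = " + ")
  } else {
    paste(spec$factors, collapse = " + ")
  }
  rhs <- paste(c(spec$covariates, fac_part), collapse = " + ")
  if (!nzchar(rhs)) stop("model has no fixed terms")
  rhs
}

# TRUE if every level of the random factor sees a single value of the term's
# factor combination (the term is a between-block contrast).
is_between_term <- function(data, term, spec) {
  tf <- intersect(strsplit(term, ":", fixed = TRUE)[[1]], spec$factors)
  if (length(tf) == 0L) return(FALSE)  # covariate terms are within-block
  cell <- interaction(data[tf], drop = TRUE)
  counts <- tapply(as.character(cell), data[[spec$random]],
                   function(x) length(unique(x)))
  all(counts == 1L)
}

anova_table <- function(rows, spec, method) {
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("anova_table", "data.frame"),
            response = spec$response, transform = spec$transform,
            ss_type = spec$ss_type, random = spec$random, method = method)
}

#' @export
print.anova_table <- function(x, ...) {
  hdr <- attr(x, "response")
  if (identical(attr(x, "transform"), "log")) hdr <- paste0("ln(", hdr, ")")
  cat("Analysis of variance: ", hdr, "\n", sep = "")
  if (!is.null(attr(x, "random")))
    cat("Random blocking factor: ", attr(x, "random"),
        " (", attr(x, "method"), ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, 5))
  print(y, row.names = FALSE)
  invisible(x)
}

# Term SS/df from a fitted lm, honouring the requested SS type.
# Returns list(terms = data.frame(term, df, sumsq), res_df, res_ss).
extract_ss <- function(fit, ss_type, data, fml) {
  if (ss_type == "I") {
    a <- stats::anova(fit)
    terms <- rownames(a)
  } else if (ss_type == "II") {
    a <- car::Anova(fit, type = 2)
    terms <- rownames(a)
  } else {
    # Type III needs sum-to-zero contrasts to be meaningful
    facs <- names(Filter(is.factor, data))
    contr <- stats::setNames(rep(list("contr.sum"), length(facs)), facs)
    fit3 <- stats::lm(fml, data = data, contrasts = contr[facs %in% all.vars(fml)])
    a <- car::Anova(fit3, type = 3)
    a <- a[rownames(a) != "(Intercept)", , drop = FALSE]
    terms <- rownames(a)
  }
  ss_col <- intersect(c("Sum Sq", "Sum of Sq"), colnames(a))[1]
  keep <- terms != "Residuals"
  list(
    terms = data.frame(term = terms[keep],
                       df = a[keep, "Df"],
                       sumsq = a[keep, ss_col],
                       stringsAsFactors = FALSE),
    res_df = a["Residuals", "Df"],
    res_ss = a["Residuals", ss_col]
  )
}

#' Fit an ANOVA or ANCOVA and return a uniform term table
#'
#' Fits the model described by a [model_spec()] and returns one row per
#' term with numerator and denominator degrees of freedom, sum of squares,
#' mean square, F and p. With a random blocking factor, fixed terms that do
#' not vary within blocks are tested against the block-stratum mean square
#' (classical expected-mean-squares ANOVA); everything else is tested
#' against the residual of its stratum. `method = "reml"` instead fits a
#' random intercept by REML through lmerTest and reports Satterthwaite
#' denominator df.
#'
#' @param data A data frame containing every column named in `spec`.
#' @param spec A [model_spec()].
#' @param method `"strata"` (default, classical error-stratum F ratios) or
#'   `"reml"` (requires the lmerTest package). Ignored when `spec` has no
#'   random factor.
#'
#' @return An `anova_table` data frame with columns `term`, `df`, `den_df`,
#'   `sumsq`, `meansq`, `F`, `p` and `stratum`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
#' fit_anova(d, model_spec("y", factors = "g"))
fit_anova <- function(data, spec, method = c("strata", "reml")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  need <- c(spec$response, spec$covariates, spec$factors, spec$random)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need]))
    stop("missing values in model variables")

  y <- data[[spec$response]]
  if (spec$transform == "log") {
    if (any(!is.finite(y) | y <= 0))
      stop("log transform requires strictly positive response values")
    y <- log(y)
  }
  if (stats::var(y) == 0)
    stop("response is constant; nothing to partition")
  data$.y <- y
  for (f in c(spec$factors, spec$random)) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop("factor '", f, "' has fewer than two levels")
  }

  rhs <- build_fixed_rhs(spec)

  if (is.null(spec$random)) {
    return(fit_anova_fixed(data, spec, rhs))
  }
  if (method == "reml") {
    return(fit_anova_reml(data, spec, rhs))
  }
  fixed_terms <- attr(stats::terms(stats::as.formula(paste("~", rhs))),
                      "term.labels")
  between <- vapply(fixed_terms, is_between_term, logical(1),
                    data = data, spec = spec)
  if (any(between)) {
    fit_anova_strata(data, spec, rhs)
  } else {
    fit_anova_block_term(data, spec, rhs)
  }
}

# No random factor: lm + requested SS type, everything against residual.
fit_anova_fixed <- function(data, spec, rhs) {
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased terms in the model")
  if (stats::df.residual(fit) < 1L)
    stop("zero residual degrees of freedom")
  ss <- extract_ss(fit, spec$ss_type, data, fml)
  ms_res <- ss$res_ss / ss$res_df
  tt <- ss$terms
  f <- (tt$sumsq / tt$df) / ms_res
  rows <- data.frame(
    term = c(tt$term, "Residuals"),
    df = c(tt$df, ss$res_df),
    den_df = c(rep(ss$res_df, nrow(tt)), NA),
    sumsq = c(tt$sumsq, ss$res_ss),
    meansq = c(tt$sumsq / tt$df, ms_res),
    F = c(f, NA),
    p = c(stats::pf(f, tt$df, ss$res_df, lower.tail = FALSE), NA),
    stratum = "within",
    stringsAsFactors = FALSE
  )
  anova_table(rows, spec, "fixed")
}

# Random factor varies every fixed term within blocks: enter the block as a
# plain term so it absorbs its df, and test fixed terms against residual.
fit_anova_block_term <- function(data, spec, rhs) {
  fml <- stats::as.formula(paste(".y ~", spec$random, "+", rhs))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("confounded design: a fixed term is aliased with the blocking factor")
  if (stats::df.residual(fit) < 1L)
    stop("zero residual degrees of freedom")
  ss <- extract_ss(fit, spec$ss_type, data, fml)
  ms_res <- ss$res_ss / ss$res_df
  tt <- ss$terms
  is_block <- tt$term == spec$random
  f <- (tt$sumsq / tt$df) / ms_res
  rows <- data.frame(
    term = c(tt$term, "Residuals"),
    df = c(tt$df, ss$res_df),
    den_df = c(rep(ss$res_df, nrow(tt)), NA),
    sumsq = c(tt$sumsq, ss$res_ss),
    meansq = c(tt$sumsq / tt$df, ms_res),
    F = c(f, NA),
    p = c(stats::pf(f, tt$df, ss$res_df, lower.tail = FALSE), NA),
    stratum = c(ifelse(is_block, "block", "within"), "within"),
    stringsAsFactors = FALSE
  )
  anova_table(rows, spec, "strata")
}

# Some fixed terms are between-block contrasts: classical multistratum aov
# with Error(random). Sequential SS within strata (equal to Type II on the
# balanced orthogonal designs this package generates).
fit_anova_strata <- function(data, spec, rhs) {
  if (spec$ss_type == "III")
    warning("Type III is not available for multistratum models; ",
            "using sequential SS within strata")
  fml <- stats::as.formula(paste(".y ~", rhs, "+ Error(", spec$random, ")"))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  rows_list <- lapply(seq_along(sm), function(i) {
    stratum_name <- sub("^\\s*Error:\\s*", "", names(sm)[i])
    tab <- sm[[i]][[1]]
    term <- trimws(rownames(tab))
    res <- term == "Residuals"
    if (!any(res))
      stop("confounded design: stratum '", stratum_name,
           "' has no residual degrees of freedom")
    res_df <- tab[res, "Df"]
    data.frame(
      term = term,
      df = tab[, "Df"],
      den_df = ifelse(res, NA, res_df),
      sumsq = tab[, "Sum Sq"],
      meansq = tab[, "Mean Sq"],
      F = ifelse(res, NA, tab[, "Mean Sq"] / tab[res, "Mean Sq"]),
      p = ifelse(res, NA,
                 stats::pf(tab[, "Mean Sq"] / tab[res, "Mean Sq"],
                           tab[, "Df"], res_df, lower.tail = FALSE)),
      stratum = if (identical(stratum_name, "Within")) "within" else "block",
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows_list)
  rows$term[rows$term == "Residuals"] <-
    paste0("Residuals (", rows$stratum[rows$term == "Residuals"], ")")
  anova_table(rows, spec, "strata")
}

# REML backend: random intercept for the blocking factor, Satterthwaite df.
fit_anova_reml <- function(data, spec, rhs) {
  if (!requireNamespace("lmerTest", quietly = TRUE))
    stop("method = 'reml' requires the lmerTest package")
  fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 |", spec$random, ")"))
  fit <- lmerTest::lmer(fml, data = data)
  type <- if (spec$ss_type == "III") 3L else 2L
  a <- stats::anova(fit, type = type, ddf = "Satterthwaite")
  rows <- data.frame(
    term = rownames(a),
    df = a[, "NumDF"],
    den_df = a[, "DenDF"],
    sumsq = a[, "Sum Sq"],
    meansq = a[, "Mean Sq"],
    F = a[, "F value"],
    p = a[, "Pr(>F)"],
    stratum = "reml",
    stringsAsFactors = FALSE
  )
  anova_table(rows, spec, "reml")
}

#' Fit an analysis of covariance
#'
#' Convenience wrapper around [fit_anova()] that requires at least one
#' continuous covariate and verifies the covariate varies within every
#' factor cell (a constant covariate within a cell makes the adjusted
#' factor contrasts meaningless).
#'
#' @inheritParams fit_anova
#' @return An `anova_table`; the covariate rows come first.
#' @export
fit_ancova <- function(data, spec, method = c("strata", "reml")) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$covariates) == 0L)
    stop("fit_ancova requires at least one covariate")
  data <- as.data.frame(data)
  if (length(spec$factors)) {
    cells <- interaction(data[spec$factors], drop = TRUE)
    for (cv in spec$covariates) {
      spread <- tapply(data[[cv]], cells,
                       function(x) length(unique(x)))
      if (any(spread < 2L))
        stop("covariate '", cv, "' is constant within a factor cell")
    }
  }
  fit_anova(data, spec, method = match.arg(method))
}
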