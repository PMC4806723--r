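# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: polygon area by the shoelace formula (not the
# trapezoid rule), permutation p by exhaustive enumeration, and factorial
# sums of squares from closed-form cell-mean algebra.

# Area under a piecewise-linear curve that starts and ends at zero,
# via the shoelace formula on the closed polygon (t1,0) .. (tn,0).
shoelace_area <- function(t, g) {
  stopifnot(g[1] == 0, g[length(g)] == 0)
  n <- length(t)
  j <- c(2:n, 1)
  abs(sum(t * g[j] - t[j] * g)) / 2
}

# Exact two-sided permutation p for a two-group mean difference,
# enumerating every way to choose the first group's labels.
exact_perm_p <- function(values, labels) {
  lv <- unique(labels)
  stopifnot(length(lv) == 2L)
  n1 <- sum(labels == lv[1])
  obs <- mean(values[labels == lv[1]]) - mean(values[labels == lv[2]])
  splits <- utils::combn(length(values), n1)
  diffs <- apply(splits, 2, function(idx)
    mean(values[idx]) - mean(values[-idx]))
  list(p = mean(abs(diffs) >= abs(obs) - 1e-12), diffs = diffs, obs = obs)
}

# Closed-form sums of squares for a balanced two-way factorial with two
# levels per factor and n per cell. Returns F and p per term.
balanced_twoway_oracle <- function(d, a_col, b_col, y_col) {
  a_lv <- sort(unique(d[[a_col]]))
  b_lv <- sort(unique(d[[b_col]]))
  stopifnot(length(a_lv) == 2L, length(b_lv) == 2L)
  n <- nrow(d) / 4
  grand <- mean(d[[y_col]])
  cell <- outer(a_lv, b_lv, Vectorize(function(a, b)
    mean(d[[y_col]][d[[a_col]] == a & d[[b_col]] == b])))
  a_mean <- rowMeans(cell)
  b_mean <- colMeans(cell)
  ss_a <- 2 * n * sum((a_mean - grand)^2)
  ss_b <- 2 * n * sum((b_mean - grand)^2)
  ss_ab <- n * sum((cell - outer(a_mean, b_mean, `+`) + grand)^2)
  fitted <- cell[cbind(match(d[[a_col]], a_lv), match(d[[b_col]], b_lv))]
  ss_e <- sum((d[[y_col]] - fitted)^2)
  df_e <- nrow(d) - 4
  ms_e <- ss_e / df_e
  f <- c(A = ss_a, B = ss_b, AB = ss_ab) / ms_e
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab, E = ss_e),
       f = f, df_e = df_e,
       p = stats::pf(f, 1, df_e, lower.tail = FALSE))
}

# Small conductance dataset with hand-controllable per-individual curves.
make_curves <- function(integr_a, integr_b, dawn = 6.5, dusk = 18.5) {
  # Triangles peaking mid-window: area = 0.5 * 12 * height, so
  # height = integral / 6 reproduces any requested integral exactly.
  mk <- function(vals, sp) {
    do.call(rbind, lapply(seq_along(vals), function(i)
      data.frame(individual_id = paste0(sp, "_", i), species = sp,
                 clock_time = (dawn + dusk) / 2, g_s = vals[i] / 6,
                 stringsAsFactors = FALSE)))
  }
  pad_dawn_dusk(rbind(mk(integr_a, "A"), mk(integr_b, "B")),
                dawn = dawn, dusk = dusk)
}

# Constant species-by-year matrix matching the default config labels.
sy_mat <- function(x) {
  matrix(x, 2, 2, dimnames = list(c("ERCI", "ERTE"),
                                  c("2004-05", "2007-08")))
}
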