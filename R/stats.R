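# Self-contained statistical toolbox used by every analysis module:
# one-way ANOVA, balanced two-factor ANOVA, pooled/Welch two-sample t,
# paired t / exact sign-flip permutation, and Mann-Whitney U with exact
# enumeration for small samples. All statistics are computed from explicit
# sums of squares / rank arithmetic; only the tail probabilities come from
# R's F/t/normal distribution functions.

#' Group-comparison result
#'
#' Container for a single hypothesis test: statistic, degrees of freedom,
#' two-sided p-value, and the significance verdict at `alpha`.
#'
#' @param test test name.
#' @param statistic statistic value.
#' @param df degrees of freedom (vector where applicable, or `NA`).
#' @param p p-value in \[0, 1\].
#' @param n group sizes.
#' @param alpha significance level (default 0.05, the study-wide criterion).
#' @param note optional free-text annotation (e.g. "skipped: n < 2").
#' @return object of class `group_comparison`.
#' @export
group_comparison <- function(test, statistic, df, p, n, alpha = 0.05,
                             note = NULL) {
  if (is.finite(p) && (p < 0 || p > 1)) stopf("p-value %g outside [0, 1]", p)
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 alpha = alpha,
                 significant = is.finite(p) && p < alpha,
                 n = n, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g [%s at alpha = %g]%s\n",
              x$test, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p, if (x$significant) "significant" else "not significant",
              x$alpha,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

check_sample <- function(x, name, min_n = 2) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stopf("'%s' contains non-finite values", name)
  if (length(x) < min_n) stopf("'%s' needs at least %d observations", name, min_n)
  x
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares F test across k groups,
#' df = (k - 1, N - k). Degenerate inputs are handled explicitly: all values
#' identical gives F = 0, p = 1; zero within-group variance with unequal
#' means gives the F = Inf, p = 0 limit.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param alpha significance level.
#' @return a [group_comparison()] with fields `ss_between`, `ss_within`
#'   attached as attributes.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("one_way_anova needs >= 2 groups")
  groups <- lapply(seq_along(groups), function(i)
    check_sample(groups[[i]], paste0("group ", i)))
  ni <- lengths(groups)
  N <- sum(ni)
  k <- length(groups)
  mi <- vapply(groups, mean, 0)
  gm <- sum(unlist(groups)) / N
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - mi[i])^2), 0))
  dfb <- k - 1; dfw <- N - k
  if (ssw <= 0) {
    if (ssb <= 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
  } else {
    F <- (ssb / dfb) / (ssw / dfw)
    p <- pf(F, dfb, dfw, lower.tail = FALSE)
  }
  res <- group_comparison("one-way ANOVA", F, c(dfb, dfw), p, ni, alpha)
  attr(res, "ss_between") <- ssb
  attr(res, "ss_within") <- ssw
  res
}

#' Independent two-sample t test
#'
#' Pooled-variance or Welch form, two-sided. Zero variance in both samples
#' with equal means is reported as t = 0, p = 1 by convention.
#'
#' @param x,y numeric samples of length >= 2.
#' @param var_equal use the pooled-variance form (default) or Welch.
#' @param alpha significance level.
#' @return a [group_comparison()].
#' @export
two_sample_t <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  d <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0)
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)) else NA_real_
  }
  if (se <= 0) {
    if (d == 0) { t <- 0; p <- 1; df <- nx + ny - 2 }
    else { t <- sign(d) * Inf; p <- 0; df <- nx + ny - 2 }
  } else {
    t <- d / se
    p <- 2 * pt(-abs(t), df)
  }
  group_comparison(if (var_equal) "two-sample t (pooled)" else "two-sample t (Welch)",
                   t, df, p, c(nx, ny), alpha)
}

#' Paired comparison of two matched samples
#'
#' Either a paired t test on the differences or an exact sign-flip
#' permutation test (all 2^n sign assignments when n <= 16, otherwise 2000
#' Monte Carlo flips). With all differences zero the permutation p is
#' exactly 1.
#'
#' @param x,y matched numeric samples of equal length >= 2.
#' @param method `"t"` or `"permutation"`.
#' @param alpha significance level.
#' @param n_mc Monte Carlo permutations for large n.
#' @return a [group_comparison()].
#' @export
paired_comparison <- function(x, y, method = c("t", "permutation"),
                              alpha = 0.05, n_mc = 2000) {
  method <- match.arg(method)
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  if (length(x) != length(y)) stopf("paired samples must have equal length")
  d <- x - y
  n <- length(d)
  if (method == "t") {
    s <- stats::sd(d)
    if (s <= 0) {
      if (mean(d) == 0) { t <- 0; p <- 1 } else { t <- sign(mean(d)) * Inf; p <- 0 }
    } else {
      t <- mean(d) / (s / sqrt(n))
      p <- 2 * pt(-abs(t), n - 1)
    }
    return(group_comparison("paired t", t, n - 1, p, n, alpha))
  }
  obs <- mean(d)
  if (n <= 16) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_perm <- as.vector(signs %*% d) / n
  } else {
    stats_perm <- vapply(seq_len(n_mc), function(i)
      mean(d * sample(c(-1, 1), n, replace = TRUE)), 0)
  }
  p <- mean(abs(stats_perm) >= abs(obs) - 1e-12)
  group_comparison("paired permutation (sign-flip)", obs, NA_real_, p, n, alpha)
}

#' Mann-Whitney U test
#'
#' Midrank-tied U statistic. Exact two-sided p by full enumeration of all
#' C(N, nx) labelings when the combined sample size is <= 12 and there are
#' no ties; otherwise a normal approximation with tie and continuity
#' corrections. With all observations tied the p-value is 1.
#'
#' @param x,y numeric samples (length >= 1).
#' @param exact force exact enumeration on/off; default decides by size/ties.
#' @param alpha significance level.
#' @return a [group_comparison()].
#' @export
mann_whitney_u <- function(x, y, exact = NULL, alpha = 0.05) {
  x <- check_sample(x, "x", 1); y <- check_sample(y, "y", 1)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (N <= 12) && !ties
  mu <- nx * ny / 2
  if (exact) {
    if (ties) stopf("exact Mann-Whitney enumeration requires untied data")
    combos <- utils::combn(N, nx)
    Us <- colSums(matrix(seq_len(N)[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(group_comparison("Mann-Whitney U (exact)", U, NA_real_, p,
                            c(nx, ny), alpha))
  }
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(0, z)))
  }
  group_comparison("Mann-Whitney U (normal approx.)", U, NA_real_, p,
                   c(nx, ny), alpha)
}

#' Two-factor (UNIANOVA-style) analysis of variance
#'
#' Main effects and interaction F tests for a crossed two-factor design.
#' For balanced designs the classical sums of squares coincide with
#' Type-III tests. Unbalanced designs are restricted to a balanced subset
#' (the first `min(cell n)` observations per cell) with a warning. With one
#' observation per cell the interaction is untestable and the main effects
#' are tested against the residual of the additive model.
#'
#' @param value numeric response.
#' @param f1,f2 factors (coerced), each with >= 2 levels.
#' @param alpha significance level.
#' @return named list of [group_comparison()] for `factor1`, `factor2` and
#'   `interaction` (the latter carries a note when untestable).
#' @export
two_way_anova <- function(value, f1, f2, alpha = 0.05) {
  value <- as.numeric(value)
  f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stopf("two_way_anova requires >= 2 levels per factor")
  if (any(!is.finite(value))) stopf("'value' contains non-finite values")
  counts <- table(f1, f2)
  if (any(counts == 0)) stopf("empty design cell: two_way_anova needs every cell filled")
  nmin <- min(counts)
  if (any(counts != nmin)) {
    warnf("unbalanced design: restricting every cell to its first %d observations", nmin)
    keep <- logical(length(value))
    for (l1 in levels(f1)) for (l2 in levels(f2)) {
      i <- which(f1 == l1 & f2 == l2)
      keep[head(i, nmin)] <- TRUE
    }
    value <- value[keep]; f1 <- droplevels(f1[keep]); f2 <- droplevels(f2[keep])
  }
  a <- nlevels(f1); b <- nlevels(f2); n <- nmin
  G <- mean(value)
  Ai <- tapply(value, f1, mean)
  Bj <- tapply(value, f2, mean)
  cellm <- tapply(value, list(f1, f2), mean)
  ssa <- b * n * sum((Ai - G)^2)
  ssb <- a * n * sum((Bj - G)^2)
  ssab <- n * sum((cellm - outer(Ai, rep(1, b)) -
                     outer(rep(1, a), Bj) + G)^2)
  cell_of <- cellm[cbind(as.integer(f1), as.integer(f2))]
  sse <- sum((value - cell_of)^2)
  dfa <- a - 1; dfb <- b - 1; dfab <- (a - 1) * (b - 1); dfe <- a * b * (n - 1)
  ftest <- function(ss, df, sse, dfe, label) {
    if (dfe == 0) return(NULL)
    mse <- sse / dfe
    if (mse <= 0) {
      if (ss <= 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
    } else {
      F <- (ss / df) / mse
      p <- pf(F, df, dfe, lower.tail = FALSE)
    }
    group_comparison(label, F, c(df, dfe), p, a * b * n, alpha)
  }
  if (n == 1) {
    # additive model: interaction SS becomes the residual
    res <- list(
      factor1 = ftest(ssa, dfa, ssab, dfab, "two-way ANOVA: factor 1"),
      factor2 = ftest(ssb, dfb, ssab, dfab, "two-way ANOVA: factor 2"),
      interaction = group_comparison("two-way ANOVA: interaction",
                                     NA_real_, c(dfab, 0), NA_real_,
                                     a * b * n, alpha,
                                     note = "untestable with one observation per cell"))
    return(res)
  }
  list(factor1 = ftest(ssa, dfa, sse, dfe, "two-way ANOVA: factor 1"),
       factor2 = ftest(ssb, dfb, sse, dfe, "two-way ANOVA: factor 2"),
       interaction = ftest(ssab, dfab, sse, dfe, "two-way ANOVA: interaction"))
}
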