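# Group statistics used on feature, density and expression tables: the
# variance-gated t-test, the F-test of variances, coefficient of variation,
# Kruskal-Wallis with Dunn's post hoc comparisons, and a four-test
# normality suite with QQ-plot data.

#' Two-sample t-test with a variance-gated Welch correction
#'
#' Runs the F-test of variances first; when its p-value is below
#' `var_alpha` the groups are compared with Welch's t-test, otherwise with
#' Student's t-test. The gate decision and both component results are
#' recorded, so the pretest can be bypassed by reading the raw results.
#' (Always-Welch is the statistically cleaner default; the gate reproduces
#' the common Prism workflow this package mirrors.)
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_alpha significance level of the variance gate (default 0.05).
#' @return A list of class `mgmorph_test`: `test_name`, `statistic`, `df`,
#'   `p_value`, `welch_used`, `f_test` (the gating [f_test_variance()]
#'   result), `degenerate` flag.
#' @export
welch_or_student_t <- function(a, b, var_alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) stop_param("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(test_name = "t (degenerate: zero variance)",
                          statistic = if (equal) 0 else Inf,
                          df = NA_real_, p_value = if (equal) 1 else 0,
                          welch_used = FALSE, f_test = NULL, degenerate = TRUE),
                     class = "mgmorph_test"))
  }
  ft <- f_test_variance(a, b)
  welch <- !ft$degenerate && ft$p_value < var_alpha
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(list(test_name = if (welch) "Welch t-test" else "Student t-test",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, welch_used = welch, f_test = ft,
                 degenerate = FALSE),
            class = "mgmorph_test")
}

#' F-test for equality of two variances
#'
#' F is the larger sample variance over the smaller, with matched degrees of
#' freedom, and the two-sided p-value is twice the upper tail of the F
#' distribution (capped at 1).
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return A list of class `mgmorph_test` with `statistic` (F), `df1`,
#'   `df2`, `p_value`, `degenerate`.
#' @export
f_test_variance <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_param("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    return(structure(list(test_name = "F test (degenerate: zero variances)",
                          statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                          p_value = 1, degenerate = TRUE),
                     class = "mgmorph_test"))
  if (va >= vb) { Fstat <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L }
  else         { Fstat <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L }
  p <- min(1, 2 * stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  structure(list(test_name = "F test of variances", statistic = Fstat,
                 df1 = df1, df2 = df2, p_value = p, degenerate = FALSE),
            class = "mgmorph_test")
}

#' @export
print.mgmorph_test <- function(x, ...) {
  cat(x$test_name, ": statistic =", format(x$statistic, digits = 5),
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Scale
#' invariant; undefined for zero-mean samples.
#'
#' @param x numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  m <- mean(x)
  if (m == 0) stop_param("CV undefined for zero-mean sample")
  100 * stats::sd(x) / m
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's z-tests on all group pairs: `z = (Ri - Rj) /
#' sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` where `Ri` are mean ranks over the
#' pooled sample and `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties.
#' Pairwise p-values are family-wise adjusted (Holm by default).
#'
#' @param groups named list of numeric vectors (>= 2 groups, total n >= 5).
#' @param p_adjust adjustment method for the Dunn p-values: `"holm"`
#'   (default), `"bonferroni"`, or `"none"`.
#' @return List with `omnibus` (an `mgmorph_test` with H, df, p) and
#'   `pairwise` (data.frame: group1, group2, z, p, p_adjusted).
#' @export
kruskal_dunn <- function(groups, p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 2L) stop_param("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(x) < 5L) stop_param("need total n >= 5")
  if (length(unique(x)) == 1L) {
    omnibus <- structure(list(test_name = "Kruskal-Wallis (degenerate: all ties)",
                              statistic = 0, df = length(groups) - 1L,
                              p_value = 1, degenerate = TRUE),
                         class = "mgmorph_test")
  } else {
    kt <- stats::kruskal.test(x, g)
    omnibus <- structure(list(test_name = "Kruskal-Wallis",
                              statistic = unname(kt$statistic),
                              df = unname(kt$parameter), p_value = kt$p.value,
                              degenerate = FALSE),
                         class = "mgmorph_test")
  }
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  prs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(prs))
  for (i in seq_len(ncol(prs))) {
    g1 <- prs[1L, i]; g2 <- prs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z[i] <- if (se > 0) (mean_ranks[[g1]] - mean_ranks[[g2]]) / se else 0
    p[i] <- 2 * stats::pnorm(abs(z[i]), lower.tail = FALSE)
  }
  pairwise <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ], z = z, p = p,
                         p_adjusted = stats::p.adjust(p, method = p_adjust))
  list(omnibus = omnibus, pairwise = pairwise)
}

# D'Agostino (1970) transformed skewness z-test.
dagostino_skew_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  b1 <- m3 / m2^1.5
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
}

# Anscombe & Glynn (1983) transformed kurtosis z-test.
anscombe_kurt_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  ((1 - 2 / (9 * A)) -
     ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) / sqrt(2 / (9 * A))
}

#' Four-test normality suite with QQ data
#'
#' Runs the D'Agostino-Pearson omnibus K^2 test (transformed skewness and
#' kurtosis), the Anderson-Darling test, the Shapiro-Wilk test, and the
#' Kolmogorov-Smirnov test with the Lilliefors correction (parameters are
#' estimated from the sample, so the uncorrected KS null would be wrong).
#' Also returns QQ data: the sorted sample against standard normal
#' quantiles at probability points `(i - 0.5) / n`.
#'
#' @param x numeric vector. All four tests need `n >= 8` (the
#'   D'Agostino-Pearson minimum); below that, unsupported tests are skipped
#'   with a message.
#' @return List with `tests` (data.frame: test, statistic, p_value),
#'   `qq` (data.frame: theoretical, sample), `degenerate` flag.
#' @export
normality_suite <- function(x) {
  n <- length(x)
  if (n < 3L) stop_param("need n >= 3")
  if (stats::sd(x) == 0) {
    return(list(tests = data.frame(test = character(), statistic = numeric(),
                                   p_value = numeric()),
                qq = data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                                sample = sort(x)),
                degenerate = TRUE))
  }
  rows <- list()
  if (n >= 8L) {
    zs <- dagostino_skew_z(x)
    zk <- anscombe_kurt_z(x)
    k2 <- zs^2 + zk^2
    rows$dagostino <- data.frame(test = "dagostino_pearson", statistic = k2,
                                 p_value = stats::pchisq(k2, 2, lower.tail = FALSE))
  } else message("n < 8: D'Agostino-Pearson test skipped")
  if (n >= 8L) {
    ad <- nortest::ad.test(x)
    rows$ad <- data.frame(test = "anderson_darling", statistic = unname(ad$statistic),
                          p_value = ad$p.value)
  } else message("n < 8: Anderson-Darling test skipped")
  sw <- stats::shapiro.test(x)
  rows$sw <- data.frame(test = "shapiro_wilk", statistic = unname(sw$statistic),
                        p_value = sw$p.value)
  if (n >= 5L) {
    ks <- nortest::lillie.test(x)
    rows$ks <- data.frame(test = "kolmogorov_smirnov",
                          statistic = unname(ks$statistic), p_value = ks$p.value)
  } else message("n < 5: Kolmogorov-Smirnov (Lilliefors) test skipped")
  list(tests = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       qq = data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                       sample = sort(x)),
       degenerate = FALSE)
}
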