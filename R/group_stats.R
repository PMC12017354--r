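# Normality-gated univariate comparisons, effect sizes, confidence
# intervals, correlation, and a priori power computation.

#' Student-t confidence interval for a mean from summary statistics
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation.
#' @param n Sample size (>= 2).
#' @param level Confidence level, default 0.95.
#' @param digits Decimals for the reported endpoints (half-up rounding);
#'   `NULL` leaves endpoints unrounded.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' ci_mean(0.153, 0.084, 35)   # 0.124 to 0.182
#' @export
ci_mean <- function(mean, sd, n, level = 0.95, digits = 3) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n))
  if (n < 2) stop("ci_mean requires n >= 2")
  if (sd < 0) stop("sd must be non-negative")
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  out <- c(lower = mean - half, upper = mean + half)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

# Exact noncentral-t power of a two-sample t test with n per group.
.t_power <- function(n, d, alpha, two_tailed = TRUE) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (two_tailed) {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' A priori sample size for a two-sample t test
#'
#' Smallest integer per-group n whose exact noncentral-t power reaches the
#' target, matching the usual G*Power "a priori" computation.
#'
#' @param d Anticipated Cohen's d (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param two_tailed Two-tailed test? Default `TRUE`.
#' @return Integer participants per group.
#' @examples
#' required_n(0.7, 0.05, 0.80)  # 34
#' @export
required_n <- function(d, alpha = 0.05, power = 0.80, two_tailed = TRUE) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (.t_power(n, d, alpha, two_tailed) < power) {
    n <- n + 1L
    if (n > 1e6L) stop("required sample size exceeds 1e6; check parameters")
  }
  n
}

#' Cliff's delta dominance effect size
#'
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, computed from midranks
#' so large samples do not require the full double loop.
#'
#' @param x,y Numeric samples.
#' @return Value in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  # rank-sum identity: sum of x-ranks = U_x + nx(nx+1)/2 with ties as 1/2
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # #{x>y} + 0.5 * ties
  (2 * ux - nx * ny) / (nx * ny)
}

#' Cohen's d (pooled-SD standardized mean difference)
#' @param x,y Numeric samples.
#' @return Numeric effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Cohen's h for two proportions
#' @param p1,p2 Proportions in `[0, 1]`.
#' @return Numeric effect size.
#' @export
cohens_h <- function(p1, p2) {
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Normality-gated two-group comparison
#'
#' Continuous variables: Shapiro-Wilk on each group at `alpha_norm`; both
#' normal selects Welch's t test with |Cohen's d|, otherwise a two-sided
#' Mann-Whitney U test with |Cliff's delta|. Categorical variables:
#' Pearson chi-square (no continuity correction) with |Cohen's h| for 2x2
#' tables.
#'
#' @param x,y Observations for the two groups: numeric when
#'   `type = "continuous"`, factor/character when `type = "categorical"`.
#' @param type `"continuous"` or `"categorical"`.
#' @param alpha_norm Normality-gate level.
#' @param variable Optional variable name carried into the result.
#' @return A one-row data.frame: variable, test, statistic, p, effect
#'   size name and absolute value.
#' @export
auto_compare <- function(x, y, type = c("continuous", "categorical"),
                         alpha_norm = 0.05, variable = NA_character_) {
  type <- match.arg(type)
  if (type == "continuous") {
    stopifnot(length(x) >= 3, length(y) >= 3)
    normal <- shapiro.test(x)$p.value > alpha_norm &&
      shapiro.test(y)$p.value > alpha_norm
    if (normal) {
      ht <- t.test(x, y)          # Welch
      es <- abs(cohens_d(x, y)); esn <- "cohens_d"; test <- "t"
    } else {
      ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
      es <- abs(cliffs_delta(x, y)); esn <- "cliffs_delta"
      test <- "mann_whitney"
    }
    data.frame(variable = variable, test = test,
               statistic = unname(ht$statistic), p = ht$p.value,
               effect_size = esn, effect = es,
               stringsAsFactors = FALSE)
  } else {
    tab <- table(factor(c(rep("A", length(x)), rep("B", length(y)))),
                 c(as.character(x), as.character(y)))
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate contingency table")
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    es <- NA_real_
    if (all(dim(tab) == 2)) {
      p1 <- tab[1, 1] / sum(tab[1, ])
      p2 <- tab[2, 1] / sum(tab[2, ])
      es <- abs(cohens_h(p1, p2))
    }
    data.frame(variable = variable, test = "chi_square",
               statistic = unname(ht$statistic), p = ht$p.value,
               effect_size = "cohens_h", effect = es,
               stringsAsFactors = FALSE)
  }
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk on each variable gates Pearson (both normal) versus
#' Spearman correlation, mirroring the analysis recipe used for the
#' language/clinical association.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param alpha_norm Normality-gate level.
#' @return List with `method`, `r`, `p`.
#' @export
gated_correlation <- function(x, y, alpha_norm = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("gated_correlation requires n >= 4 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input vector; correlation undefined")
    return(list(method = NA_character_, r = NA_real_, p = NA_real_))
  }
  normal <- shapiro.test(x)$p.value > alpha_norm &&
    shapiro.test(y)$p.value > alpha_norm
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), p = ct$p.value)
}
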