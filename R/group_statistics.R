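#' Pooled-SD standardized mean difference (Cohen's d)
#'
#' \eqn{d = (\bar x - \bar y)/s_p} with
#' \eqn{s_p^2 = ((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)}.
#'
#' @param x,y Numeric samples.
#' @return The standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

## stop with the names of aliased (rank-deficient) terms
check_full_rank <- function(fit) {
  if (!anyNA(coef(fit))) return(invisible(TRUE))
  stop("singular design; aliased terms: ",
       paste(names(which(is.na(coef(fit)))), collapse = ", "))
}

#' Group-by-electrode ANCOVA on steady-state metrics
#'
#' Fits, on the stacked per-electrode rows, the linear model
#' `outcome ~ group * electrode + covariate` with sum-to-zero contrasts
#' and type-III sums of squares (`design = "full"`, the 3 x 8 layout),
#' or the one-way `outcome ~ group + covariate` on one row per subject
#' (`design = "max"`, intended for the maximal-electrode summary).
#' Pairwise Cohen's d between groups is reported on the subject-level
#' outcome (electrode-averaged in the full design).
#'
#' @param tbl Cohort table (long, per electrode) with columns `group`,
#'   `electrode`, `subject_id`, the outcome and the covariate.
#' @param outcome,covariate Column names (default `f_plus` adjusted for
#'   `F_snr`). `covariate = NULL` drops the covariate (plain ANOVA).
#' @param design `"full"` or `"max"`.
#' @return List with `anova` (term, df, F, p, partial eta squared),
#'   `pairwise_d` (data frame of group contrasts) and the fitted model.
#' @export
ancova_group_by_electrode <- function(tbl, outcome = "f_plus",
                                      covariate = "F_snr",
                                      design = c("full", "max")) {
  design <- match.arg(design)
  d <- tbl
  d$group <- factor(d$group)
  d$.y <- d[[outcome]]
  stats::contrasts(d$group) <- stats::contr.sum(nlevels(d$group))
  rhs <- if (design == "full") {
    d$electrode <- factor(d$electrode)
    stats::contrasts(d$electrode) <- stats::contr.sum(nlevels(d$electrode))
    ".y ~ group * electrode"
  } else ".y ~ group"
  if (!is.null(covariate)) {
    d$.cov <- d[[covariate]]
    rhs <- paste(rhs, "+ .cov")
  }
  fit <- lm(stats::as.formula(rhs), data = d)
  check_full_rank(fit)
  a3 <- car::Anova(fit, type = 3)
  a3 <- a3[!rownames(a3) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  sse <- sum(stats::residuals(fit)^2)
  tab <- data.frame(term = sub("^\\.cov$", covariate %||% "", rownames(a3)),
                    df = a3$Df, F = a3$`F value`, p = a3$`Pr(>F)`,
                    partial_eta_sq = a3$`Sum Sq` / (a3$`Sum Sq` + sse),
                    row.names = NULL)

  ## subject-level pairwise effect sizes
  subj <- aggregate(d$.y, list(subject_id = d$subject_id, group = d$group), mean)
  gl <- levels(d$group)
  pairs <- utils::combn(gl, 2L)
  pairwise_d <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    d = apply(pairs, 2L, function(p)
      cohens_d(subj$x[subj$group == p[1L]], subj$x[subj$group == p[2L]])))
  list(anova = tab, pairwise_d = pairwise_d, fit = fit)
}

#' Tie-corrected Mann-Whitney U test (normal approximation)
#'
#' Reports the smaller of the two U statistics, the tie-corrected
#' normal-approximation Z (always non-positive, as conventionally
#' printed), and the two-sided p value.
#'
#' @param x,y Numeric samples.
#' @return List: `U`, `Z`, `p`.
#' @export
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U <- min(U1, n1 * n2 - U1)
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 == 0) 0 else (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, Z = z, p = min(1, 2 * pnorm(z)))
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise post hocs
#'
#' Omnibus Kruskal-Wallis across groups followed by all pairwise
#' two-sided Mann-Whitney tests (tie-corrected normal approximation),
#' with p values multiplied by the number of comparisons (capped at 1).
#'
#' @param tbl Data frame with a `group` column and the outcome.
#' @param outcome Outcome column name.
#' @param group Grouping column name.
#' @return List with `kruskal` (`H`, `df`, `p`) and `pairwise`
#'   (data frame: group1, group2, U, Z, p, p_bonferroni).
#' @export
kruskal_wallis_posthoc <- function(tbl, outcome, group = "group") {
  g <- factor(tbl[[group]])
  y <- tbl[[outcome]]
  ok <- !is.na(y) & !is.na(g)
  g <- droplevels(g[ok]); y <- y[ok]
  kw <- kruskal.test(y, g)
  pairs <- utils::combn(levels(g), 2L)
  ph <- apply(pairs, 2L, function(p) {
    mw <- mann_whitney_z(y[g == p[1L]], y[g == p[2L]])
    data.frame(group1 = p[1L], group2 = p[2L], U = mw$U, Z = mw$Z, p = mw$p,
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_bonferroni <- pmin(1, ph$p * nrow(ph))
  list(kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = ph)
}

#' Case-resampling bootstrap for a linear regression
#'
#' Ordinary least squares refit on `B` case resamples (with
#' replacement); 95% confidence intervals are the 2.5/97.5 percentiles
#' of the bootstrap coefficient distribution and the bootstrap p value
#' is \eqn{2\min(P(\beta^* \le 0), P(\beta^* \ge 0))} with the +1
#' small-sample correction. Standardized coefficients rescale each
#' predictor and the response to unit variance. Complete cases only.
#'
#' @param data Data frame.
#' @param formula Model formula, e.g.
#'   `ace_memory ~ f_plus + acc_2afc + speed_2afc`.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed (resampling is seed-deterministic).
#' @param conf Confidence level.
#' @return List with `coefficients` (term, estimate, std_estimate,
#'   ci_lower, ci_upper, p_boot), `B`, `n` and the full-sample fit.
#' @export
bootstrap_regression <- function(data, formula, B = 1000L, seed = 1L,
                                 conf = 0.95) {
  if (B < 100L) warning("B < 100 bootstrap resamples gives unstable intervals")
  vars <- all.vars(formula)
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  X <- model.matrix(formula, data)
  y <- data[[vars[1L]]]
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors: design matrix is rank deficient")
  n <- nrow(X)
  fit <- .lm.fit(X, y)
  est <- setNames(fit$coefficients, colnames(X))

  sds <- apply(X, 2L, sd)
  std <- est * ifelse(colnames(X) == "(Intercept)", NA, sds / sd(y))

  set.seed(seed)
  bs <- matrix(NA_real_, B, ncol(X), dimnames = list(NULL, colnames(X)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bs[b, ] <- .lm.fit(X[idx, , drop = FALSE], y[idx])$coefficients
  }
  alpha <- (1 - conf) / 2
  ci <- apply(bs, 2L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  pboot <- apply(bs, 2L, function(b) {
    b <- b[!is.na(b)]
    min(1, 2 * min((1 + sum(b <= 0)) / (length(b) + 1),
                   (1 + sum(b >= 0)) / (length(b) + 1)))
  })
  list(coefficients = data.frame(term = colnames(X), estimate = unname(est),
                                 std_estimate = unname(std),
                                 ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                                 p_boot = unname(pboot), row.names = NULL),
       B = B, n = n, seed = seed)
}

#' Two-way mixed-model intraclass correlations
#'
#' From the two-way ANOVA mean squares of a subjects x sessions matrix
#' (rows MSR, columns/sessions MSC, error MSE) computes the single- and
#' average-measure ICCs for consistency, ICC(C,1) and ICC(C,k), and for
#' absolute agreement, ICC(A,1) and ICC(A,k), with F-based 95%
#' confidence intervals, the session-bias F test (MSC/MSE), and the
#' qualitative reliability band of each point estimate (see
#' [icc_band()]). Subjects with missing sessions are dropped
#' (complete-case), with the count reported.
#'
#' @param m Numeric matrix, subjects in rows, sessions (k >= 2) in
#'   columns.
#' @param conf Confidence level for the intervals.
#' @return Object of class `fb_icc` with elements `icc` (data frame:
#'   type, est, ci_lower, ci_upper, band), `bias_F`
#'   (statistic, df1, df2, p), mean squares, `n`, `k`, and
#'   `n_dropped`.
#' @export
icc_two_way <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  cc <- complete.cases(m)
  n_dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need >= 3 complete subjects and >= 2 sessions")

  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  MSR <- k * sum((rm_ - grand)^2) / (n - 1)
  MSC <- n * sum((cm_ - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc_c1 <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  icc_a1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icc_ck <- (MSR - MSE) / MSR
  icc_ak <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  alpha <- 1 - conf
  Fobs <- MSR / MSE
  FL <- Fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  FU <- Fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci_c1 <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  ci_ck <- c(1 - 1 / FL, 1 - 1 / FU)

  ## McGraw & Wong interval for absolute-agreement single measures
  a <- k * icc_a1 / (n * (1 - icc_a1))
  b <- 1 + k * icc_a1 * (n - 1) / (n * (1 - icc_a1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- qf(1 - alpha / 2, n - 1, v)
  F2 <- qf(1 - alpha / 2, v, n - 1)
  lo_a1 <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi_a1 <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown to k measures
  ci_a1 <- c(lo_a1, hi_a1)
  ci_ak <- sb(ci_a1)

  icc <- data.frame(
    type = c("ICC(C,1)", "ICC(A,1)", "ICC(C,k)", "ICC(A,k)"),
    est = c(icc_c1, icc_a1, icc_ck, icc_ak),
    ci_lower = c(ci_c1[1L], ci_a1[1L], ci_ck[1L], ci_ak[1L]),
    ci_upper = c(ci_c1[2L], ci_a1[2L], ci_ck[2L], ci_ak[2L]),
    stringsAsFactors = FALSE)
  icc$band <- icc_band(icc$est)

  biasF <- MSC / MSE
  structure(list(icc = icc,
                 bias_F = list(statistic = biasF, df1 = k - 1,
                               df2 = (n - 1) * (k - 1),
                               p = pf(biasF, k - 1, (n - 1) * (k - 1),
                                      lower.tail = FALSE)),
                 MSR = MSR, MSC = MSC, MSE = MSE,
                 n = n, k = k, n_dropped = n_dropped),
            class = "fb_icc")
}

#' @export
print.fb_icc <- function(x, ...) {
  cat(sprintf("Two-way mixed-model ICC (n = %d, k = %d%s)\n", x$n, x$k,
              if (x$n_dropped) paste0(", ", x$n_dropped, " incomplete dropped") else ""))
  for (i in seq_len(nrow(x$icc)))
    cat(sprintf("  %s = %.2f [%.2f, %.2f] (%s)\n", x$icc$type[i], x$icc$est[i],
                x$icc$ci_lower[i], x$icc$ci_upper[i], x$icc$band[i]))
  cat(sprintf("  session bias F(%d,%d) = %.2f, p = %.3f\n",
              x$bias_F$df1, x$bias_F$df2, x$bias_F$statistic, x$bias_F$p))
  invisible(x)
}

#' Qualitative reliability band of an ICC value
#'
#' Below 0.40: poor; 0.40 to below 0.60: moderate; 0.60 to below 0.75:
#' good; 0.75 and above: excellent.
#'
#' @param value Numeric ICC value(s).
#' @return Character vector of band labels.
#' @export
icc_band <- function(value) {
  as.character(cut(value, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = FALSE))
}
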