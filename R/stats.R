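#' @include pipeline.R
NULL

# Long table (subject, level, value) -> complete-case wide matrix
# subjects x levels, preserving first-appearance level order.
.rmWide <- function(table, metric, value, subject, within) {
  if (!is.null(metric) && "metric" %in% names(table)) {
    table <- table[table$metric == metric, , drop = FALSE]
  }
  lev <- unique(table[[within]])
  sub <- unique(table[[subject]])
  Y <- matrix(NA_real_, length(sub), length(lev),
              dimnames = list(sub, lev))
  Y[cbind(match(table[[subject]], sub), match(table[[within]], lev))] <-
    table[[value]]
  complete <- rowSums(is.na(Y)) == 0L
  if (any(!complete)) {
    message("dropping ", sum(!complete),
            " subject(s) with incomplete cases (listwise): ",
            paste(sub[!complete], collapse = ", "))
  }
  Y[complete, , drop = FALSE]
}

#' One-way repeated-measures ANOVA
#'
#' Univariate repeated-measures ANOVA of one within-subject factor,
#' computed from the sums-of-squares decomposition
#' `SS_total = SS_subjects + SS_level + SS_error` with
#' `F = MS_level / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom. Subjects with incomplete cases are dropped listwise (as when
#' deaths censor late time points). The uncorrected p-value is reported
#' alongside a Greenhouse-Geisser corrected p (epsilon estimated from the
#' double-centered covariance of the within-subject data); sphericity is
#' otherwise not assumed away.
#'
#' @param table long data.frame with subject, level and value columns
#'   (optionally a `metric` column filtered by `metric`).
#' @param metric optional metric name to filter on.
#' @param value,subject,within column names (defaults `value`,
#'   `subject_id`, `epoch`).
#' @return a [TestResult-class]; `details` carries the level means, error
#'   MS and degrees of freedom used by [tukeyHsd()].
#' @examples
#' d <- expand.grid(subject_id = 1:6, epoch = c("BL", "T1", "T2"))
#' d$value <- rnorm(nrow(d)) + (d$epoch == "T2")
#' oneWayRmAnova(d)
#' @export
oneWayRmAnova <- function(table, metric = NULL, value = "value",
                          subject = "subject_id", within = "epoch") {
  Y <- .rmWide(table, metric, value, subject, within)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L) stop("insufficient data: need >= 2 complete subjects")
  if (k < 2L) stop("insufficient data: need >= 2 within-subject levels")
  g <- mean(Y)
  colM <- colMeans(Y); rowM <- rowMeans(Y)
  ssLevel <- n * sum((colM - g)^2)
  ssSubj <- k * sum((rowM - g)^2)
  ssTot <- sum((Y - g)^2)
  ssErr <- max(ssTot - ssLevel - ssSubj, 0)
  dfL <- k - 1L
  dfE <- (n - 1L) * (k - 1L)
  msL <- ssLevel / dfL
  msE <- ssErr / dfE
  F <- if (msE > 0) msL / msE else if (msL == 0) 0 else Inf
  p <- if (ssLevel == 0) 1 else pf(F, dfL, dfE, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- cov(Y)
  Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  denom <- (k - 1) * sum(Sc^2)
  eps <- if (denom > 0) sum(diag(Sc))^2 / denom else 1
  eps <- min(max(eps, 1 / (k - 1)), 1)
  pGG <- if (ssLevel == 0) 1 else {
    pf(F, eps * dfL, eps * dfE, lower.tail = FALSE)
  }
  .TestResult("one-way RM-ANOVA", statistic = F, df = c(dfL, dfE),
              pValue = p, pGG = pGG,
              details = list(means = colM, levels = colnames(Y),
                             n = n, msErr = msE, dfErr = dfE,
                             epsilonGG = eps, ssLevel = ssLevel,
                             ssSubject = ssSubj, ssError = ssErr,
                             data = Y))
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA (e.g. treatment x time for the
#' plethysmography comparisons), fitted with `stats::aov` using the
#' `Error(subject/(A*B))` stratification. Requires a fully crossed design
#' per subject; subjects with incomplete cells are dropped listwise and
#' an error lists missing cells if no complete crossing remains.
#'
#' Unlike the one-way and paired comparisons, the two-way design has no
#' standard nonparametric equivalent; when [normalityGate()] fails on its
#' residuals the analysis should be flagged for manual review rather than
#' dispatched automatically.
#'
#' @param table long data.frame.
#' @param metric optional metric filter (against a `metric` column).
#' @param factors length-2 character vector naming the within-subject
#'   factor columns, `c(treatment, time)`.
#' @param value,subject column names.
#' @return a [TestResult-class] with the `effects` table filled (one row
#'   per main effect and the interaction).
#' @export
twoWayRmAnova <- function(table, metric = NULL,
                          factors = c("treatment", "epoch"),
                          value = "value", subject = "subject_id") {
  if (!is.null(metric) && "metric" %in% names(table)) {
    table <- table[table$metric == metric, , drop = FALSE]
  }
  a <- factors[1L]; b <- factors[2L]
  cells <- with(table, paste(table[[a]], table[[b]], sep = ":"))
  allCells <- as.vector(outer(unique(table[[a]]), unique(table[[b]]),
                              paste, sep = ":"))
  keepSub <- vapply(unique(table[[subject]]), function(s) {
    have <- cells[table[[subject]] == s]
    all(allCells %in% have)
  }, logical(1))
  subs <- unique(table[[subject]])
  if (any(!keepSub)) {
    miss <- unlist(lapply(subs[!keepSub], function(s) {
      have <- cells[table[[subject]] == s]
      paste0(s, "[", paste(setdiff(allCells, have), collapse = ","), "]")
    }))
    if (sum(keepSub) < 2L) {
      stop("insufficient data: missing cells leave < 2 complete subjects: ",
           paste(miss, collapse = "; "))
    }
    message("dropping incomplete subject(s): ",
            paste(miss, collapse = "; "))
    table <- table[table[[subject]] %in% subs[keepSub], , drop = FALSE]
  }
  d <- data.frame(
    y = table[[value]],
    S = factor(table[[subject]]),
    A = factor(table[[a]]),
    B = factor(table[[b]])
  )
  if (any(!is.finite(d$y))) stop("insufficient data: non-finite values")
  fit <- aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  ssTot <- sum((d$y - mean(d$y))^2)
  eff <- do.call(rbind, lapply(sm, function(stratum) {
    tb <- stratum[[1L]]
    rn <- trimws(rownames(tb))
    sel <- rn %in% c("A", "B", "A:B")
    if (!any(sel)) return(NULL)
    out <- data.frame(effect = rn[sel], df1 = tb$Df[sel],
                      df2 = tb$Df[rn == "Residuals"],
                      F = tb$`F value`[sel], p = tb$`Pr(>F)`[sel])
    # an effect whose sum of squares is numerically zero is a true null
    # even when its error stratum is zero too (0/0 in aov)
    null0 <- tb$`Sum Sq`[sel] <= 1e-12 * max(ssTot, .Machine$double.eps)
    out$F[null0] <- 0
    out$p[null0] <- 1
    out
  }))
  eff$effect <- c(A = a, B = b,
                  `A:B` = paste0(a, ":", b))[eff$effect]
  rownames(eff) <- NULL
  .TestResult("two-way RM-ANOVA", effects = eff,
              details = list(factors = factors,
                             n = length(unique(d$S))))
}

#' Paired t-test
#'
#' Two-sided paired t-test (e.g. left vs right hemidiaphragm, or
#' between-cohort responses at a matched time point).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return a [TestResult-class].
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must be paired vectors of equal length >= 2")
  }
  d <- x - y
  if (sd(d) == 0) {
    stop("degenerate paired data: differences have zero variance")
  }
  tt <- t.test(x, y, paired = TRUE)
  .TestResult("paired t-test", statistic = unname(tt$statistic),
              df = unname(tt$parameter), pValue = tt$p.value,
              details = list(meanDiff = unname(tt$estimate)))
}

#' Tukey HSD post hoc for a repeated-measures ANOVA
#'
#' All pairwise comparisons of the within-subject level means using the
#' studentized-range distribution with the ANOVA's error mean square and
#' error degrees of freedom: `q = |m_i - m_j| / sqrt(MS_err / n)`,
#' adjusted p from `ptukey(q, k, df_err)`.
#'
#' @param res a [TestResult-class] from [oneWayRmAnova()].
#' @return data.frame of comparisons: `comparison`, `diff`, `q`,
#'   `p_unadj` (pairwise t) and `p_adj`; empty (with a message) when
#'   fewer than 3 levels make the post hoc inapplicable.
#' @export
tukeyHsd <- function(res) {
  stopifnot(is(res, "TestResult"))
  dt <- res@details
  k <- length(dt$means)
  if (k < 3L) {
    message("Tukey post hoc not applicable with < 3 levels")
    return(data.frame(comparison = character(), diff = numeric(),
                      q = numeric(), p_unadj = numeric(),
                      p_adj = numeric()))
  }
  se <- sqrt(dt$msErr / dt$n)
  pairs <- combn(k, 2L)
  comp <- apply(pairs, 2L, function(ij) {
    paste(dt$levels[ij[2L]], "-", dt$levels[ij[1L]])
  })
  diffs <- dt$means[pairs[2L, ]] - dt$means[pairs[1L, ]]
  q <- abs(diffs) / se
  pAdj <- ptukey(q, nmeans = k, df = dt$dfErr, lower.tail = FALSE)
  pUn <- 2 * pt(-q / sqrt(2), df = dt$dfErr)
  data.frame(comparison = comp, diff = unname(diffs), q = unname(q),
             p_unadj = unname(pUn), p_adj = unname(pAdj))
}

#' Pearson chi-squared test with Yates continuity correction
#'
#' The corrected statistic on a 2x2 contingency table,
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` with 1 degree of freedom; the
#' correction term is clamped at zero so no cell contributes negatively.
#' This is the test applied to cohort survival proportions.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return a [TestResult-class].
#' @examples
#' chiSquaredYates(rbind(c(6, 5), c(9, 0)))
#' @export
chiSquaredYates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("tab must contain nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero margin")
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  .TestResult("chi-squared (Yates)", statistic = stat, df = 1,
              pValue = pchisq(stat, df = 1, lower.tail = FALSE),
              correction = "Yates",
              details = list(observed = tab, expected = E))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance
#'   (e.g. time post-AAV vs mean ligand response).
#' @return a [TestResult-class]; `statistic` is r, p is the t-based
#'   two-sided p-value on n - 2 df.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: constant vector")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  .TestResult("Pearson correlation", statistic = unname(ct$estimate),
              df = unname(ct$parameter), pValue = ct$p.value,
              details = list(t = unname(ct$statistic),
                             conf.int = ct$conf.int))
}

#' Normality gate for parametric vs nonparametric dispatch
#'
#' Shapiro-Wilk test on residuals at alpha = 0.05 (optionally plus a
#' Bartlett equal-variance check across groups for ANOVA designs). When
#' assumptions fail, the analysis should fall back to the nonparametric
#' equivalent: Friedman test for the one-way repeated-measures ANOVA,
#' Wilcoxon signed-rank for the paired t-test. Degenerate input (fewer
#' than 3 residuals, or zero variance) routes nonparametric.
#'
#' @param residuals numeric vector of model residuals.
#' @param groups optional grouping factor for the equal-variance check.
#' @param alpha significance level of the assumption checks.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normalityGate <- function(residuals, groups = NULL, alpha = 0.05) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3L || sd(residuals) == 0) return("nonparametric")
  if (n > 5000L) {
    residuals <- residuals[round(seq(1L, n, length.out = 5000L))]
  }
  if (shapiro.test(residuals)$p.value < alpha) return("nonparametric")
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (nlevels(groups) >= 2L &&
        all(tapply(residuals, groups, function(v) length(v) >= 2L &&
                     sd(v) > 0))) {
      if (bartlett.test(residuals, groups)$p.value < alpha) {
        return("nonparametric")
      }
    }
  }
  "parametric"
}

#' One-way RM comparison with automatic assumption gate
#'
#' Runs [oneWayRmAnova()] and checks its interaction residuals with
#' [normalityGate()]; on failure reruns the comparison as a Friedman test
#' (the nonparametric equivalent). The chosen route is recorded in
#' `testName`.
#'
#' @inheritParams oneWayRmAnova
#' @return a [TestResult-class].
#' @export
oneWayRmAnovaAuto <- function(table, metric = NULL, value = "value",
                              subject = "subject_id", within = "epoch") {
  res <- oneWayRmAnova(table, metric, value, subject, within)
  Y <- res@details$data
  resid <- Y - rowMeans(Y) -
    matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE) + mean(Y)
  route <- normalityGate(as.vector(resid),
                         groups = rep(colnames(Y), each = nrow(Y)))
  if (route == "parametric") return(res)
  fr <- friedman.test(Y)
  .TestResult("Friedman test (nonparametric route)",
              statistic = unname(fr$statistic),
              df = unname(fr$parameter), pValue = fr$p.value,
              details = res@details)
}

#' Paired comparison with automatic assumption gate
#'
#' [pairedT()] when the paired differences pass [normalityGate()], else a
#' Wilcoxon signed-rank test.
#'
#' @inheritParams pairedT
#' @return a [TestResult-class].
#' @export
pairedTAuto <- function(x, y) {
  d <- x - y
  if (normalityGate(d) == "parametric") return(pairedT(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  .TestResult("Wilcoxon signed-rank (nonparametric route)",
              statistic = unname(wt$statistic), df = NA_real_,
              pValue = wt$p.value)
}
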