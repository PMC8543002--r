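# Statistical comparisons: normality-gated paired tests and two-way
# repeated-measures ANOVA with Tukey post-hoc pairwise comparisons.

#' Normality-gated paired comparison
#'
#' Tests the paired differences for normality (Shapiro-Wilk); if the
#' normality p-value is at least `alpha`, a paired t-test is used, otherwise
#' a Wilcoxon signed-rank test (zero differences dropped; exact distribution
#' for n <= 25 without ties).  `force_test` overrides the gating.
#'
#' @param a,b Condition values, matched order (differences are `b - a`).
#' @param force_test `NULL`, `"paired-t"` or `"wilcoxon"`.
#' @param alpha Significance (and gating) level.
#' @return An object of class `paired_test`: `test`, `statistic`, `p_value`,
#'   `normality_p`, `alpha`, `n`, `degenerate`.
#' @export
paired_compare <- function(a, b, force_test = NULL, alpha = 0.05) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  if (length(a) < 3) stopf("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stopf("missing pairs are not allowed")
  if (!is.null(force_test)) force_test <- match.arg(force_test, c("paired-t", "wilcoxon"))
  d <- b - a
  res <- function(test, statistic, p, normality_p, degenerate = FALSE) {
    structure(list(test = test, statistic = unname(statistic),
                   p_value = unname(p), normality_p = normality_p,
                   alpha = alpha, n = length(d), degenerate = degenerate),
              class = "paired_test")
  }
  if (stats::sd(d) == 0) {
    # all differences identical: no dispersion to test against
    if (all(d == 0)) return(res(force_test %||% "paired-t", 0, 1, NA_real_, TRUE))
    return(res(force_test %||% "paired-t", sign(mean(d)) * Inf, 0, NA_real_, TRUE))
  }
  normality_p <- stats::shapiro.test(d)$p.value
  test <- force_test %||% (if (normality_p >= alpha) "paired-t" else "wilcoxon")
  if (test == "paired-t") {
    fit <- stats::t.test(b, a, paired = TRUE)
    res("paired-t", fit$statistic, fit$p.value, normality_p)
  } else {
    dn <- d[d != 0]
    if (!length(dn)) return(res("wilcoxon", 0, 1, normality_p, TRUE))
    exact <- length(dn) <= 25 && !anyDuplicated(abs(dn))
    fit <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE, exact = exact))
    res("wilcoxon", fit$statistic, fit$p.value, normality_p)
  }
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (normality p = %.3g, n = %d%s)\n",
              x$test, x$statistic, x$p_value, x$normality_p, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

.check_balanced <- function(data, subject, a, b) {
  tab <- table(data[[subject]], data[[a]], data[[b]])
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    msg <- if (nrow(miss)) {
      paste(apply(miss, 1, function(r) {
        paste0(dimnames(tab)[[1]][r[1]], "/", dimnames(tab)[[2]][r[2]], "/",
               dimnames(tab)[[3]][r[3]])
      }), collapse = ", ")
    } else "duplicated cells"
    stopf("design is not balanced (one observation per subject x cell); problem cells: %s",
          msg)
  }
  invisible(TRUE)
}

# Greenhouse-Geisser epsilon for an effect with orthonormal contrast matrix C,
# from the subjects x cells data matrix Y: eps = tr(C'SC)^2 / (df * tr((C'SC)^2))
.gg_epsilon <- function(Y, C) {
  S <- stats::cov(Y)
  M <- t(C) %*% S %*% C
  sum(diag(M))^2 / (ncol(C) * sum(M^2))
}

.orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Two-way repeated-measures ANOVA
#'
#' Univariate repeated-measures ANOVA with subject as the repeated factor:
#' each within-subject effect (factor A, factor B and their interaction) is
#' tested against its own subject-by-effect error stratum, as fitted by
#' `aov` with an `Error(subject/(A*B))` term.  The design must be complete
#' and balanced.  Optionally, Greenhouse-Geisser corrected p-values are
#' added (`gg = TRUE`); no sphericity correction is applied by default.
#'
#' @param data Long data frame.
#' @param dv,subject,a,b Column names of the response, subject identifier
#'   and the two within-subject factors.
#' @param gg Add Greenhouse-Geisser corrected p-values.
#' @return An object of class `rm_anova` whose `table` element has one row
#'   per effect: `effect`, `df1`, `df2`, `ss`, `ms`, `F`, `p` (and
#'   `epsilon`, `p_gg` when `gg = TRUE`).
#' @export
rm_anova2 <- function(data, dv = "value", subject = "subject",
                      a = "lap", b = "segment", gg = FALSE) {
  for (col in c(dv, subject, a, b)) {
    if (is.null(data[[col]])) stopf("data is missing column '%s'", col)
  }
  data <- data.frame(y = data[[dv]],
                     subject = factor(data[[subject]]),
                     A = factor(data[[a]]),
                     B = factor(data[[b]]))
  .check_balanced(data, "subject", "A", "B")
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = data)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    data.frame(effect = term,
               df1 = tab$Df[i], df2 = tab$Df[j],
               ss = tab$`Sum Sq`[i], ms = tab$`Mean Sq`[i],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  table <- rbind(pull("subject:A", "A"), pull("subject:B", "B"),
                 pull("subject:A:B", "A:B"))
  table$effect <- c(a, b, paste0(a, ":", b))
  # effects whose sum of squares is numerically zero report F = 0, p = 1
  # (otherwise 0/0 rounding noise masquerades as F ~ 1)
  zero <- table$ss < 1e-12 * max(1, sum(data$y^2))
  table$F[zero] <- 0
  table$p[zero] <- 1
  if (gg) {
    ka <- nlevels(data$A)
    kb <- nlevels(data$B)
    wide <- stats::xtabs(y ~ subject + interaction(A, B), data = data)
    Y <- matrix(as.numeric(wide), nrow = nrow(wide))
    Ca <- .orth_contrasts(ka)
    Cb <- .orth_contrasts(kb)
    ones <- function(k) matrix(1 / sqrt(k), k, 1)
    kron <- function(x, y) kronecker(y, x)  # cells vary A fastest
    Cs <- list(kron(Ca, ones(kb)), kron(ones(ka), Cb), kron(Ca, Cb))
    table$epsilon <- vapply(Cs, function(C) .gg_epsilon(Y, C), numeric(1))
    table$p_gg <- stats::pf(table$F, table$epsilon * table$df1,
                            table$epsilon * table$df2, lower.tail = FALSE)
  }
  rownames(table) <- NULL
  structure(list(table = table, data = data, fit = fit,
                 factors = c(a = a, b = b)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey post-hoc pairwise comparisons for a repeated-measures effect
#'
#' Compares all level pairs of one main effect using the studentised-range
#' distribution with the effect's own error stratum (mean square and degrees
#' of freedom), the standard Tukey HSD construction for within-subject
#' factors.
#'
#' @param fit An `rm_anova` object.
#' @param effect Which factor to compare (its original column name).
#' @return Data frame: `level_1`, `level_2`, `diff`, `se`, `p_adj`,
#'   `p_unadj`.
#' @export
tukey_pairs <- function(fit, effect) {
  which_f <- names(fit$factors)[match(effect, fit$factors)]
  if (is.na(which_f)) stopf("effect must be one of: %s",
                            paste(fit$factors, collapse = ", "))
  data <- fit$data
  f <- data[[toupper(which_f)]]
  # error MS and df for this effect's stratum
  stratum <- paste0("Error: subject:", toupper(which_f))
  s <- summary(fit$fit)[[stratum]][[1]]
  rn <- trimws(rownames(s))
  ms_err <- s$`Mean Sq`[match("Residuals", rn)]
  df_err <- s$Df[match("Residuals", rn)]
  means <- tapply(data$y, f, mean)
  k <- length(means)
  n_per <- length(data$y) / k
  pairs <- utils::combn(names(means), 2)
  diffs <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(2 * ms_err / n_per)
  q <- abs(diffs) / sqrt(ms_err / n_per)
  data.frame(level_1 = pairs[1, ], level_2 = pairs[2, ],
             diff = as.numeric(diffs), se = se,
             p_adj = stats::ptukey(q, k, df_err, lower.tail = FALSE),
             p_unadj = 2 * stats::pt(abs(diffs) / se, df_err, lower.tail = FALSE),
             row.names = NULL)
}
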