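# F ratio that treats numerically-zero mean squares (relative to the data
# scale) as exact zeros, so constant tables give F = 0 rather than noise/noise.
.safe_F <- function(ms, ms_e, scale) {
  tol <- 1e-12 * scale
  if (ms <= tol) return(0)
  if (ms_e <= tol) return(Inf)
  ms / ms_e
}

#' One-way repeated-measures ANOVA
#'
#' Fixed-effects repeated-measures F test for a balanced within-subject
#' design: `F = MS_condition / MS_(condition x subject)`, with
#' `df = (k - 1, (k - 1)(n - 1))` for `k` levels and `n` subjects (so a
#' 4-level, 5-subject dose-response table yields df (3, 12), and 4 treatment
#' conditions over 13 subjects yield df (3, 36)). Computed via
#' [stats::aov()] with the subject term absorbing between-subject variance.
#'
#' @param table data.frame with columns `subject`, `level`, `value`; every
#'   subject must appear exactly once at every level.
#' @return Object of class `rm_anova`: `F`, `df1`, `df2`, `p`, plus the
#'   mean-square components.
#' @export
one_way_rm_anova <- function(table) {
  if (!all(c("subject", "level", "value") %in% names(table)))
    stopf("table must have columns subject, level, value")
  tab <- table(table$subject, table$level)
  if (any(tab != 1L))
    stopf("unbalanced repeated-measures table: every subject needs exactly one value per level")
  d <- data.frame(subject = factor(table$subject),
                  level = factor(table$level),
                  value = as.numeric(table$value))
  fit <- aov(value ~ level + subject, data = d)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  ms_cond <- sm[rn == "level", "Mean Sq"]
  ms_err <- sm[rn == "Residuals", "Mean Sq"]
  df1 <- sm[rn == "level", "Df"]
  df2 <- sm[rn == "Residuals", "Df"]
  Fv <- .safe_F(ms_cond, ms_err, mean(d$value^2) + 1)
  p <- if (is.finite(Fv)) pf(Fv, df1, df2, lower.tail = FALSE) else 0
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p,
                 ms_condition = ms_cond, ms_error = ms_err,
                 k = nlevels(d$level), n = nlevels(d$subject)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Balanced two-factor within-subject decomposition (e.g. pulse order x
#' inter-pulse interval), with each effect tested against its own
#' subject-interaction stratum, as in `aov(value ~ A * B +
#' Error(subject/(A * B)))`. For 2 orders, 3 intervals and 4 subjects the
#' interaction has df (2, 6).
#'
#' @param table data.frame with columns `subject`, `factor1`, `factor2`,
#'   `value`; one value per subject per cell.
#' @return List of `rm_anova`-like entries `factor1`, `factor2`,
#'   `interaction`, each with `F`, `df1`, `df2`, `p`.
#' @export
two_way_rm_anova <- function(table) {
  need <- c("subject", "factor1", "factor2", "value")
  if (!all(need %in% names(table)))
    stopf("table must have columns subject, factor1, factor2, value")
  tab <- table(table$subject, table$factor1, table$factor2)
  if (any(tab != 1L))
    stopf("unbalanced design: every subject needs one value per (factor1, factor2) cell")
  d <- data.frame(subject = factor(table$subject),
                  A = factor(table$factor1), B = factor(table$factor2),
                  value = as.numeric(table$value))
  fit <- aov(value ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    s <- sm[[stratum]][[1]]
    row <- trimws(rownames(s)) == term
    ms <- s[row, "Mean Sq"]; df1 <- s[row, "Df"]
    res <- trimws(rownames(s)) == "Residuals"
    ms_e <- s[res, "Mean Sq"]; df2 <- s[res, "Df"]
    Fv <- .safe_F(ms, ms_e, mean(d$value^2) + 1)
    p <- if (is.finite(Fv)) pf(Fv, df1, df2, lower.tail = FALSE) else 0
    list(F = Fv, df1 = df1, df2 = df2, p = p)
  }
  list(factor1 = pull("Error: subject:A", "A"),
       factor2 = pull("Error: subject:B", "B"),
       interaction = pull("Error: subject:A:B", "A:B"))
}
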