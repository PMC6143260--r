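#' Amplification efficiency from a serial-dilution standard curve
#'
#' Ordinary least squares of mean Ct on log10(dilution); the amplification
#' efficiency is `E = 10^(-1/slope) - 1` (E = 1 for perfect doubling, slope
#' -3.3219). Curves with E outside \code{[0.9, 1.1]} or R^2 <= 0.99 are
#' flagged.
#'
#' @param dilution relative template amounts (e.g. 1, 0.1, 0.01, ...).
#' @param ct mean Ct per dilution point.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `flagged`.
#' @export
standard_curve <- function(dilution, ct) {
  if (length(dilution) < 3L) stop("need at least 3 dilution points")
  stopifnot(length(dilution) == length(ct), all(dilution > 0))
  fit <- lm(ct ~ log10(dilution))
  slope <- coef(fit)[[2L]]
  eff <- 10^(-1 / slope) - 1
  r2 <- summary(fit)$r.squared
  structure(list(slope = slope, intercept = coef(fit)[[1L]],
                 efficiency = eff, r_squared = r2,
                 flagged = eff < 0.9 || eff > 1.1 || r2 <= 0.99),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.3f, efficiency %.3f, R^2 %.4f%s\n",
              x$slope, x$efficiency, x$r_squared,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Relative expression by the 2^-deltaCt method
#'
#' Per sample, replicate Ct values are averaged per gene, deltaCt is the
#' target minus the reference (housekeeping) mean Ct, and relative expression
#' is 2^-deltaCt. Samples missing the reference gene are dropped with a
#' warning.
#'
#' @param ct `ct_table`-like data.frame (sample / gene / ct, optionally
#'   replicate).
#' @param target_gene target gene name.
#' @param reference_gene reference gene name (default `"ubq"`).
#' @return data.frame sample / delta_ct / rel_expr.
#' @export
relative_expression <- function(ct, target_gene, reference_gene = "ubq") {
  tg <- ct[ct$gene == target_gene, ]
  rf <- ct[ct$gene == reference_gene, ]
  if (!nrow(tg)) stop("no Ct rows for target gene ", target_gene)
  mean_by <- function(d) tapply(d$ct, d$sample, mean)
  mt <- mean_by(tg)
  mr <- mean_by(rf)
  miss <- setdiff(names(mt), names(mr))
  if (length(miss)) {
    warning("dropping samples without reference-gene Ct: ",
            paste(miss, collapse = ", "))
  }
  smp <- intersect(names(mt), names(mr))
  dct <- mt[smp] - mr[smp]
  data.frame(sample = smp, delta_ct = unname(dct),
             rel_expr = unname(2^(-dct)))
}

#' Two-group comparison of relative expression
#'
#' Compares testes against ovaries on log-transformed 2^-deltaCt values with
#' a t-test (Welch by default; `var_equal = TRUE` for Student's t). The fold
#' change is the ratio of arithmetic group means of 2^-deltaCt
#' (testes/ovaries); a geometric-mean fold change is also reported.
#' Kolmogorov-Smirnov normality checks (per group, on log values with
#' estimated moments) and a Levene variance-homogeneity test are reported
#' but never gate the comparison.
#'
#' @param rel result of [relative_expression()].
#' @param design [cohort_design()] (the `sex` column groups the samples).
#' @param var_equal use Student's t instead of Welch.
#' @return list of class `expression_result`: `fold_change`,
#'   `fold_change_geometric`, `group_means`, `t`, `df`, `p`, `normality_p`
#'   (per group), `levene_p`, `n`.
#' @export
compare_groups <- function(rel, design, var_equal = FALSE) {
  sex <- design$sex[match(rel$sample, design$sample)]
  if (anyNA(sex)) stop("samples missing from design")
  vt <- rel$rel_expr[sex == "testis"]
  vo <- rel$rel_expr[sex == "ovary"]
  if (length(vt) < 2L || length(vo) < 2L) stop("need >= 2 samples per sex")
  lt <- log(vt); lo <- log(vo)
  tt <- tryCatch(t.test(lt, lo, var.equal = var_equal),
                 error = function(e) NULL)
  ksp <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  lev <- tryCatch(
    car::leveneTest(c(lt, lo), factor(rep(c("t", "o"), c(length(lt), length(lo)))))[1, "Pr(>F)"],
    error = function(e) NA_real_)
  structure(list(
    fold_change = mean(vt) / mean(vo),
    fold_change_geometric = exp(mean(lt) - mean(lo)),
    group_means = c(testis = mean(vt), ovary = mean(vo)),
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p = if (is.null(tt)) NA_real_ else tt$p.value,
    normality_p = c(testis = ksp(lt), ovary = ksp(lo)),
    levene_p = lev,
    n = c(testis = length(vt), ovary = length(vo))),
    class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("Relative expression: fold change (testes/ovaries) %.2f, t = %.2f, p = %.3g\n",
              x$fold_change, x$t, x$p))
  cat(sprintf("  group means 2^-dCt: testis %.3g (n=%d), ovary %.3g (n=%d)\n",
              x$group_means["testis"], x$n["testis"],
              x$group_means["ovary"], x$n["ovary"]))
  invisible(x)
}
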