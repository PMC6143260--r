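#' Per-sample amplicon-level methylation values
#'
#' The per-sample value of an amplicon is the mean methylation over its CpG
#' sites (missing cells excluded).
#'
#' @param mm `meth_matrix`.
#' @return samples x amplicons numeric matrix.
#' @export
amplicon_sample_means <- function(mm) {
  amps <- unique(mm$sites$amplicon_id)
  out <- sapply(amps, function(aid) {
    cols <- mm$sites$amplicon_id == aid
    rowMeans(mm$pct[, cols, drop = FALSE], na.rm = TRUE)
  })
  matrix(out, nrow = length(mm$samples),
         dimnames = list(mm$samples, amps))
}

#' Group summary of amplicon methylation
#'
#' Summarises each amplicon per sex-by-origin group (mean, SD, n over the
#' samples' amplicon-level values) and overall. The overall mean is the
#' unweighted average of the four group means; the overall SD is taken over
#' all samples pooled (the definition consistent with published summaries,
#' where group sizes differ but the overall column averages the groups).
#'
#' @param mm `meth_matrix`.
#' @param design [cohort_design()] covering the matrix's samples.
#' @param alpha significance level for the group letter display
#'   (default 0.01 at amplicon level).
#' @return object of class `group_summary`: `groups` (long data.frame
#'   amplicon_id / group / mean_pct / sd_pct / n / letters) and `overall`
#'   (amplicon_id / overall_mean / overall_sd).
#' @export
amplicon_group_summary <- function(mm, design, alpha = 0.01) {
  vals <- amplicon_sample_means(mm)
  grp <- design$group[match(rownames(vals), design$sample)]
  if (anyNA(grp)) stop("samples missing from design")
  groups <- unique(design$group)
  rows <- list()
  overall <- list()
  for (aid in colnames(vals)) {
    v <- vals[, aid]
    gm <- vapply(groups, function(g) mean(v[grp == g], na.rm = TRUE), 0)
    gs <- vapply(groups, function(g) sd(v[grp == g], na.rm = TRUE), 0)
    gn <- vapply(groups, function(g) sum(grp == g & !is.na(v)), 0L)
    if (any(gn == 0L)) warning("empty group for amplicon ", aid)
    letters <- tryCatch(
      compact_letters(v, grp, alpha = alpha),
      error = function(e) setNames(rep(NA_character_, length(groups)), groups))
    rows[[aid]] <- data.frame(amplicon_id = aid, group = groups,
                              mean_pct = gm, sd_pct = gs, n = gn,
                              letters = letters[groups], row.names = NULL)
    overall[[aid]] <- data.frame(amplicon_id = aid,
                                 overall_mean = overall_group_mean(gm),
                                 overall_sd = sd(v, na.rm = TRUE))
  }
  structure(list(groups = do.call(rbind, c(rows, make.row.names = FALSE)),
                 overall = do.call(rbind, c(overall, make.row.names = FALSE))),
            class = "group_summary")
}

#' Overall mean as the unweighted average of group means
#'
#' @param group_means numeric vector of per-group means.
#' @return their plain average.
#' @examples
#' overall_group_mean(c(92.5, 88.0, 44.1, 54.0))  # 69.65, prints as 69.6
#' @export
overall_group_mean <- function(group_means) mean(group_means, na.rm = TRUE)

#' @export
print.group_summary <- function(x, ...) {
  cat("Amplicon group summary (mean % +/- SD):\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis test at every CpG site
#'
#' Rank-based H with tie correction and a chi-square reference distribution
#' on k-1 degrees of freedom, per CpG site across the design groups. No
#' cross-site multiple-testing correction is applied by default (per-site
#' testing, as in the study); set `p_adjust = "BH"` for a
#' Benjamini-Hochberg-corrected column.
#'
#' @param mm `meth_matrix`.
#' @param design [cohort_design()].
#' @param alpha per-site significance level for letters (default 0.05).
#' @param p_adjust optional method for an adjusted p column ("none" default).
#' @param letters compute per-site compact letter displays (default TRUE).
#' @return data.frame site_id / gene / amplicon_id / position / H / df / p
#'   (+ p_adj) and one letter column per group when requested.
#' @export
kruskal_wallis_per_cpg <- function(mm, design, alpha = 0.05,
                                   p_adjust = "none", letters = TRUE) {
  grp <- design$group[match(mm$samples, design$sample)]
  groups <- unique(design$group)
  res <- mm$sites[, c("site_id", "gene", "amplicon_id", "position")]
  res$H <- NA_real_
  res$df <- length(groups) - 1L
  res$p <- NA_real_
  lets <- matrix(NA_character_, nrow(res), length(groups),
                 dimnames = list(NULL, paste0("letter_", groups)))
  for (j in seq_len(nrow(res))) {
    v <- mm$pct[, j]
    ok <- !is.na(v)
    if (length(unique(grp[ok])) < 2L) next
    if (length(unique(v[ok])) == 1L) {
      res$H[j] <- 0; res$p[j] <- 1
      lets[j, ] <- "a"
      next
    }
    kw <- kruskal.test(v[ok], factor(grp[ok]))
    res$H[j] <- unname(kw$statistic)
    res$df[j] <- unname(kw$parameter)
    res$p[j] <- kw$p.value
    if (letters) {
      cl <- compact_letters(v[ok], grp[ok], alpha = alpha)
      lets[j, match(paste0("letter_", names(cl)), colnames(lets))] <- cl
    }
  }
  if (!identical(p_adjust, "none")) res$p_adj <- p.adjust(res$p, p_adjust)
  if (letters) res <- cbind(res, as.data.frame(lets))
  res
}

#' Pairwise Dunn post-hoc tests
#'
#' Rank-based Dunn z statistics with tie correction on the joint ranking,
#' two-sided p values, Holm-adjusted by default.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param p_adjust adjustment method (default "holm").
#' @return data.frame group1 / group2 / z / p / p_adj.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups[ok])
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- unique(groups)
  mean_r <- vapply(gl, function(g) mean(r[groups == g]), 0)
  n_g <- vapply(gl, function(g) sum(groups == g), 0L)
  pairs <- utils::combn(gl, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[g1] + 1 / n_g[g2]))
    if (se == 0) {  # every observation tied: no evidence of any difference
      z[k] <- 0; p[k] <- 1
    } else {
      z[k] <- (mean_r[g1] - mean_r[g2]) / se
      p[k] <- 2 * pnorm(-abs(z[k]))
    }
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             p_adj = p.adjust(p, p_adjust))
}

#' Compact letter display from Dunn post-hoc tests
#'
#' Groups sharing a letter are not significantly different at `alpha` after
#' Holm adjustment of pairwise Dunn tests; groups sharing no letter are.
#' Letters are assigned with the insertion algorithm and are invariant under
#' group relabelling (up to letter names).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha significance level (default 0.05).
#' @param p_adjust adjustment method for the pairwise p values.
#' @return named character vector of letter strings, one per group (in order
#'   of first appearance).
#' @export
compact_letters <- function(values, groups, alpha = 0.05, p_adjust = "holm") {
  gl <- unique(as.character(groups[!is.na(values)]))
  if (length(gl) < 2L) return(setNames(rep("a", length(gl)), gl))
  dt <- dunn_test(values, groups, p_adjust)
  sig <- matrix(FALSE, length(gl), length(gl), dimnames = list(gl, gl))
  for (k in seq_len(nrow(dt))) {
    s <- dt$p_adj[k] < alpha
    sig[dt$group1[k], dt$group2[k]] <- s
    sig[dt$group2[k], dt$group1[k]] <- s
  }
  letters_from_significance(sig)
}

# Letter sets are the maximal cliques of the "not significantly different"
# graph (the canonical compact-letter-display construction); with a handful
# of groups these are enumerated exhaustively over subsets.
letters_from_significance <- function(sig) {
  gl <- rownames(sig)
  k <- length(gl)
  is_clique <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    prs <- utils::combn(idx, 2L)
    !any(sig[cbind(prs[1L, ], prs[2L, ])])
  }
  subsets <- lapply(seq_len(2^k) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  cliques <- Filter(function(s) length(s) > 0L && is_clique(s), subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                TRUE))
  }, cliques)
  maximal <- maximal[order(vapply(maximal, min, 0L))]
  out <- setNames(rep("", k), gl)
  for (s in seq_along(maximal)) {
    for (g in maximal[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

#' Sex-difference table across a gene's CpG sites
#'
#' Per gene, the testes-minus-ovaries methylation difference in percentage
#' points. `"pooled"` (default) averages all testis cells (samples x the
#' gene's CpGs) and subtracts the ovary average; `"group_means"` averages the
#' two origin-group means within each sex first. Significance is a
#' Mann-Whitney (two-group Kruskal-Wallis) test on the per-sample gene-level
#' means across sexes.
#'
#' @param mm `meth_matrix`.
#' @param design [cohort_design()].
#' @param mode `"pooled"` or `"group_means"`.
#' @return data.frame gene / diff_pct / p.
#' @export
sex_difference_table <- function(mm, design, mode = c("pooled", "group_means")) {
  mode <- match.arg(mode)
  sex <- design$sex[match(mm$samples, design$sample)]
  grp <- design$group[match(mm$samples, design$sample)]
  genes <- unique(mm$sites$gene)
  out <- lapply(genes, function(g) {
    cols <- mm$sites$gene == g
    sub <- mm$pct[, cols, drop = FALSE]
    sample_means <- rowMeans(sub, na.rm = TRUE)
    if (mode == "pooled") {
      d <- mean(sub[sex == "testis", ], na.rm = TRUE) -
        mean(sub[sex == "ovary", ], na.rm = TRUE)
    } else {
      gsex <- function(sx) {
        gg <- unique(grp[sex == sx])
        mean(vapply(gg, function(x) mean(sub[grp == x, ], na.rm = TRUE), 0))
      }
      d <- gsex("testis") - gsex("ovary")
    }
    p <- tryCatch(
      stats::wilcox.test(sample_means[sex == "testis"],
                         sample_means[sex == "ovary"], exact = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(gene = g, diff_pct = d, p = p)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Exponential fit of methylation against CpG density
#'
#' Least-squares fit of `methylation = a * exp(-b * density)`, the inverse
#' exponential relationship between an amplicon's CpG density (sites per
#' 100 bp) and its methylation level: CpG-dense (island-like) amplicons tend
#' to be hypomethylated. Start values come from a log-linear regression.
#'
#' @param density CpG sites per 100 bp (> 0).
#' @param methylation percent methylation.
#' @return list: `a`, `b`, `r_squared`, `residuals`, `fit` (the nls object).
#' @export
density_methylation_fit <- function(density, methylation) {
  stopifnot(length(density) == length(methylation), length(density) >= 3,
            all(density > 0))
  lm0 <- lm(log(pmax(methylation, 1e-6)) ~ density)
  start <- list(a = exp(coef(lm0)[[1L]]), b = -coef(lm0)[[2L]])
  fit <- tryCatch(
    nls(methylation ~ a * exp(-b * density), start = start,
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  res <- resid(fit)
  ss_tot <- sum((methylation - mean(methylation))^2)
  list(a = coef(fit)[["a"]], b = coef(fit)[["b"]],
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
       residuals = res, fit = fit)
}
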