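#' Default gonad cohort design
#'
#' The study design the simulator emulates: four sex-by-origin groups of
#' adult barramundi gonads — captive testes (n = 14), wild testes (n = 10),
#' captive ovaries (n = 14) and wild ovaries (n = 4), 42 samples in all
#' (24 testes, 18 ovaries).
#'
#' @param n_captive_testis,n_wild_testis,n_captive_ovary,n_wild_ovary group
#'   sizes; defaults are the study's.
#' @return data.frame with columns `sample`, `sex` ("testis"/"ovary"),
#'   `origin` ("captive"/"wild") and `group` (sex_origin label), class
#'   `cohort_design`.
#' @export
cohort_design <- function(n_captive_testis = 14L, n_wild_testis = 10L,
                          n_captive_ovary = 14L, n_wild_ovary = 4L) {
  grp <- function(sex, origin, n) {
    if (n < 1L) stop("each group needs n >= 1")
    data.frame(sample = sprintf("%s_%s_%02d", substr(sex, 1, 1), origin, seq_len(n)),
               sex = sex, origin = origin,
               group = paste(origin, sex, sep = "_"))
  }
  d <- rbind(grp("testis", "captive", n_captive_testis),
             grp("testis", "wild", n_wild_testis),
             grp("ovary", "captive", n_captive_ovary),
             grp("ovary", "wild", n_wild_ovary))
  d$sample <- make.unique(d$sample)
  class(d) <- c("cohort_design", "data.frame")
  d
}

#' Default group methylation truth for the barramundi panel
#'
#' Group-level mean and SD (percent methylation) per amplicon and
#' sex-by-origin group, as published for the default panel. These are the
#' generative parameters the simulator draws per-sample methylation from.
#'
#' @return data.frame amplicon_id / group / mean_pct / sd_pct, class
#'   `methylation_truth`.
#' @export
lates_methylation_truth <- function() {
  amp <- c("dmrt1 (1)", "dmrt1 (2)", "nr5a2 (1)", "nr5a2 (2)", "cyp19a1",
           "amh", "foxl2 (1)", "foxl2 (2)", "sox8 (1)", "sox8 (2)", "sox9")
  # columns: captive_testis, wild_testis, captive_ovary, wild_ovary
  means <- rbind(
    c(41.2, 67.8, 58.6, 71.0),
    c(6.8, 6.5, 17.0, 16.3),
    c(10.2, 10.7, 16.2, 20.6),
    c(12.9, 13.4, 59.3, 59.3),
    c(92.5, 88.0, 44.1, 54.0),
    c(94.0, 76.6, 59.5, 46.0),
    c(3.7, 6.9, 5.8, 4.0),
    c(6.4, 8.61, 7.55, 8.5),
    c(1.5, 2.0, 2.3, 2.4),
    c(7.1, 10.0, 9.1, 10.5),
    c(0.8, 1.1, 1.1, 1.3))
  sds <- rbind(
    c(17.1, 20.2, 14.6, 12.3),
    c(6.9, 7.3, 9.5, 10.4),
    c(1.3, 1.4, 4.8, 4.4),
    c(2.2, 1.1, 12.4, 12.9),
    c(2.0, 8.2, 8.7, 8.9),
    c(1.4, 3.0, 2.2, 2.7),
    c(0.7, 0.6, 0.8, 0.7),
    c(0.9, 0.9, 1.1, 1.0),
    c(1.2, 1.0, 1.3, 2.6),
    c(1.2, 1.7, 1.5, 2.5),
    c(0.8, 0.9, 0.7, 0.7))
  groups <- c("captive_testis", "wild_testis", "captive_ovary", "wild_ovary")
  out <- data.frame(
    amplicon_id = rep(amp, each = length(groups)),
    group = rep(groups, times = length(amp)),
    mean_pct = as.vector(t(means)),
    sd_pct = as.vector(t(sds)))
  class(out) <- c("methylation_truth", "data.frame")
  out
}
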