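#' Generative truth for the qPCR simulator
#'
#' @param genes data.frame with columns `gene`, `fold_change`
#'   (testes:ovaries ratio of mean relative expression, > 0) and `base_ct`
#'   (ovary-group target Ct at the reference expression level).
#' @param reference_gene reference (housekeeping) gene name.
#' @param ref_base_ct reference-gene Ct level.
#' @param ct_noise_sd replicate-level Gaussian Ct noise (cycles).
#' @param replicates technical replicates per sample and gene.
#' @return list of class `qpcr_truth`.
#' @export
qpcr_truth <- function(genes = data.frame(gene = "dmrt1", fold_change = 1.9,
                                          base_ct = 28),
                       reference_gene = "ubq", ref_base_ct = 20,
                       ct_noise_sd = 0.2, replicates = 3L) {
  stopifnot(all(genes$fold_change > 0))
  structure(list(genes = genes, reference_gene = reference_gene,
                 ref_base_ct = ref_base_ct, ct_noise_sd = ct_noise_sd,
                 replicates = as.integer(replicates)),
            class = "qpcr_truth")
}

#' Simulate an RT-qPCR Ct table
#'
#' For every sample and target gene, replicate Ct values are drawn as
#' `base_ct - log2(expression) + noise`, where expression is the gene's fold
#' change for testis samples and 1 for ovary samples, so the testes:ovaries
#' ratio of mean relative expression (2^-deltaCt against the reference gene)
#' equals the configured fold change in expectation. Reference-gene Ct values
#' are drawn around their own base level.
#'
#' @param qtruth [qpcr_truth()].
#' @param design [cohort_design()] (only the `sex` column is used).
#' @param seed RNG seed.
#' @return data.frame sample / group / sex / gene / replicate / ct, class
#'   `ct_table`.
#' @export
simulate_qpcr <- function(qtruth = qpcr_truth(), design = cohort_design(),
                          seed = 1L) {
  set.seed(substream_seed(seed, "qpcr"))
  reps <- qtruth$replicates
  rows <- list()
  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]
    sex <- design$sex[si]
    for (gi in seq_len(nrow(qtruth$genes))) {
      g <- qtruth$genes[gi, ]
      expr <- if (sex == "testis") g$fold_change else 1
      ct <- g$base_ct - log2(expr) + rnorm(reps, 0, qtruth$ct_noise_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = smp, group = design$group[si], sex = sex,
                   gene = g$gene, replicate = seq_len(reps), ct = ct)
    }
    ct_ref <- qtruth$ref_base_ct + rnorm(reps, 0, qtruth$ct_noise_sd)
    rows[[length(rows) + 1L]] <-
      data.frame(sample = smp, group = design$group[si], sex = sex,
                 gene = qtruth$reference_gene, replicate = seq_len(reps),
                 ct = ct_ref)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ct_table", "data.frame")
  out
}
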