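test_that("synthesized panel sequences honour declared lengths, CpGs and primers", {
  p <- synthesize_panel_sequences(lates_panel(), seed = 3)
  for (a in p$amplicons) {
    expect_identical(nchar(a$sequence), a$declared_length)
    expect_identical(nrow(enumerate_cpg_sites(a$sequence, a$start)),
                     a$declared_cpg_count)
    # converted template begins with the forward core (R1) and its reverse
    # complement with the reverse core (R2); the genomic footprints differ
    core_f <- strip_overhang(a$primers$seq_fwd)$core
    conv <- bisulfite_convert(a$sequence)
    expect_true(startsWith(conv, core_f))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(conv)))
    expect_true(startsWith(rc, strip_overhang(a$primers$seq_rev)$core))
    v <- validate_bisulfite_primers(a$primers, template = a$sequence)
    expect_true(v$anneals_converted)
  }
})

test_that("methylation profiles are Beta-distributed around the group truth", {
  pan <- synthesize_panel_sequences(lates_panel(), seed = 1)
  pan$amplicons <- pan$amplicons["cyp19a1"]
  des <- tiny_design(14L)
  tr <- flat_truth(pan, unique(des$group), mean_pct = 92.5, sd_pct = 2.0)
  # empirical mean across repeated seeds within ~2 SE of the configured mean
  means <- vapply(1:20, function(s) {
    pr <- sample_methylation_profiles(tr, des, pan, seed = s, cpg_jitter_sd = 2)
    mean(pr$true_meth) * 100
  }, 0)
  se <- 2.0 / sqrt(14 * 20)
  expect_lt(abs(mean(means) - 92.5), 2 * se + 0.1)
  # degenerate truths
  tr0 <- flat_truth(pan, unique(des$group), mean_pct = 50, sd_pct = 0)
  pr0 <- sample_methylation_profiles(tr0, des, pan, seed = 1, cpg_jitter_sd = 0)
  expect_true(all(pr0$true_meth == 0.5))
  tr1 <- flat_truth(pan, unique(des$group), mean_pct = 100, sd_pct = 0)
  pr1 <- sample_methylation_profiles(tr1, des, pan, seed = 1, cpg_jitter_sd = 0)
  expect_true(all(pr1$true_meth == 0.999))  # clipped point mass
  # infeasible SD falls back with a warning
  des1 <- tiny_design(1L)
  trbad <- flat_truth(pan, unique(des1$group), mean_pct = 50, sd_pct = 60)
  expect_warning(sample_methylation_profiles(trbad, des1, pan, seed = 1),
                 "point mass")
})

test_that("simulated reads reflect methylation state exactly when noise-free", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  cfg <- simulation_config(coverage_per_amplicon = 50L,
                           conversion_failure_rate = 0,
                           sequencing_error_rate = 0, read_length = 60L)
  k <- a$declared_cpg_count
  # fully methylated: C at every CpG, T at every non-CpG C
  rd1 <- simulate_amplicon_reads("s1", a, rep(1, k), cfg, seed = 1)
  cpg_off <- enumerate_cpg_sites(a$sequence, a$start)$offset + 1L
  for (o in cpg_off) expect_true(all(substr(rd1$r1, o, o) == "C"))
  ref <- strsplit(a$sequence, "")[[1L]]
  noncpg <- setdiff(which(ref == "C"), cpg_off)
  for (o in noncpg) expect_true(all(substr(rd1$r1, o, o) == "T"))
  # fully unmethylated, no failures: no C anywhere
  rd0 <- simulate_amplicon_reads("s1", a, rep(0, k), cfg, seed = 1)
  expect_false(any(grepl("C", rd0$r1)))
  expect_false(any(grepl("G", rd0$r2)))  # R2 is the complement strand
})

test_that("per-CpG C fraction is a binomial estimate of the truth", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  cfg <- simulation_config(coverage_per_amplicon = 10000L,
                           conversion_failure_rate = 0,
                           sequencing_error_rate = 0, read_length = 60L)
  rd <- simulate_amplicon_reads("s1", a, rep(0.5, a$declared_cpg_count), cfg,
                                seed = 99)
  cpg_off <- enumerate_cpg_sites(a$sequence, a$start)$offset + 1L
  for (o in cpg_off) {
    frac <- mean(substr(rd$r1, o, o) == "C")
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  }
})

test_that("conversion failures at non-CpG cytosines converge to the configured rate", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  cfg <- simulation_config(coverage_per_amplicon = 10000L,
                           conversion_failure_rate = 0.02,
                           sequencing_error_rate = 0, read_length = 60L)
  rd <- simulate_amplicon_reads("s1", a, rep(0, a$declared_cpg_count), cfg,
                                seed = 5)
  ref <- strsplit(a$sequence, "")[[1L]]
  cpg_off <- enumerate_cpg_sites(a$sequence, a$start)$offset + 1L
  noncpg <- setdiff(which(ref == "C"), cpg_off)
  obs <- mean(unlist(lapply(noncpg, function(o) substr(rd$r1, o, o) == "C")))
  expect_lt(abs(obs - 0.02), 3 * sqrt(0.02 * 0.98 / (10000 * length(noncpg))))
})

test_that("cohort simulation is deterministic and conserves read counts", {
  pan <- toy_panel()
  des <- cohort_design(1L, 1L, 1L, 1L)
  tr <- flat_truth(pan, unique(des$group), 50, 5)
  cfg <- simulation_config(coverage_per_amplicon = 10L, read_length = 54L)
  s1 <- simulate_cohort(pan, des, tr, cfg)
  s2 <- simulate_cohort(pan, des, tr, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  # counts: samples x amplicons x coverage
  total <- sum(vapply(s1$reads, nrow, 0L))
  expect_identical(total, nrow(des) * length(pan$amplicons) * 10L)
  # FASTQ round-trip through files is byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(pan, des, tr, cfg, dir = d1)
  simulate_cohort(pan, des, tr, cfg, dir = d2)
  f1 <- list.files(d1, "fastq$", full.names = TRUE)
  f2 <- list.files(d2, "fastq$", full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("the default cohort matches the study design", {
  des <- cohort_design()
  expect_identical(nrow(des), 42L)
  expect_identical(sum(des$sex == "testis"), 24L)
  expect_identical(sum(des$sex == "ovary"), 18L)
  expect_identical(as.vector(table(des$group)[c("captive_testis", "wild_testis",
                                                "captive_ovary", "wild_ovary")]),
                   c(14L, 10L, 14L, 4L))
})

test_that("amplicons longer than a read pair are rejected", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  cfg <- simulation_config(read_length = 20L, coverage_per_amplicon = 5L)
  expect_error(simulate_amplicon_reads("s", a, rep(0.5, a$declared_cpg_count), cfg),
               "2 x read length")
})

test_that("qPCR simulation encodes fold change as a deltaCt shift", {
  des <- cohort_design(4L, 1L, 4L, 1L)
  # noise 0, fold 2: testes deltaCt exactly 1 cycle lower
  qt <- qpcr_truth(genes = data.frame(gene = "dmrt1", fold_change = 2,
                                      base_ct = 28),
                   ct_noise_sd = 0, replicates = 3L)
  ct <- simulate_qpcr(qt, des, seed = 1)
  rel <- relative_expression(ct, "dmrt1")
  sex <- des$sex[match(rel$sample, des$sample)]
  dt_t <- unique(rel$delta_ct[sex == "testis"])
  dt_o <- unique(rel$delta_ct[sex == "ovary"])
  expect_equal(dt_o - dt_t, 1)
  # fold 1, noise 0: identical deltaCt everywhere
  qt1 <- qpcr_truth(genes = data.frame(gene = "dmrt1", fold_change = 1,
                                       base_ct = 28), ct_noise_sd = 0)
  rel1 <- relative_expression(simulate_qpcr(qt1, des, seed = 1), "dmrt1")
  expect_equal(length(unique(round(rel1$delta_ct, 10))), 1L)
})

test_that("toy isoform simulation encodes the published splice structure", {
  iso <- simulate_isoforms(seed = 4)
  # testis cyp19a1: exon1 196 -> 163, exon2 151 -> 101
  ch <- iso$cyp19a1$isoforms$testis$exon_chain
  expect_identical(ch$end[1L] - ch$start[1L] + 1L, 163L)
  expect_identical(ch$end[2L] - ch$start[2L] + 1L, 101L)
  full <- iso$cyp19a1$model$exons
  expect_identical(full$end[1L] - full$start[1L] + 1L, 196L)
  expect_identical(full$end[2L] - full$start[2L] + 1L, 151L)
  # ovary dmrt1 lacks the DM domain, testis has it
  expect_false(domain_present(iso$dmrt1$isoforms$ovary, iso$dmrt1$model, "DM"))
  expect_true(domain_present(iso$dmrt1$isoforms$testis, iso$dmrt1$model, "DM"))
  # alternative first exon is 59 bp
  expect_identical(iso$dmrt1$isoforms$ovary$exon_chain$end[1L] -
                     iso$dmrt1$isoforms$ovary$exon_chain$start[1L] + 1L, 59L)
})
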