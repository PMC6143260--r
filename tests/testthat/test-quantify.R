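q33 <- function(qs) intToUtf8(qs + 33L)

test_that("quality trimming removes the 3' run below the accuracy floor", {
  rd <- data.frame(seq = "ACGTACGTAC",
                   qual = q33(c(30, 30, 30, 30, 30, 30, 30, 30, 12, 10)))
  out <- quality_trim(rd)
  expect_identical(out$seq, "ACGTACGT")
  # all high-quality: identity
  rd2 <- data.frame(seq = "ACGT", qual = q33(rep(14, 4)))
  expect_identical(quality_trim(rd2)$seq, "ACGT")
  # trimming stops at the first passing base from the end: interior Q10 kept
  rd3 <- data.frame(seq = "ACGTAC", qual = q33(c(10, 30, 10, 30, 10, 30)))
  expect_identical(quality_trim(rd3)$seq, "ACGTAC")
  # a wholly bad read becomes empty
  rd4 <- data.frame(seq = "ACG", qual = q33(c(2, 2, 2)))
  expect_identical(quality_trim(rd4)$seq, "")
  # Q13 is above the 95%-accuracy threshold (13.0103), Q13 < threshold
  expect_identical(quality_trim(data.frame(seq = "AA", qual = q33(c(30, 13))))$seq, "A")
  expect_identical(quality_trim(data.frame(seq = "AA", qual = q33(c(30, 14))))$seq, "AA")
})

test_that("length filter keeps reads at the boundary and conserves counts", {
  rd <- data.frame(seq = c(strrep("A", 99), strrep("A", 100), strrep("A", 150)))
  out <- length_filter(rd)
  expect_identical(nchar(out$seq), c(100L, 150L))
  expect_identical(attr(out, "n_removed"), 1L)
  expect_identical(nrow(out) + attr(out, "n_removed"), nrow(rd))
})

test_that("primer-prefix assignment resolves amplicons, ties and junk", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  core_f <- strip_overhang(a$primers$seq_fwd)$core
  conv <- bisulfite_convert(a$sequence)
  reads <- data.frame(
    seq = c(conv,                                  # exact forward
            paste0(strrep("T", 10), "ACACACACAC"), # junk
            substr(conv, 1, 40)),
    mate = "R1")
  got <- assign_to_amplicon(reads, pan)
  expect_identical(got, c("geneA (1)", "unassigned", "geneA (1)"))
  # R2 assignment uses the reverse core
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(conv)))
  expect_identical(assign_to_amplicon(data.frame(seq = rc, mate = "R2"), pan),
                   "geneA (1)")
  # constructed collision: two amplicons with identical forward cores tie
  pan2 <- pan
  pan2$amplicons[[2L]]$primers$seq_fwd <- pan$amplicons[[1L]]$primers$seq_fwd
  expect_identical(assign_to_amplicon(data.frame(seq = conv, mate = "R1"), pan2),
                   "unassigned")
})

test_that("bisulfite-aware alignment treats conversion as a match and errors as other", {
  pan <- toy_panel()
  a <- pan$amplicons[[1L]]
  cpg_off <- enumerate_cpg_sites(a$sequence, a$start)$offset  # 0-based
  conv <- bisulfite_convert(a$sequence)  # 0% methylated read
  al0 <- bisulfite_align(conv, a, "R1")
  expect_true(al0$accepted)
  expect_identical(al0$mismatch_count, 0L)
  expect_true(all(al0$calls == "T"))
  # 100% methylated: C exactly at CpG offsets
  cpg <- enumerate_cpg_sites(a$sequence, a$start)
  met <- bisulfite_convert(a$sequence, methylated_positions = cpg$position,
                           start = a$start)
  al1 <- bisulfite_align(met, a, "R1")
  expect_identical(names(al1$calls)[al1$calls == "C"], as.character(cpg_off))
  # a substitution at a CpG gives an "other" call and one mismatch
  bad <- met
  substr(bad, cpg_off[1L] + 1L, cpg_off[1L] + 1L) <- "A"
  alb <- bisulfite_align(bad, a, "R1")
  expect_identical(unname(alb$calls[as.character(cpg_off[1L])]), "other")
  expect_identical(alb$mismatch_count, 1L)
  # too many plain mismatches: rejected
  junk <- paste0(substr(conv, 1, 20), strrep("A", nchar(conv) - 20))
  expect_false(bisulfite_align(junk, a, "R1")$accepted)
  # R2 anchors at the amplicon 3' end
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(met)))
  al2 <- bisulfite_align(substr(rc, 1, 30), a, "R2")
  expect_true(al2$accepted)
  expect_identical(al2$offset, nchar(conv) - 30L)
})

test_that("methylation calling is the C fraction with coverage flagging", {
  pan <- toy_panel()
  pan$amplicons <- pan$amplicons[1L]
  a <- pan$amplicons[[1L]]
  k <- a$declared_cpg_count
  cfg <- simulation_config(coverage_per_amplicon = 200L,
                           conversion_failure_rate = 0,
                           sequencing_error_rate = 0, read_length = 54L)
  des <- tiny_design(1L)
  # half methylated in expectation
  rd <- simulate_amplicon_reads(des$sample[1L], a, rep(0.5, k), cfg, seed = 3)
  al <- align_sample(sim_reads(rd), pan, min_len = 50L)
  mm <- call_methylation(setNames(list(al), des$sample[1L]), pan,
                         min_coverage = 100L)
  # both mates cover every CpG: 400 calls per site
  expect_true(all(mm$C + mm$T == 400L))
  expect_true(all(abs(mm$pct - 50) < 3 * sqrt(0.25 / 400) * 100))
  # min_coverage above attainable coverage: all missing
  mm2 <- call_methylation(setNames(list(al), des$sample[1L]), pan,
                          min_coverage = 1000L)
  expect_true(all(is.na(mm2$pct)))
})

test_that("methylation caller equals a truth-tally oracle on error-free reads", {
  pan <- toy_panel()
  des <- tiny_design(2L)
  tr <- flat_truth(pan, unique(des$group), 60, 10)
  cfg <- simulation_config(coverage_per_amplicon = 400L,
                           conversion_failure_rate = 0,
                           sequencing_error_rate = 0, read_length = 54L)
  sim <- simulate_cohort(pan, des, tr, cfg)
  mm <- quantify_cohort(sim, min_coverage = 10L, min_len = 50L)
  # oracle: tally C/T directly from the simulated read strings at CpG offsets
  for (smp in des$sample) {
    rd <- sim$reads[[smp]]
    for (aid in names(pan$amplicons)) {
      a <- sim$panel$amplicons[[aid]]
      sel <- startsWith(rd$id, paste0("sim:", smp, ":",
                                      gsub("[^A-Za-z0-9_.-]", "", aid)))
      sites <- enumerate_cpg_sites(a$sequence, a$start)
      L <- nchar(a$sequence)
      for (j in seq_len(nrow(sites))) {
        o <- sites$offset[j] + 1L
        b1 <- substr(rd$r1[sel], o, o)
        # R2 covers the site from the other end (reads are full-length here)
        o2 <- L - o + 1L
        b2 <- substr(rd$r2[sel], o2, o2)
        b2 <- chartr("ACGT", "TGCA", b2)
        calls <- c(b1, b2)
        oracle <- 100 * sum(calls == "C") / sum(calls %in% c("C", "T"))
        got <- mm$pct[smp, sprintf("%s@%+d", aid, sites$position[j])]
        expect_equal(unname(got), oracle)
      }
    }
  }
})

test_that("incomplete conversion inflates apparent methylation by its rate", {
  pan <- toy_panel()
  pan$amplicons <- pan$amplicons[1L]
  a <- pan$amplicons[[1L]]
  des <- tiny_design(1L)
  cfg <- simulation_config(coverage_per_amplicon = 5000L,
                           conversion_failure_rate = 0.05,
                           sequencing_error_rate = 0, read_length = 54L)
  rd <- simulate_amplicon_reads(des$sample[1L], a,
                                rep(0, a$declared_cpg_count), cfg, seed = 11)
  al <- align_sample(sim_reads(rd), pan, min_len = 50L)
  mm <- suppressWarnings(call_methylation(setNames(list(al), des$sample[1L]),
                                          pan, min_coverage = 100L))
  # truth 0: apparent methylation ~ failure rate x 100 = 5 points
  expect_lt(abs(mean(mm$pct) - 5), 1)
  expect_lt(abs(mean(suppressWarnings(conversion_efficiency(list(s = al)))) - 95), 1)
})

test_that("conversion efficiency warns when undefined or low", {
  al <- structure(list(tallies = list(x = list(cpg_C = 1L, cpg_T = 1L,
                                               cpg_other = 0L, noncpg_C = 0L,
                                               noncpg_T = 0L, positions = 1L)),
                       qc = c(reads_in = 2)), class = "sample_alignments")
  expect_warning(conversion_efficiency(list(s1 = al)), "undefined")
  al$tallies$x$noncpg_C <- 10L; al$tallies$x$noncpg_T <- 90L
  expect_warning(conversion_efficiency(list(s1 = al)), "below 98")
})

test_that("read accounting is conserved through the per-sample chain", {
  pan <- toy_panel()
  des <- tiny_design(1L)
  tr <- flat_truth(pan, unique(des$group), 50, 0)
  cfg <- simulation_config(coverage_per_amplicon = 30L, read_length = 54L,
                           sequencing_error_rate = 0.001)
  sim <- simulate_cohort(pan, des, tr, cfg)
  rd <- sim_reads(sim$reads[[1L]])
  # add junk that must come out unassigned, and a short read
  rd <- rbind(rd, data.frame(id = c("junk1", "short1"),
                             seq = c(strrep("ACGT", 30), strrep("A", 20)),
                             qual = c(strrep("I", 120), strrep("I", 20)),
                             mate = "R1"))
  al <- align_sample(rd, sim$panel, min_len = 50L)
  qc <- al$qc
  expect_identical(unname(qc["reads_in"]),
                   unname(qc["removed_short"] + qc["unassigned"] +
                            qc["rejected_alignment"] + qc["aligned"]))
  expect_equal(unname(qc["removed_short"]), 1)
  expect_equal(unname(qc["unassigned"]), 1)
})

test_that("quantification from FASTQ files matches in-memory quantification", {
  pan <- toy_panel()
  des <- tiny_design(2L)
  tr <- flat_truth(pan, unique(des$group), 40, 5)
  cfg <- simulation_config(coverage_per_amplicon = 60L, read_length = 54L)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(pan, des, tr, cfg, dir = dir)
  mm_mem <- quantify_cohort(sim, min_coverage = 10L, min_len = 50L)
  mm_fil <- quantify_cohort(dir, panel = sim$panel, min_coverage = 10L,
                            min_len = 50L)
  expect_equal(mm_fil$pct, mm_mem$pct)
  expect_equal(mm_fil$C, mm_mem$C)
})
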