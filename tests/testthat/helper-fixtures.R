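# Shared fixtures: all built in code, no files.

# A tiny two-amplicon panel with concrete sequences and primer cores that are
# valid bisulfite primers (fwd no C, rev no G, no CpG in cores).
toy_panel <- function() {
  mk <- function(gene, id, start, seqs) {
    len <- nchar(seqs$full)
    amplicon(gene, id, start, end = start + len,  # naive-subtraction length
             declared_length = len,
             declared_cpg_count = nrow(enumerate_cpg_sites(seqs$full, start)),
             primers = list(name_fwd = "F", name_rev = "R",
                            seq_fwd = seqs$fwd, seq_rev = seqs$rev,
                            overhang_fwd = "", overhang_rev = ""),
             sequence = seqs$full)
  }
  # amp A: genomic primer footprints carry non-CpG C's that convert into the
  # primer cores (so primers match converted but not genomic template);
  # middle has 2 CpGs plus a free non-CpG C.
  fwdA <- "TTGAGGATTAGAGATT"      # core, no C
  revA <- "TCCTAATAAACTTAAT"      # core, no G
  footA <- "CTGAGGACTAGAGACT"     # converts to fwdA
  sufA <- "ACTAAGCTTACTAGGA"      # converts to revcomp(revA)
  midA <- "ATTACGTTCATTACGATTATTA"
  ampA <- mk("geneA", "geneA (1)", -20L,
             list(full = paste0(footA, midA, sufA), fwd = fwdA, rev = revA))
  fwdB <- "GATTTGGTTAGTTGAT"
  revB <- "ACCTCATTAATTCTAA"
  footB <- "GACTTGGCTAGCTGAT"     # converts to fwdB
  sufB <- "CTAGAACTAATGAGGT"      # converts to revcomp(revB)
  midB <- "TTACGTAACGATACGTTATTTT"
  ampB <- mk("geneB", "geneB (1)", 5L,
             list(full = paste0(footB, midB, sufB), fwd = fwdB, rev = revB))
  amplicon_panel(list(ampA, ampB), spacer_length = 10L)
}

# Uniform group truth for a panel: same mean/sd for every amplicon x group.
flat_truth <- function(panel, groups, mean_pct, sd_pct = 0) {
  expand <- expand.grid(amplicon_id = names(panel$amplicons), group = groups,
                        stringsAsFactors = FALSE)
  expand$mean_pct <- mean_pct
  expand$sd_pct <- sd_pct
  expand
}

# Tiny design: n samples in a single group (or several).
tiny_design <- function(n = 2L, sex = "testis", origin = "captive") {
  d <- data.frame(sample = sprintf("s%02d", seq_len(n)), sex = sex,
                  origin = origin, group = paste(origin, sex, sep = "_"))
  class(d) <- c("cohort_design", "data.frame")
  d
}

# Fabricate a meth_matrix directly from a percent matrix (samples x sites),
# bypassing read simulation, for statistics-layer tests.
make_meth_matrix <- function(pct, design,
                             gene = rep("g1", ncol(pct)),
                             amplicon_id = rep("g1 (1)", ncol(pct)),
                             position = seq_len(ncol(pct))) {
  sites <- data.frame(gene = gene, amplicon_id = amplicon_id,
                      position = position,
                      site_id = sprintf("%s@%+d", amplicon_id, position))
  rownames(pct) <- design$sample
  colnames(pct) <- sites$site_id
  structure(list(sites = sites, samples = design$sample,
                 C = pct, T = 100 - pct, pct = pct,
                 conversion_efficiency = setNames(rep(100, nrow(pct)),
                                                  design$sample),
                 qc = NULL, min_coverage = 1L),
            class = "meth_matrix")
}

# Widen a simulator read table into the long form align_sample() consumes.
sim_reads <- function(rd) {
  out <- data.frame(id = rd$id, seq = rd$r1, qual = rd$q1, mate = "R1")
  if (!is.null(rd$r2)) {
    out <- rbind(out, data.frame(id = rd$id, seq = rd$r2, qual = rd$q2,
                                 mate = "R2"))
  }
  out
}

# Independent brute-force Kruskal-Wallis H with tie correction.
bf_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gl <- unique(groups)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(gl, function(g) {
      n <- sum(groups == g)
      n * mean(r[groups == g])^2
    }, 0)) - 3 * (N + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

bf_virtual_pcr_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Exhaustive-substring virtual-PCR oracle: scan every (fwd, rev) placement.
bf_virtual_pcr <- function(fwd, rev, tx) {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hits <- function(pat) {
    k <- nchar(pat); n <- nchar(tx)
    if (k > n) return(integer(0))
    starts <- seq_len(n - k + 1L)
    starts[substring(tx, starts, starts + k - 1L) == pat]
  }
  f <- hits(fwd)
  r <- hits(rc(rev))
  sizes <- integer(0)
  for (i in f) for (j in r) {
    if (i < j) sizes <- c(sizes, j + nchar(rev) - 1L - i + 1L)
  }
  sizes
}
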