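#' Simulation settings for the bisulfite amplicon read generator
#'
#' Defaults emulate the study's sequencing setup: 300 bp paired-end reads,
#' deep per-amplicon coverage, directional bisulfite PCR with a small
#' incomplete-conversion rate at non-CpG cytosines and a small substitution
#' error rate.
#'
#' @param coverage_per_amplicon read pairs simulated per sample and amplicon.
#' @param conversion_failure_rate probability an unmethylated (non-CpG)
#'   cytosine escapes conversion and is read as C.
#' @param sequencing_error_rate per-base substitution error probability.
#' @param read_length bases sequenced from each end.
#' @param paired simulate read pairs (R1 from the forward primer, R2 from the
#'   reverse primer).
#' @param cpg_jitter_sd site-to-site spread (percentage points) added around
#'   each sample's amplicon-level methylation.
#' @param quality_decay if TRUE, ramp the last 10 base qualities down to Q2
#'   to exercise 3' quality trimming.
#' @param seed RNG seed for the simulation stream.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(coverage_per_amplicon = 2000L,
                              conversion_failure_rate = 0.005,
                              sequencing_error_rate = 0.001,
                              read_length = 300L,
                              paired = TRUE,
                              cpg_jitter_sd = 2,
                              quality_decay = FALSE,
                              seed = 1L) {
  stopifnot(coverage_per_amplicon >= 1,
            conversion_failure_rate >= 0, conversion_failure_rate <= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1,
            read_length >= 1)
  structure(list(coverage_per_amplicon = as.integer(coverage_per_amplicon),
                 conversion_failure_rate = conversion_failure_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 read_length = as.integer(read_length),
                 paired = isTRUE(paired),
                 cpg_jitter_sd = cpg_jitter_sd,
                 quality_decay = isTRUE(quality_decay),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Synthesize unconverted amplicon sequences for a panel
#'
#' Panels transcribed from published tables carry coordinates, primer pairs
#' and CpG counts but no sequence. This generator fabricates, per amplicon, a
#' random top-strand sequence that (i) has the declared length, (ii) begins
#' with the forward primer core and ends with the reverse complement of the
#' reverse primer core (both already bisulfite-compatible, so converted reads
#' start with the primer cores), (iii) contains exactly the declared number
#' of CpG dinucleotides, all outside the primer footprints, and (iv) carries
#' non-CpG cytosines so conversion-efficiency QC has substrate.
#'
#' @param panel `amplicon_panel`; amplicons that already have a sequence are
#'   left untouched.
#' @param seed RNG seed.
#' @param non_cpg_c_frac fraction of free middle positions turned into
#'   non-CpG cytosines.
#' @return the panel with all amplicons carrying sequences.
#' @export
synthesize_panel_sequences <- function(panel, seed = 1L, non_cpg_c_frac = 0.15) {
  set.seed(substream_seed(seed, "panel_sequences"))
  panel$amplicons <- lapply(panel$amplicons, function(a) {
    if (!is.null(a$sequence)) return(a)
    a$sequence <- synth_amplicon_sequence(a, non_cpg_c_frac)
    # re-validate through the constructor invariants
    amplicon(a$gene, a$amplicon_id, a$start, a$end, a$declared_length,
             a$declared_cpg_count, a$primers, sequence = a$sequence)
  })
  panel
}

synth_amplicon_sequence <- function(a, non_cpg_c_frac) {
  fwd <- strip_overhang(a$primers$seq_fwd)$core
  rev <- strip_overhang(a$primers$seq_rev)$core
  suffix <- revcomp(rev)
  L <- a$declared_length
  m <- L - nchar(fwd) - nchar(suffix)
  k <- a$declared_cpg_count
  if (m < 2L * k + 2L) {
    stop(sprintf("%s: middle too short (%d bp) for %d CpGs", a$amplicon_id, m, k))
  }
  mid <- sample(c("A", "T", "G", "C"), m, replace = TRUE,
                prob = c((1 - non_cpg_c_frac) / 3, (1 - non_cpg_c_frac) / 3,
                         (1 - non_cpg_c_frac) / 3, non_cpg_c_frac))
  # place the CpGs on an even grid with random offset, >= 2 apart
  if (k > 0L) {
    slots <- floor(seq(2L, m - 2L, length.out = k))
    mid[slots] <- "C"
    mid[slots + 1L] <- "G"
  } else {
    slots <- integer(0)
  }
  # repair accidental CG created by filler C's (and by the suffix junction)
  repeat {
    cg <- which(mid[-m] == "C" & mid[-1L] == "G")
    cg <- setdiff(cg, slots)
    if (!length(cg)) break
    mid[cg + 1L] <- "A"
  }
  if (length(mid) && mid[m] == "C" && substr(suffix, 1L, 1L) == "G") mid[m] <- "T"
  # the genomic primer footprints carry unmethylated C's that bisulfite
  # conversion turns into the primer cores' T's, so primers anneal to
  # converted but not to genomic template (a T not followed by G may have
  # been a C in the genome without creating a CpG)
  cify <- function(s) {
    ch <- seq_chars(s)[[1L]]
    n <- length(ch)
    for (i in seq_len(n - 1L)) {
      if (ch[i] == "T" && ch[i + 1L] != "G" && runif(1) < 0.4) ch[i] <- "C"
    }
    paste(ch, collapse = "")
  }
  seq <- paste0(cify(fwd), paste(mid, collapse = ""), cify(suffix))
  found <- nrow(enumerate_cpg_sites(seq, a$start))
  if (found != k) {
    stop(sprintf("%s: synthesized %d CpGs, wanted %d", a$amplicon_id, found, k))
  }
  seq
}

#' Draw per-sample, per-CpG true methylation from group-level truth
#'
#' Per sample, an amplicon-level methylation value is drawn from a Beta
#' distribution moment-matched to the group's (mean, SD) in the truth table;
#' each CpG of that amplicon then receives independent Gaussian jitter
#' (`cpg_jitter_sd` percentage points) and is clipped to \code{[0, 1]}. The
#' expected group mean equals the configured mean. Degenerate truths (SD 0,
#' or an SD exceeding the Beta variance bound, for which a warning is given)
#' fall back to a point mass at the mean; amplicon-level values are clipped
#' to \code{[0.001, 0.999]} so fully (un)methylated groups remain simulable.
#'
#' @param truth data.frame amplicon_id / group / mean_pct / sd_pct (see
#'   [lates_methylation_truth()]).
#' @param design [cohort_design()] data.frame.
#' @param panel `amplicon_panel` with sequences.
#' @param seed RNG seed.
#' @param cpg_jitter_sd per-CpG jitter in percentage points.
#' @return data.frame sample / group / gene / amplicon_id / position /
#'   true_meth (0-1).
#' @export
sample_methylation_profiles <- function(truth, design, panel, seed = 1L,
                                        cpg_jitter_sd = 2) {
  set.seed(substream_seed(seed, "methylation_profiles"))
  sites <- panel_cpg_sites(panel)
  out <- vector("list", nrow(design) * length(panel$amplicons))
  idx <- 0L
  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]
    grp <- design$group[si]
    for (a in panel$amplicons) {
      row <- truth[truth$amplicon_id == a$amplicon_id & truth$group == grp, ]
      if (nrow(row) != 1L) {
        stop(sprintf("no truth for amplicon '%s', group '%s'", a$amplicon_id, grp))
      }
      m <- row$mean_pct / 100
      s <- row$sd_pct / 100
      amp_level <- draw_beta_matched(1L, m, s)
      asites <- sites[sites$amplicon_id == a$amplicon_id, ]
      tm <- amp_level + rnorm(nrow(asites), 0, cpg_jitter_sd / 100)
      tm <- pmin(pmax(tm, 0), 1)
      idx <- idx + 1L
      out[[idx]] <- data.frame(sample = smp, group = grp, gene = a$gene,
                               amplicon_id = a$amplicon_id,
                               position = asites$position, true_meth = tm)
    }
  }
  do.call(rbind, out[seq_len(idx)])
}

# Beta draw moment-matched to (mean m, sd s) on [0,1]; point-mass fallback.
draw_beta_matched <- function(n, m, s) {
  if (s <= 0 || m <= 0 || m >= 1) {
    x <- rep(m, n)
  } else if (s^2 >= m * (1 - m)) {
    warning(sprintf("sd %.3f exceeds Beta bound for mean %.3f; using point mass", s, m))
    x <- rep(m, n)
  } else {
    nu <- m * (1 - m) / s^2 - 1
    x <- rbeta(n, m * nu, (1 - m) * nu)
  }
  pmin(pmax(x, 0.001), 0.999)
}

#' Simulate directional bisulfite amplicon read pairs for one sample/amplicon
#'
#' Each template is the amplicon's top strand after bisulfite conversion:
#' every CpG cytosine is retained (read C) with its site's true methylation
#' probability, every non-CpG cytosine converts to T except with the
#' incomplete-conversion probability, and independent substitution errors are
#' then applied. R1 reads the template 5'-3' from the forward primer, R2 the
#' reverse complement from the reverse primer, each truncated to the read
#' length. Base qualities are constant at the Phred equivalent of the error
#' rate (capped at Q40), optionally with a 3' decay.
#'
#' @param sample sample label (encoded in read names for truth tracking).
#' @param amplicon `amplicon` with a sequence.
#' @param true_meth numeric vector of per-CpG methylation (0-1) in amplicon
#'   order.
#' @param config [simulation_config()].
#' @param seed RNG seed.
#' @return data.frame id / r1 / q1 / r2 / q2 (r2/q2 absent when unpaired).
#' @export
simulate_amplicon_reads <- function(sample, amplicon, true_meth, config,
                                    seed = config$seed) {
  set.seed(substream_seed(seed, paste("reads", sample, amplicon$amplicon_id)))
  if (is.null(amplicon$sequence)) stop("amplicon has no sequence: ", amplicon$amplicon_id)
  L <- nchar(amplicon$sequence)
  if (L > 2L * config$read_length) {
    stop(sprintf("%s: %d bp exceeds 2 x read length (%d); not representable as a pair",
                 amplicon$amplicon_id, L, config$read_length))
  }
  ref <- seq_chars(amplicon$sequence)[[1L]]
  cpg_off <- enumerate_cpg_sites(amplicon$sequence, amplicon$start)$offset + 1L
  if (length(true_meth) != length(cpg_off)) {
    stop("true_meth length != number of CpGs in amplicon")
  }
  ncc_off <- setdiff(which(ref == "C"), cpg_off)
  n <- config$coverage_per_amplicon
  # start from the fully converted template, then re-instate C's
  tmpl <- ref
  tmpl[tmpl == "C"] <- "T"
  mat <- matrix(rep(tmpl, each = n), nrow = n)
  for (j in seq_along(cpg_off)) {
    # an unmethylated CpG cytosine can also escape conversion and read C
    p_c <- true_meth[j] + (1 - true_meth[j]) * config$conversion_failure_rate
    keep <- rbinom(n, 1L, p_c) == 1L
    mat[keep, cpg_off[j]] <- "C"
  }
  if (config$conversion_failure_rate > 0 && length(ncc_off)) {
    fail <- matrix(rbinom(n * length(ncc_off), 1L, config$conversion_failure_rate) == 1L,
                   nrow = n)
    mat[, ncc_off][fail] <- "C"
  }
  if (config$sequencing_error_rate > 0) {
    err <- which(runif(n * L) < config$sequencing_error_rate)
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- mat[err]
      repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      mat[err] <- repl
    }
  }
  full <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
  rl <- config$read_length
  r1 <- substr(full, 1L, rl)
  q1 <- quality_string(nchar(r1)[1L], config)
  tag <- gsub("[^A-Za-z0-9_.-]", "", amplicon$amplicon_id)
  ids <- sprintf("sim:%s:%s:%05d", sample, tag, seq_len(n))
  out <- data.frame(id = ids, r1 = r1, q1 = q1)
  if (config$paired) {
    rc <- revcomp(full)
    out$r2 <- substr(rc, 1L, rl)
    out$q2 <- quality_string(nchar(out$r2)[1L], config)
  }
  out
}

quality_string <- function(len, config) {
  q <- if (config$sequencing_error_rate <= 0) 40L else {
    min(40L, as.integer(round(-10 * log10(config$sequencing_error_rate))))
  }
  qs <- rep(q, len)
  if (config$quality_decay && len > 10L) {
    tail_idx <- (len - 9L):len
    qs[tail_idx] <- pmax(2L, as.integer(round(seq(q, 2L, length.out = 10L))))
  }
  intToUtf8(qs + 33L)
}

#' Simulate a full BSAS cohort
#'
#' Draws per-sample per-CpG methylation truth and generates one set of read
#' pairs per sample spanning all panel amplicons. Deterministic given the
#' seed. Optionally writes per-sample FASTQ files and a truth TSV.
#'
#' @param panel `amplicon_panel`; sequences are synthesized when absent.
#' @param design [cohort_design()].
#' @param truth group-level methylation truth table.
#' @param config [simulation_config()].
#' @param dir optional output directory for FASTQ/truth files.
#' @return list of class `bsas_simulation`: `panel` (with sequences),
#'   `design`, `truth` (per-sample per-CpG), `reads` (named per-sample list
#'   of read data.frames), and `files` when `dir` was given.
#' @export
simulate_cohort <- function(panel = lates_panel(), design = cohort_design(),
                            truth = lates_methylation_truth(),
                            config = simulation_config(), dir = NULL) {
  panel <- synthesize_panel_sequences(panel, seed = config$seed)
  profiles <- sample_methylation_profiles(truth, design, panel,
                                          seed = config$seed,
                                          cpg_jitter_sd = config$cpg_jitter_sd)
  reads <- vector("list", nrow(design))
  names(reads) <- design$sample
  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]
    per_amp <- lapply(panel$amplicons, function(a) {
      tm <- profiles$true_meth[profiles$sample == smp &
                                 profiles$amplicon_id == a$amplicon_id]
      simulate_amplicon_reads(smp, a, tm, config, seed = config$seed)
    })
    reads[[si]] <- do.call(rbind, c(per_amp, make.row.names = FALSE))
  }
  sim <- structure(list(panel = panel, design = design, truth = profiles,
                        reads = reads, config = config),
                   class = "bsas_simulation")
  if (!is.null(dir)) sim$files <- write_simulation(sim, dir)
  sim
}

#' @export
print.bsas_simulation <- function(x, ...) {
  cat(sprintf("BSAS simulation: %d samples x %d amplicons, %d read pairs/amplicon\n",
              nrow(x$design), length(x$panel$amplicons),
              x$config$coverage_per_amplicon))
  invisible(x)
}

# Write per-sample FASTQ (R1/R2) plus the per-CpG truth table.
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (smp in names(sim$reads)) {
    rd <- sim$reads[[smp]]
    f1 <- file.path(dir, paste0(smp, "_R1.fastq"))
    write_fastq(rd$id, rd$r1, rd$q1, f1)
    files[[smp]] <- c(R1 = f1)
    if (!is.null(rd$r2)) {
      f2 <- file.path(dir, paste0(smp, "_R2.fastq"))
      write_fastq(rd$id, rd$r2, rd$q2, f2)
      files[[smp]] <- c(files[[smp]], R2 = f2)
    }
  }
  tf <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  files$truth <- tf
  files
}

#' Write reads to FASTQ
#'
#' @param id,seq,qual equal-length character vectors.
#' @param path output file; `.gz` suffix triggers compression.
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seq, id)),
    Biostrings::PhredQuality(qual))
  # Biostrings chatters about (absent) metadata columns on the inner set
  suppressWarnings(
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = grepl("\\.gz$", path)))
  invisible(path)
}

#' Read a FASTQ file into the package's plain read table
#'
#' @param path FASTQ file (optionally gzipped).
#' @param mate `"R1"` or `"R2"` label attached to the reads.
#' @return data.frame id / seq / qual / mate.
#' @export
read_fastq <- function(path, mate = "R1") {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             mate = mate)
}
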