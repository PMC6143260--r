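#' Quality-trim reads from the 3' end
#'
#' Removes bases from the 3' end for as long as the base-call accuracy is
#' below `min_accuracy`; trimming stops at the first passing base from the
#' end, leaving interior bases untouched. A 95% accuracy floor corresponds to
#' Phred quality below 10*log10(1/(1-0.95)) ~ 13.01.
#'
#' @param reads data.frame with columns `seq` and `qual` (Phred+33 strings).
#' @param min_accuracy minimum per-base call accuracy (0-1, default 0.95).
#' @return the reads with trimmed `seq`/`qual` (possibly empty strings).
#' @export
quality_trim <- function(reads, min_accuracy = 0.95) {
  stopifnot(min_accuracy > 0, min_accuracy < 1)
  thr <- -10 * log10(1 - min_accuracy)
  keep_len <- vapply(reads$qual, function(q) {
    if (!nzchar(q)) return(0L)
    qs <- utf8ToInt(q) - 33L
    ok <- which(qs >= thr)
    if (!length(ok)) 0L else max(ok)
  }, 0L, USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Drop reads shorter than a minimum length
#'
#' Retains reads of length `>= min_len` (the published filter removes reads
#' strictly shorter than 100 bp; a 100 bp read is kept).
#'
#' @param reads data.frame with a `seq` column.
#' @param min_len minimum retained length (default 100).
#' @return filtered data.frame; the number removed is in attribute
#'   `"n_removed"`.
#' @export
length_filter <- function(reads, min_len = 100L) {
  keep <- nchar(reads$seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Bisulfite-converted primer cores of a panel: the forward core matches the
# converted top strand 5' end; the reverse core is the R2 5' end.
panel_primer_cores <- function(panel) {
  lapply(panel$amplicons, function(a) {
    list(fwd = strip_overhang(a$primers$seq_fwd)$core,
         rev = strip_overhang(a$primers$seq_rev)$core)
  })
}

#' Assign reads to panel amplicons by their primer prefix
#'
#' Compares each read's 5' end against every amplicon's expected converted
#' primer (the forward primer core for R1, the reverse core for R2), allowing
#' up to `max_mismatch` substitutions. The unique best match wins; ties and
#' no-matches are `"unassigned"`.
#'
#' @param reads data.frame with `seq` and `mate` ("R1"/"R2") columns.
#' @param panel `amplicon_panel`.
#' @param max_mismatch per-primer mismatch budget (default 2).
#' @return character vector of amplicon ids (or `"unassigned"`), one per read.
#' @export
assign_to_amplicon <- function(reads, panel, max_mismatch = 2L) {
  cores <- panel_primer_cores(panel)
  ids <- names(panel$amplicons)
  n <- nrow(reads)
  if (n == 0L) return(character(0))
  mm <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  is_r1 <- reads$mate == "R1"
  for (k in seq_along(ids)) {
    col <- rep(NA_integer_, n)
    if (any(is_r1)) col[is_r1] <- prefix_mismatches(reads$seq[is_r1], cores[[k]]$fwd)
    if (any(!is_r1)) col[!is_r1] <- prefix_mismatches(reads$seq[!is_r1], cores[[k]]$rev)
    mm[, k] <- col
  }
  best <- apply(mm, 1L, min)
  n_best <- rowSums(mm == best)
  out <- ids[apply(mm, 1L, which.min)]
  out[best > max_mismatch | n_best > 1L] <- "unassigned"
  out
}

#' Bisulfite-aware ungapped alignment of one read to its amplicon
#'
#' Anchors the read at the matched primer: R1 at the amplicon 5' end, R2
#' (reverse-complemented) at the 3' end. Scoring is asymmetric: a read T
#' opposite an unconverted reference C is a legal bisulfite conversion, not a
#' mismatch. The alignment is rejected when plain mismatches exceed
#' `ceil(max_mismatch_frac * aligned_length)`. A C/T call is recorded at
#' every covered reference cytosine; any other base there is an `"other"`
#' call (and a mismatch).
#'
#' @param read single read sequence (character scalar).
#' @param amplicon `amplicon` with an (unconverted) sequence.
#' @param mate `"R1"` or `"R2"`.
#' @param max_mismatch_frac rejection threshold as a fraction of the aligned
#'   length (default 0.05).
#' @return list: `amplicon_id`, `strand`, `offset` (0-based), `calls` (named
#'   character vector, names = 0-based reference cytosine offsets),
#'   `mismatch_count`, `accepted`.
#' @export
bisulfite_align <- function(read, amplicon, mate = c("R1", "R2"),
                            max_mismatch_frac = 0.05) {
  mate <- match.arg(mate)
  b <- align_batch(read, amplicon, mate, max_mismatch_frac)
  cyt <- which(seq_chars(amplicon$sequence)[[1L]] == "C")
  covered <- !is.na(b$calls[1L, ])
  list(amplicon_id = amplicon$amplicon_id,
       strand = if (mate == "R1") "converted-top" else "converted-bottom",
       offset = b$offset[1L],
       calls = setNames(b$calls[1L, covered], cyt[covered] - 1L),
       mismatch_count = b$mismatches[1L],
       accepted = b$accepted[1L])
}

# Vectorised core: align equal-length handling via per-position substring.
# reads: character vector, all anchored per mate rule. Returns per-read
# mismatch counts, acceptance, and a reads x cytosine-position call matrix
# ("C"/"T"/"other", NA where uncovered), plus offsets.
align_batch <- function(reads, amplicon, mate, max_mismatch_frac = 0.05) {
  ref <- seq_chars(amplicon$sequence)[[1L]]
  L <- length(ref)
  cyt <- which(ref == "C")
  n <- length(reads)
  lens <- nchar(reads)
  if (mate == "R2") reads <- revcomp(reads)
  offsets <- if (mate == "R1") rep(0L, n) else pmax(L - lens, 0L)
  mism <- integer(n)
  calls <- matrix(NA_character_, n, length(cyt))
  for (len in unique(lens)) {
    sel <- lens == len
    alen <- min(len, L)
    # reference window per group: R1 covers 1..alen, R2 covers (L-alen+1)..L
    win <- if (mate == "R1") seq_len(alen) else (L - alen + 1L):L
    sub <- reads[sel]
    if (mate == "R2" && len > L) sub <- substr(sub, len - L + 1L, len)
    grp_mism <- integer(sum(sel))
    grp_calls <- matrix(NA_character_, sum(sel), length(cyt))
    for (i in seq_len(alen)) {
      rpos <- win[i]
      b <- substr(sub, i, i)
      rc <- ref[rpos]
      if (rc == "C") {
        j <- match(rpos, cyt)
        call <- ifelse(b == "C", "C", ifelse(b == "T", "T", "other"))
        grp_calls[, j] <- call
        grp_mism <- grp_mism + as.integer(call == "other")
      } else {
        grp_mism <- grp_mism + as.integer(b != rc)
      }
    }
    mism[sel] <- grp_mism
    calls[sel, ] <- grp_calls
  }
  alens <- pmin(lens, L)
  list(offset = offsets, mismatches = mism,
       accepted = mism <= ceiling(max_mismatch_frac * alens),
       calls = calls, cyt_offsets = cyt - 1L)
}

#' Align one sample's reads against the panel and tally cytosine calls
#'
#' Runs the whole per-sample quantification chain: 3' quality trimming,
#' length filtering, primer-based amplicon assignment and bisulfite-aware
#' alignment, accumulating C/T tallies at every reference cytosine.
#'
#' @param reads data.frame `id`/`seq`/`qual`/`mate` (R1 and R2 rows mixed).
#' @param panel `amplicon_panel` with sequences.
#' @param min_accuracy,min_len,max_primer_mismatch,max_mismatch_frac stage
#'   parameters (see the stage functions).
#' @return list of class `sample_alignments`: per-amplicon tallies (`cpg_C`,
#'   `cpg_T`, `cpg_other` per CpG; `noncpg_C`, `noncpg_T` totals) and a `qc`
#'   count vector.
#' @export
align_sample <- function(reads, panel, min_accuracy = 0.95, min_len = 100L,
                         max_primer_mismatch = 2L, max_mismatch_frac = 0.05) {
  n_in <- nrow(reads)
  reads <- quality_trim(reads, min_accuracy)
  reads <- length_filter(reads, min_len)
  n_short <- attr(reads, "n_removed")
  assigned <- assign_to_amplicon(reads, panel, max_primer_mismatch)
  n_unassigned <- sum(assigned == "unassigned")
  tallies <- list()
  n_rejected <- 0L
  for (aid in names(panel$amplicons)) {
    a <- panel$amplicons[[aid]]
    ref <- seq_chars(a$sequence)[[1L]]
    cyt <- which(ref == "C")
    cpg_off <- enumerate_cpg_sites(a$sequence, a$start)$offset + 1L
    is_cpg <- cyt %in% cpg_off
    tl <- list(cpg_C = integer(sum(is_cpg)), cpg_T = integer(sum(is_cpg)),
               cpg_other = integer(sum(is_cpg)),
               noncpg_C = 0L, noncpg_T = 0L,
               positions = tss_positions(a$start, nchar(a$sequence))[cyt[is_cpg]])
    for (mate in c("R1", "R2")) {
      sel <- assigned == aid & reads$mate == mate
      if (!any(sel)) next
      b <- align_batch(reads$seq[sel], a, mate, max_mismatch_frac)
      n_rejected <- n_rejected + sum(!b$accepted)
      cm <- b$calls[b$accepted, , drop = FALSE]
      if (!nrow(cm)) next
      ccount <- colSums(cm == "C", na.rm = TRUE)
      tcount <- colSums(cm == "T", na.rm = TRUE)
      ocount <- colSums(cm == "other", na.rm = TRUE)
      tl$cpg_C <- tl$cpg_C + ccount[is_cpg]
      tl$cpg_T <- tl$cpg_T + tcount[is_cpg]
      tl$cpg_other <- tl$cpg_other + ocount[is_cpg]
      tl$noncpg_C <- tl$noncpg_C + sum(ccount[!is_cpg])
      tl$noncpg_T <- tl$noncpg_T + sum(tcount[!is_cpg])
    }
    tallies[[aid]] <- tl
  }
  structure(list(tallies = tallies,
                 qc = c(reads_in = n_in, removed_short = n_short,
                        unassigned = n_unassigned,
                        rejected_alignment = n_rejected,
                        aligned = n_in - n_short - n_unassigned - n_rejected)),
            class = "sample_alignments")
}

#' Call per-CpG methylation across samples
#'
#' Per sample and CpG site, methylation is the percentage of unconverted
#' cytosine, `100 * C / (C + T)`; sequencing-error ("other") calls are in
#' neither count. Sites with fewer than `min_coverage` informative calls are
#' reported missing.
#'
#' @param alignments named list of [align_sample()] results (names = sample
#'   ids).
#' @param panel `amplicon_panel` with sequences.
#' @param min_coverage minimum informative (C+T) calls per cell (default 100).
#' @return object of class `meth_matrix`: `sites` (gene/amplicon_id/position/
#'   site_id), matrices `C`, `T`, `pct` (samples x sites),
#'   `conversion_efficiency` per sample, and `qc`.
#' @export
call_methylation <- function(alignments, panel, min_coverage = 100L) {
  sites <- panel_cpg_sites(panel)
  sites$site_id <- sprintf("%s@%+d", sites$amplicon_id, sites$position)
  samples <- names(alignments)
  k <- nrow(sites)
  Cm <- matrix(0L, length(samples), k, dimnames = list(samples, sites$site_id))
  Tm <- Cm
  for (s in samples) {
    for (aid in names(alignments[[s]]$tallies)) {
      tl <- alignments[[s]]$tallies[[aid]]
      cols <- match(sprintf("%s@%+d", aid, tl$positions), sites$site_id)
      Cm[s, cols] <- tl$cpg_C
      Tm[s, cols] <- tl$cpg_T
    }
  }
  denom <- Cm + Tm
  pct <- 100 * Cm / denom
  pct[denom < min_coverage] <- NA_real_
  qc <- do.call(rbind, lapply(alignments, `[[`, "qc"))
  structure(list(sites = sites, samples = samples, C = Cm, T = Tm, pct = pct,
                 conversion_efficiency = conversion_efficiency(alignments),
                 qc = qc, min_coverage = as.integer(min_coverage)),
            class = "meth_matrix")
}

#' Per-sample bisulfite conversion efficiency
#'
#' Percentage of non-CpG reference cytosines read as T; complete conversion
#' gives ~100%. Samples below `warn_below` trigger a warning; samples with no
#' covered non-CpG cytosine are NA with a warning.
#'
#' @param alignments named list of [align_sample()] results.
#' @param warn_below warning threshold in percent (default 98).
#' @return named numeric vector (percent).
#' @export
conversion_efficiency <- function(alignments, warn_below = 98) {
  out <- vapply(alignments, function(al) {
    cc <- sum(vapply(al$tallies, function(t) as.numeric(t$noncpg_C), 0))
    tt <- sum(vapply(al$tallies, function(t) as.numeric(t$noncpg_T), 0))
    if (cc + tt == 0L) return(NA_real_)
    100 * tt / (cc + tt)
  }, 0)
  if (anyNA(out)) warning("conversion efficiency undefined (no non-CpG cytosines covered) for: ",
                          paste(names(out)[is.na(out)], collapse = ", "))
  low <- !is.na(out) & out < warn_below
  if (any(low)) warning("conversion efficiency below ", warn_below, "% for: ",
                        paste(names(out)[low], collapse = ", "))
  out
}

#' Quantify a simulated or on-disk BSAS cohort
#'
#' Convenience wrapper running [align_sample()] and [call_methylation()] over
#' every sample of a [simulate_cohort()] result or a directory of per-sample
#' `<sample>_R1.fastq`/`_R2.fastq` files.
#'
#' @param x `bsas_simulation` or a directory path.
#' @param panel panel with sequences (taken from the simulation when `x` is
#'   one).
#' @param min_coverage,min_accuracy,min_len stage parameters.
#' @param samples optional sample subset.
#' @return `meth_matrix`.
#' @export
quantify_cohort <- function(x, panel = NULL, min_coverage = 100L,
                            min_accuracy = 0.95, min_len = 100L,
                            samples = NULL) {
  if (inherits(x, "bsas_simulation")) {
    panel <- panel %||% x$panel
    smp <- samples %||% names(x$reads)
    reads_of <- function(s) sim_reads_long(x$reads[[s]])
  } else {
    stopifnot(is.character(x), dir.exists(x), !is.null(panel))
    r1 <- list.files(x, "_R1\\.fastq(\\.gz)?$", full.names = TRUE)
    found <- sub("_R1\\.fastq(\\.gz)?$", "", basename(r1))
    smp <- samples %||% found
    reads_of <- function(s) {
      f1 <- r1[match(s, found)]
      f2 <- sub("_R1", "_R2", f1)
      rd <- read_fastq(f1, "R1")
      if (file.exists(f2)) rd <- rbind(rd, read_fastq(f2, "R2"))
      rd
    }
  }
  alignments <- lapply(setNames(smp, smp), function(s) {
    align_sample(reads_of(s), panel, min_accuracy = min_accuracy,
                 min_len = min_len)
  })
  call_methylation(alignments, panel, min_coverage = min_coverage)
}

# Widen a simulator per-sample read table (id/r1/q1/r2/q2) into the long
# id/seq/qual/mate form the quantifier consumes.
sim_reads_long <- function(rd) {
  out <- data.frame(id = rd$id, seq = rd$r1, qual = rd$q1, mate = "R1")
  if (!is.null(rd$r2)) {
    out <- rbind(out, data.frame(id = rd$id, seq = rd$r2, qual = rd$q2,
                                 mate = "R2"))
  }
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix: %d samples x %d CpG sites (min coverage %d)\n",
              length(x$samples), nrow(x$sites), x$min_coverage))
  cat(sprintf("  mean methylation %.1f%%, conversion efficiency %.2f%%\n",
              mean(x$pct, na.rm = TRUE),
              mean(x$conversion_efficiency, na.rm = TRUE)))
  invisible(x)
}

#' Long-form data.frame of a methylation matrix
#'
#' @param x `meth_matrix`.
#' @param ... unused.
#' @return data.frame sample / gene / amplicon_id / position / site_id /
#'   count_C / count_T / pct_meth.
#' @export
as.data.frame.meth_matrix <- function(x, ...) {
  k <- nrow(x$sites)
  n <- length(x$samples)
  data.frame(sample = rep(x$samples, times = k),
             gene = rep(x$sites$gene, each = n),
             amplicon_id = rep(x$sites$amplicon_id, each = n),
             position = rep(x$sites$position, each = n),
             site_id = rep(x$sites$site_id, each = n),
             count_C = as.vector(x$C),
             count_T = as.vector(x$T),
             pct_meth = as.vector(x$pct))
}

#' Write a methylation matrix (long and wide TSV) plus QC
#'
#' @param x `meth_matrix`.
#' @param dir output directory.
#' @param name basename.
#' @return invisibly, the paths written.
#' @export
write_meth_matrix <- function(x, dir, name = "methylation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- file.path(dir, paste0(name, "_long.tsv"))
  write.table(as.data.frame(x), long, sep = "\t", quote = FALSE,
              row.names = FALSE)
  wide <- file.path(dir, paste0(name, "_wide.tsv"))
  wmat <- data.frame(sample = x$samples, x$pct, check.names = FALSE)
  write.table(wmat, wide, sep = "\t", quote = FALSE, row.names = FALSE)
  qc <- file.path(dir, paste0(name, "_qc.tsv"))
  qdf <- data.frame(sample = rownames(x$qc), x$qc,
                    conversion_efficiency = x$conversion_efficiency,
                    check.names = FALSE)
  write.table(qdf, qc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(long = long, wide = wide, qc = qc))
}
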