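#' TSS-relative coordinates without a position zero
#'
#' Positions are counted relative to the transcription start site with the
#' convention ..., -2, -1, +1, +2, ...: there is no position 0. Amplicon
#' lengths quoted alongside such coordinates are the plain signed difference
#' `end - start`; that convention reproduces every published amplicon size in
#' the default panel, including amplicons that span the TSS.
#'
#' @param start,end TSS-relative positions (non-zero integers).
#' @return `amplicon_length()` returns the amplicon size in bp.
#' @examples
#' amplicon_length(-107, 160)  # 267
#' amplicon_length(-575, -305) # 270
#' @export
amplicon_length <- function(start, end) {
  check_tss_position(start)
  check_tss_position(end)
  if (any(start >= end)) stop("amplicon start must precede end")
  end - start
}

check_tss_position <- function(x) {
  if (any(!is.finite(x)) || any(x != as.integer(x))) {
    stop("TSS-relative positions must be integers")
  }
  if (any(x == 0)) stop("invalid TSS-relative position: 0 (convention skips zero)")
  invisible(as.integer(x))
}

# TSS-relative positions of n consecutive bases whose first base sits at
# `start`, skipping zero.
tss_positions <- function(start, n) {
  check_tss_position(start)
  if (n == 0L) return(integer(0))
  raw <- start + seq_len(n) - 1L
  if (start < 0L) raw[raw >= 0L] <- raw[raw >= 0L] + 1L
  raw
}

# Inverse: 0-based offset of a TSS-relative position within a sequence whose
# first base sits at `start`.
tss_offset <- function(position, start) {
  check_tss_position(position)
  check_tss_position(start)
  off <- position - start
  if (start < 0L & position > 0L) off <- off - 1L
  off
}

#' Enumerate CpG sites in an amplicon sequence
#'
#' Scans for `CG` dinucleotides and reports one site per occurrence, labelled
#' by the TSS-relative position of the cytosine under the no-zero convention.
#'
#' @param sequence DNA string (A/C/G/T/N, uppercase).
#' @param start TSS-relative position of the first base.
#' @param gene,amplicon_id optional labels carried into the result.
#' @return data.frame with columns `gene`, `amplicon_id`, `position`
#'   (TSS-relative) and `offset` (0-based within the sequence).
#' @export
enumerate_cpg_sites <- function(sequence, start, gene = NA_character_,
                                amplicon_id = NA_character_) {
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) {
    return(data.frame(gene = character(0), amplicon_id = character(0),
                      position = integer(0), offset = integer(0)))
  }
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be uppercase A/C/G/T/N")
  m <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(gene = character(0), amplicon_id = character(0),
                      position = integer(0), offset = integer(0)))
  }
  off <- as.integer(m) - 1L
  pos <- tss_positions(start, nchar(sequence))[off + 1L]
  data.frame(gene = gene, amplicon_id = amplicon_id,
             position = pos, offset = off)
}

#' In-silico bisulfite conversion
#'
#' Converts a top-strand DNA sequence as bisulfite treatment would: every
#' unmethylated cytosine deaminates and is read as T, while methylated CpG
#' cytosines resist conversion. The complementary PCR strand is represented on
#' top-strand coordinates: there every G (the base pairing a bottom-strand C)
#' becomes A unless it pairs the G of a methylated CpG.
#'
#' @param sequence DNA string, uppercase.
#' @param methylated_positions TSS-relative positions (no-zero convention) of
#'   methylated CpG cytosines; must be CpG C positions of `sequence`.
#' @param strand `"top"` or `"bottom"`.
#' @param start TSS-relative position of the first base (default +1).
#' @return converted DNA string.
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer(0),
                              strand = c("top", "bottom"), start = 1L) {
  strand <- match.arg(strand)
  chars <- seq_chars(sequence)[[1L]]
  n <- length(chars)
  keep <- logical(n)
  if (length(methylated_positions)) {
    cpg <- enumerate_cpg_sites(sequence, start)
    bad <- setdiff(methylated_positions, cpg$position)
    if (length(bad)) {
      stop("methylated position(s) not at a CpG cytosine: ",
           paste(bad, collapse = ", "))
    }
    keep[cpg$offset[match(methylated_positions, cpg$position)] + 1L] <- TRUE
  }
  if (strand == "top") {
    idx <- chars == "C" & !keep
    chars[idx] <- "T"
  } else {
    # G one base after a methylated CpG C is protected on the bottom strand
    keep_g <- logical(n)
    w <- which(keep)
    keep_g[w[w < n] + 1L] <- TRUE
    idx <- chars == "G" & !keep_g
    chars[idx] <- "A"
  }
  paste(chars, collapse = "")
}

#' Strip Illumina sequencing overhangs from a BSAS primer
#'
#' BSAS primers are ordered as overhang + locus-specific core. Removes the
#' exact forward (FO) or reverse (RO) overhang prefix when present.
#'
#' @param primer primer sequence 5'-3'.
#' @return list with `core` and `overhang_found` (`"FO"`, `"RO"` or `"none"`).
#' @export
strip_overhang <- function(primer) {
  stopifnot(length(primer) == 1L, nzchar(primer))
  for (tag in names(ILLUMINA_OVERHANGS)) {
    oh <- ILLUMINA_OVERHANGS[[tag]]
    if (startsWith(primer, oh)) {
      return(list(core = substring(primer, nchar(oh) + 1L), overhang_found = tag))
    }
  }
  list(core = primer, overhang_found = "none")
}

#' Illumina forward/reverse overhang adapter constants
#' @export
ILLUMINA_OVERHANGS <- list(
  FO = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
  RO = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"
)

#' Validate a bisulfite PCR primer pair
#'
#' Checks the design rules that make a primer pair specific to fully
#' converted template: the forward core may contain no C (all template C
#' outside CpGs reads as T), the reverse core no G (complement rule), and
#' neither core may cover a CpG (whose conversion state is unknown). When an
#' unconverted template is supplied the pair is additionally required to
#' anneal to the converted top strand (forward on the sense, reverse on its
#' reverse complement, each within `max_mismatch` substitutions, no indels)
#' and to fail on the unconverted template, mirroring the wet-lab control
#' that genomic DNA yields no product.
#'
#' @param primers list with `seq_fwd`, `seq_rev` (overhangs allowed; stripped
#'   internally).
#' @param template optional unconverted top-strand template DNA string.
#' @param max_mismatch mismatch budget for template annealing (default 2).
#' @return list of logical checks: `fwd_no_c`, `rev_no_g`, `no_cpg_in_core`,
#'   and, with a template, `anneals_converted` and `no_genomic_amplification`;
#'   plus `core_fwd`, `core_rev` and overall `pass`.
#' @export
validate_bisulfite_primers <- function(primers, template = NULL, max_mismatch = 2L) {
  fwd <- strip_overhang(primers$seq_fwd)$core
  rev <- strip_overhang(primers$seq_rev)$core
  if (!nzchar(fwd) || !nzchar(rev)) stop("empty primer core")
  res <- list(
    core_fwd = fwd,
    core_rev = rev,
    fwd_no_c = !grepl("C", fwd, fixed = TRUE),
    rev_no_g = !grepl("G", rev, fixed = TRUE),
    no_cpg_in_core = !grepl("CG", fwd, fixed = TRUE) && !grepl("CG", rev, fixed = TRUE)
  )
  if (!is.null(template)) {
    converted <- bisulfite_convert(template, strand = "top")
    res$anneals_converted <-
      anneals_anywhere(converted, fwd, max_mismatch) &&
      anneals_anywhere(revcomp(converted), rev, max_mismatch)
    genomic <- anneals_anywhere(template, fwd, max_mismatch) &&
      anneals_anywhere(revcomp(template), rev, max_mismatch)
    res$no_genomic_amplification <- !genomic
  }
  res$pass <- all(unlist(res[c("fwd_no_c", "rev_no_g", "no_cpg_in_core",
                               "anneals_converted", "no_genomic_amplification")],
                         use.names = FALSE))
  res
}

# Does `pattern` match anywhere in `subject` with at most mm substitutions?
anneals_anywhere <- function(subject, pattern, mm) {
  k <- nchar(pattern)
  n <- nchar(subject)
  if (k > n) return(FALSE)
  starts <- seq_len(n - k + 1L)
  windows <- substring(subject, starts, starts + k - 1L)
  any(prefix_mismatches(windows, pattern) <= mm)
}

#' CpG density of an amplicon
#'
#' @param amplicon an `amplicon` object (or any list with
#'   `declared_cpg_count` and `declared_length`).
#' @return CpG sites per 100 bp.
#' @export
cpg_density <- function(amplicon) {
  len <- amplicon$declared_length
  if (is.null(len) || len <= 0) stop("amplicon length must be positive")
  100 * amplicon$declared_cpg_count / len
}

#' Construct an amplicon record
#'
#' @param gene gene symbol.
#' @param amplicon_id unique amplicon label, e.g. `"dmrt1 (1)"`.
#' @param start,end TSS-relative coordinates (no zero).
#' @param declared_length expected size in bp; must equal `end - start`.
#' @param declared_cpg_count expected number of CpG sites.
#' @param primers list with `seq_fwd`/`seq_rev` and optional names/overhangs.
#' @param sequence optional unconverted top-strand sequence; when given its
#'   length and CpG count must match the declared values.
#' @return object of class `amplicon`.
#' @export
amplicon <- function(gene, amplicon_id, start, end, declared_length,
                     declared_cpg_count, primers, sequence = NULL) {
  len <- amplicon_length(start, end)
  if (len != declared_length) {
    stop(sprintf("%s: declared length %d != computed %d",
                 amplicon_id, declared_length, len))
  }
  if (declared_cpg_count < 0) stop("negative CpG count")
  if (!is.null(sequence)) {
    if (nchar(sequence) != declared_length) {
      stop(sprintf("%s: sequence length %d != declared %d",
                   amplicon_id, nchar(sequence), declared_length))
    }
    ncpg <- nrow(enumerate_cpg_sites(sequence, start))
    if (ncpg != declared_cpg_count) {
      stop(sprintf("%s: sequence has %d CpGs, declared %d",
                   amplicon_id, ncpg, declared_cpg_count))
    }
  }
  structure(list(gene = gene, amplicon_id = amplicon_id,
                 start = as.integer(start), end = as.integer(end),
                 declared_length = as.integer(declared_length),
                 declared_cpg_count = as.integer(declared_cpg_count),
                 primers = primers, sequence = sequence),
            class = "amplicon")
}

#' Construct an amplicon panel
#'
#' @param amplicons list of [amplicon()] objects with unique ids.
#' @param spacer_length number of N bases between amplicons in the mapping
#'   reference (default 100).
#' @return object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicons, spacer_length = 100L) {
  ids <- vapply(amplicons, `[[`, "", "amplicon_id")
  if (anyDuplicated(ids)) stop("duplicate amplicon ids")
  structure(list(amplicons = setNames(amplicons, ids),
                 spacer_length = as.integer(spacer_length)),
            class = "amplicon_panel")
}

#' Read an amplicon panel from a YAML config
#'
#' @param path YAML file with `amplicons` entries (gene, amplicon_id, start,
#'   end, declared_length, declared_cpg_count, primers) and optional
#'   `spacer_length`.
#' @return `amplicon_panel`.
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  amps <- lapply(cfg$amplicons, function(a) {
    pr <- a$primers
    # expand overhang tags into full ordered primer sequences
    oh_f <- if (!is.null(pr$overhang_fwd)) ILLUMINA_OVERHANGS[[pr$overhang_fwd]] else ""
    oh_r <- if (!is.null(pr$overhang_rev)) ILLUMINA_OVERHANGS[[pr$overhang_rev]] else ""
    primers <- list(name_fwd = pr$name_fwd %||% "", name_rev = pr$name_rev %||% "",
                    seq_fwd = paste0(oh_f, pr$seq_fwd),
                    seq_rev = paste0(oh_r, pr$seq_rev),
                    overhang_fwd = oh_f, overhang_rev = oh_r)
    amplicon(a$gene, a$amplicon_id, a$start, a$end,
             a$declared_length, a$declared_cpg_count, primers,
             sequence = a$sequence)
  })
  amplicon_panel(amps, spacer_length = cfg$spacer_length %||% 100L)
}

#' The default barramundi sex-gene BSAS panel
#'
#' Eleven amplicons over seven sex-related genes (dmrt1, cyp19a1, foxl2,
#' nr5a2, amh, sox8, sox9), with TSS-relative coordinates, published CpG
#' counts and bisulfite-PCR primer pairs. Amplicon sequences are not bundled;
#' [synthesize_panel_sequences()] generates sequences honouring the declared
#' lengths, CpG counts and primer footprints.
#'
#' @return `amplicon_panel` with 11 amplicons.
#' @export
lates_panel <- function() {
  read_panel(system.file("extdata", "lates_panel.yaml", package = "bsaskit",
                         mustWork = TRUE))
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d amplicons, %d genes, %d CpG sites, %d bp\n",
              length(x$amplicons),
              length(unique(vapply(x$amplicons, `[[`, "", "gene"))),
              sum(vapply(x$amplicons, `[[`, 0L, "declared_cpg_count")),
              sum(vapply(x$amplicons, `[[`, 0L, "declared_length"))))
  for (a in x$amplicons) {
    cat(sprintf("  %-12s %4d bp (%+d, %+d)  %2d CpG  %s\n",
                a$amplicon_id, a$declared_length, a$start, a$end,
                a$declared_cpg_count,
                if (is.null(a$sequence)) "" else "[sequence]"))
  }
  invisible(x)
}

#' Panel CpG site table
#'
#' Enumerates the CpG sites of every amplicon that carries a sequence.
#'
#' @param panel `amplicon_panel` whose amplicons have sequences.
#' @return data.frame gene / amplicon_id / position / offset.
#' @export
panel_cpg_sites <- function(panel) {
  do.call(rbind, lapply(panel$amplicons, function(a) {
    if (is.null(a$sequence)) {
      stop("amplicon without sequence: ", a$amplicon_id)
    }
    enumerate_cpg_sites(a$sequence, a$start, a$gene, a$amplicon_id)
  }))
}

#' Build the N-spaced bisulfite-converted mapping reference
#'
#' Concatenates the fully converted (all-CpG-unmethylated) top-strand
#' sequences of the panel's amplicons, separated by runs of N. Emits the
#' reference string, a 0-based half-open index of amplicon offsets and a CpG
#' site table with reference offsets.
#'
#' @param panel `amplicon_panel`; every amplicon needs a sequence.
#' @return list with `sequence`, `length`, `index` (data.frame amplicon_id /
#'   ref_start / ref_end) and `cpg_sites`.
#' @export
build_reference <- function(panel) {
  amps <- panel$amplicons
  for (a in amps) {
    if (is.null(a$sequence)) stop("amplicon without sequence: ", a$amplicon_id)
  }
  conv <- vapply(amps, function(a) bisulfite_convert(a$sequence, strand = "top"), "")
  lens <- nchar(conv)
  n <- length(conv)
  offs <- cumsum(c(0L, head(lens + panel$spacer_length, -1L)))
  spacer <- strrep("N", panel$spacer_length)
  ref <- paste(conv, collapse = spacer)
  idx <- data.frame(amplicon_id = vapply(amps, `[[`, "", "amplicon_id"),
                    ref_start = offs, ref_end = offs + lens,
                    row.names = NULL)
  cpg <- panel_cpg_sites(panel)
  cpg$ref_offset <- cpg$offset + idx$ref_start[match(cpg$amplicon_id, idx$amplicon_id)]
  list(sequence = ref, length = nchar(ref), index = idx, cpg_sites = cpg)
}

#' Write the mapping reference and its annotation files
#'
#' @param panel `amplicon_panel` with sequences.
#' @param dir output directory (created if needed).
#' @param name basename for the outputs.
#' @return invisibly, the paths written (FASTA reference, BED-like offsets
#'   TSV, CpG sites TSV).
#' @export
write_reference <- function(panel, dir, name = "panel_reference") {
  ref <- build_reference(panel)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, fa)
  bed <- file.path(dir, paste0(name, "_amplicons.tsv"))
  write.table(ref$index, bed, sep = "\t", quote = FALSE, row.names = FALSE)
  cpg <- file.path(dir, paste0(name, "_cpg_sites.tsv"))
  write.table(ref$cpg_sites, cpg, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, amplicons = bed, cpg_sites = cpg))
}
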