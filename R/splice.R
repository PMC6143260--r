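#' Gene model for splice-variant comparison
#'
#' @param gene gene symbol.
#' @param exons data.frame `id`, `start`, `end` in 1-based inclusive gene
#'   coordinates; must be sorted and non-overlapping.
#' @param genomic_sequence optional gene-coordinate DNA string.
#' @param domains optional data.frame `name`, `start`, `end` giving annotated
#'   domain intervals in transcript coordinates of the model's full
#'   (all-exon) transcript, e.g. the DM DNA-binding domain.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene, exons, genomic_sequence = NULL, domains = NULL) {
  stopifnot(all(c("id", "start", "end") %in% names(exons)))
  if (is.unsorted(exons$start, strictly = TRUE)) stop("exons must be sorted")
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (any(exons$start[-1L] <= exons$end[-nrow(exons)])) stop("overlapping exons")
  structure(list(gene = gene, exons = exons,
                 genomic_sequence = genomic_sequence, domains = domains),
            class = "gene_model")
}

#' Transcript isoform as an exon chain
#'
#' @param transcript_id label.
#' @param exon_chain data.frame `start`, `end` (1-based inclusive gene
#'   coordinates), sorted, non-overlapping.
#' @param sequence optional spliced sequence; length must equal the summed
#'   exon lengths.
#' @return object of class `isoform`.
#' @export
isoform <- function(transcript_id, exon_chain, sequence = NULL) {
  if (nrow(exon_chain)) {
    if (is.unsorted(exon_chain$start, strictly = TRUE)) stop("exon chain must be sorted")
    if (any(exon_chain$end < exon_chain$start)) stop("segment end before start")
    if (nrow(exon_chain) > 1L &&
        any(exon_chain$start[-1L] <= exon_chain$end[-nrow(exon_chain)])) {
      stop("overlapping segments")
    }
  }
  if (!is.null(sequence)) {
    want <- sum(exon_chain$end - exon_chain$start + 1L)
    if (nchar(sequence) != want) {
      stop(sprintf("sequence length %d != exon chain total %d", nchar(sequence), want))
    }
  }
  structure(list(transcript_id = transcript_id, exon_chain = exon_chain,
                 sequence = sequence), class = "isoform")
}

#' Classify splice events of an isoform against a gene model
#'
#' Compares the isoform's exon chain with the model's exons by coordinate
#' intervals. A model exon with no overlapping segment is `exon_skipped`; a
#' segment truncated at the 5' or 3' exon boundary yields
#' `exon_shortened_5p` / `exon_shortened_3p` with the (negative) bp delta
#' ("partial intronization"); a segment extending past an exon boundary
#' yields `intron_retained` with the positive delta ("exonization"); an
#' isoform segment overlapping no model exon is a `novel_exon`. Events are
#' ordered 5' to 3'.
#'
#' @param iso [isoform()].
#' @param model [gene_model()].
#' @return data.frame kind / exon_ref / delta / start / end.
#' @export
exon_diff <- function(iso, model) {
  segs <- iso$exon_chain
  ex <- model$exons
  ev <- list()
  add <- function(kind, exon_ref, delta, start, end) {
    ev[[length(ev) + 1L]] <<- data.frame(kind = kind, exon_ref = exon_ref,
                                         delta = delta, start = start, end = end)
  }
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  seg_used <- rep(FALSE, nrow(segs))
  for (i in seq_len(nrow(ex))) {
    hit <- which(overlaps(segs$start, segs$end, ex$start[i], ex$end[i]))
    if (!length(hit)) {
      add("exon_skipped", ex$id[i], -(ex$end[i] - ex$start[i] + 1L),
          ex$start[i], ex$end[i])
      next
    }
    seg_used[hit] <- TRUE
    s <- segs[hit[1L], ]            # leftmost overlapping segment: 5' boundary
    e <- segs[hit[length(hit)], ]   # rightmost: 3' boundary
    if (s$start > ex$start[i]) {
      add("exon_shortened_5p", ex$id[i], -(s$start - ex$start[i]),
          ex$start[i], s$start - 1L)
    } else if (s$start < ex$start[i]) {
      add("intron_retained", ex$id[i], ex$start[i] - s$start,
          s$start, ex$start[i] - 1L)
    }
    if (e$end < ex$end[i]) {
      add("exon_shortened_3p", ex$id[i], -(ex$end[i] - e$end),
          e$end + 1L, ex$end[i])
    } else if (e$end > ex$end[i]) {
      add("intron_retained", ex$id[i], e$end - ex$end[i],
          ex$end[i] + 1L, e$end)
    }
  }
  for (j in which(!seg_used)) {
    add("novel_exon", NA_character_, segs$end[j] - segs$start[j] + 1L,
        segs$start[j], segs$end[j])
  }
  if (!length(ev)) {
    return(data.frame(kind = character(0), exon_ref = character(0),
                      delta = integer(0), start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, ev)
  out[order(out$start), , drop = FALSE]
}

#' Is an annotated domain fully present in an isoform?
#'
#' Maps the domain's transcript-coordinate interval (on the model's full
#' transcript) to gene coordinates and checks every base is covered by the
#' isoform's exon chain. Removing exons can therefore never turn an absent
#' domain present.
#'
#' @param iso [isoform()].
#' @param model [gene_model()] with a `domains` table.
#' @param domain_name name of the domain to test.
#' @return logical.
#' @export
domain_present <- function(iso, model, domain_name) {
  d <- model$domains[model$domains$name == domain_name, ]
  if (nrow(d) != 1L) stop("unknown domain: ", domain_name)
  gpos <- transcript_to_gene(model, d$start:d$end)
  covered <- logical(length(gpos))
  for (k in seq_len(nrow(iso$exon_chain))) {
    covered <- covered | (gpos >= iso$exon_chain$start[k] &
                            gpos <= iso$exon_chain$end[k])
  }
  all(covered)
}

# Map transcript positions (1-based on the concatenated model exons) to gene
# coordinates.
transcript_to_gene <- function(model, tpos) {
  ex <- model$exons
  lens <- ex$end - ex$start + 1L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- integer(length(tpos))
  for (i in seq_along(tpos)) {
    k <- which(tpos[i] >= starts & tpos[i] <= ends)
    if (!length(k)) stop("transcript position outside model: ", tpos[i])
    out[i] <- ex$start[k] + (tpos[i] - starts[k])
  }
  out
}

# Spliced transcript sequence of an exon chain over a genomic sequence.
splice_sequence <- function(genomic, chain) {
  paste(substring(genomic, chain$start, chain$end), collapse = "")
}

#' Virtual RT-PCR on a transcript
#'
#' Searches the forward primer on the sense strand and the reverse primer on
#' the antisense strand, requiring a full-length match within `max_mismatch`
#' substitutions and an exact 3'-terminal base (polymerase extension rule).
#' A product is reported for every forward site upstream of a reverse site;
#' multiple products are flagged non-specific. The product size includes both
#' primer footprints, as gel sizes are reported.
#'
#' @param primers list with `seq_fwd`, `seq_rev` (5'-3').
#' @param transcript DNA string.
#' @param max_mismatch allowed substitutions per primer (default 0).
#' @return list with `products` (integer vector of sizes, empty if none),
#'   `specific` (TRUE when exactly one), and per-product `fwd_start`,
#'   `rev_end` positions.
#' @export
virtual_pcr <- function(primers, transcript, max_mismatch = 0L) {
  f_sites <- primer_sites(transcript, primers$seq_fwd, max_mismatch,
                          anchor = "right")
  # reverse primer anneals to the sense strand; its site on the sense strand
  # is the reverse complement of the primer, and its 3' end is the site's
  # leftmost base
  r_sites <- primer_sites(transcript, revcomp(primers$seq_rev), max_mismatch,
                          anchor = "left")
  prods <- list(fwd_start = integer(0), rev_end = integer(0))
  for (f in f_sites) {
    for (r in r_sites) {
      r_end <- r + nchar(primers$seq_rev) - 1L
      if (f < r) prods <- list(fwd_start = c(prods$fwd_start, f),
                               rev_end = c(prods$rev_end, r_end))
    }
  }
  sizes <- prods$rev_end - prods$fwd_start + 1L
  list(products = sizes, specific = length(sizes) == 1L,
       fwd_start = prods$fwd_start, rev_end = prods$rev_end)
}

# All start positions where `site` matches `subject` within mm substitutions;
# the base at the anchored end ("right" = last position, "left" = first) must
# match exactly.
primer_sites <- function(subject, site, mm, anchor = c("right", "left")) {
  anchor <- match.arg(anchor)
  k <- nchar(site)
  n <- nchar(subject)
  if (k > n) return(integer(0))
  starts <- seq_len(n - k + 1L)
  windows <- substring(subject, starts, starts + k - 1L)
  d <- prefix_mismatches(windows, site)
  anchor_pos <- if (anchor == "right") k else 1L
  ok <- d <= mm &
    substr(windows, anchor_pos, anchor_pos) == substr(site, anchor_pos, anchor_pos)
  starts[ok]
}

#' Sex-typing from the paired RT-PCR assays
#'
#' Combines the male-specific dmrt1 DM-domain assay and the female-specific
#' cyp19a1a exon-1 assay into a sex call: product in the dmrt1 assay only is
#' the male pattern, product in the cyp19a1a assay only the female pattern.
#'
#' @param dmrt1_products,cyp19a1a_products integer vectors of product sizes
#'   (as from [virtual_pcr()]`$products`).
#' @return one of `"male-pattern"`, `"female-pattern"`, `"both"`, `"neither"`
#'   (the last two with a warning).
#' @export
sex_type <- function(dmrt1_products, cyp19a1a_products) {
  m <- length(dmrt1_products) > 0L
  f <- length(cyp19a1a_products) > 0L
  if (m && !f) return("male-pattern")
  if (f && !m) return("female-pattern")
  out <- if (m) "both" else "neither"
  warning("ambiguous sex-typing result: ", out)
  out
}

#' Simulate toy sex-specific splice variants
#'
#' Builds two toy genes mirroring the study's splice findings, with random
#' sequence but fixed structure:
#' \itemize{
#'   \item a dmrt1-like gene whose canonical exon 1a carries the DM-domain
#'     interval; the testis isoform uses exon 1a, the ovary isoform replaces
#'     it with a 59 bp untranslated alternative first exon (1b) far upstream,
#'     so ovaries lack the DM domain;
#'   \item a cyp19a1-like gene with nine exons whose testis variant shortens
#'     exon 1 from 196 to 163 bp and exon 2 from 151 to 101 bp (partial
#'     intronization), with exon 3 occasionally spliced out.
#' }
#' Assay primers are cut from the transcripts so the male-specific assay
#' yields a 575 bp product on testis dmrt1 only and the female-specific assay
#' a 207 bp product on ovary cyp19a1 only (the reverse primer spans the
#' full-length exon1/exon2 junction).
#'
#' @param seed RNG seed.
#' @return list with `dmrt1` and `cyp19a1` entries (each: `model`, `isoforms`
#'   named by tissue, `events` truth lists) and `assays` (primer pairs with
#'   expected product sizes).
#' @export
simulate_isoforms <- function(seed = 1L) {
  set.seed(substream_seed(seed, "isoforms"))
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

  # dmrt1-like: exon1a 3400-3699 (DM domain inside), exon2 4200-4499,
  # exon3 4800-4999; alternative first exon 1b at 1-59
  g1 <- rand_dna(5100)
  d_model <- gene_model(
    "dmrt1",
    data.frame(id = c("exon1a", "exon2", "exon3"),
               start = c(3400L, 4200L, 4800L), end = c(3699L, 4499L, 4999L)),
    genomic_sequence = g1,
    domains = data.frame(name = "DM", start = 101L, end = 200L))
  d_testis_chain <- d_model$exons[, c("start", "end")]
  d_ovary_chain <- data.frame(start = c(1L, 4200L, 4800L),
                              end = c(59L, 4499L, 4999L))
  d_iso <- list(
    testis = isoform("dmrt1a_testis", d_testis_chain,
                     splice_sequence(g1, d_testis_chain)),
    ovary = isoform("dmrt1b_ovary", d_ovary_chain,
                    splice_sequence(g1, d_ovary_chain)))

  # cyp19a1-like: 9 exons; exon1 196 bp, exon2 151 bp, exon3 120 bp, then
  # six 100 bp exons, introns 200 bp
  c_starts <- c(101L, 497L, 848L, 1168L, 1468L, 1768L, 2068L, 2368L, 2668L)
  c_ends <- c(296L, 647L, 967L, 1267L, 1567L, 1867L, 2167L, 2467L, 2767L)
  g2 <- rand_dna(2900)
  c_model <- gene_model(
    "cyp19a1",
    data.frame(id = paste0("exon", 1:9), start = c_starts, end = c_ends),
    genomic_sequence = g2)
  c_ovary_chain <- c_model$exons[, c("start", "end")]
  short1 <- data.frame(start = 101L, end = 263L)   # 196 -> 163 (3' cut)
  short2 <- data.frame(start = 547L, end = 647L)   # 151 -> 101 (5' cut)
  c_testis_chain <- rbind(short1, short2, c_ovary_chain[3:9, ])
  c_testis_noe3 <- rbind(short1, short2, c_ovary_chain[4:9, ])
  c_iso <- list(
    ovary = isoform("cyp19a1_full_ovary", c_ovary_chain,
                    splice_sequence(g2, c_ovary_chain)),
    testis = isoform("cyp19a1_short_testis", c_testis_chain,
                     splice_sequence(g2, c_testis_chain)),
    testis_noexon3 = isoform("cyp19a1_short_noe3_testis", c_testis_noe3,
                             splice_sequence(g2, c_testis_noe3)))

  # assay primers cut from the transcripts
  t_tx <- d_iso$testis$sequence
  male_assay <- list(
    seq_fwd = substr(t_tx, 10L, 30L),
    seq_rev = revcomp(substr(t_tx, 564L, 584L)),
    expected_bp = 575L)
  o_tx <- c_iso$ovary$sequence
  female_assay <- list(
    seq_fwd = substr(o_tx, 1L, 21L),
    seq_rev = revcomp(substr(o_tx, 187L, 207L)),
    expected_bp = 207L)

  events <- list(
    dmrt1_ovary = exon_diff(d_iso$ovary, d_model),
    cyp19a1_testis = exon_diff(c_iso$testis, c_model),
    cyp19a1_testis_noexon3 = exon_diff(c_iso$testis_noexon3, c_model))

  list(dmrt1 = list(model = d_model, isoforms = d_iso),
       cyp19a1 = list(model = c_model, isoforms = c_iso),
       assays = list(male = male_assay, female = female_assay),
       events = events)
}

#' Write a set of isoform transcripts as FASTA plus an exon-chain TSV
#'
#' @param iso_sim result of [simulate_isoforms()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_isoforms <- function(iso_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- character(0)
  chains <- list()
  for (gene in c("dmrt1", "cyp19a1")) {
    for (iso in iso_sim[[gene]]$isoforms) {
      seqs[iso$transcript_id] <- iso$sequence
      chains[[iso$transcript_id]] <-
        data.frame(gene = gene, transcript_id = iso$transcript_id,
                   exon_start = iso$exon_chain$start,
                   exon_end = iso$exon_chain$end)
    }
  }
  fa <- file.path(dir, "transcripts.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  tsv <- file.path(dir, "exon_chains.tsv")
  write.table(do.call(rbind, chains), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, chains = tsv))
}
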