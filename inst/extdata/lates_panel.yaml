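# Default BSAS amplicon panel: 7 sex-related genes, 11 amplicons,
# TSS-relative coordinates (no position zero) and locus-specific
# bisulfite-PCR primer pairs with Illumina overhang constants.
overhangs:
  FO: TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
  RO: GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG
spacer_length: 100
amplicons:
  - gene: dmrt1
    amplicon_id: "dmrt1 (1)"
    start: -575
    end: -305
    declared_length: 270
    declared_cpg_count: 5
    primers:
      name_fwd: D1-BS-P-F1Seq
      name_rev: D1-BS-P-R1Seq
      seq_fwd: GTTGATTAGGATTTGTGTTTTAAAGT
      seq_rev: TAAAACCTATTATTTCATATAAACATATTT
      overhang_fwd: FO
      overhang_rev: RO
  - gene: dmrt1
    amplicon_id: "dmrt1 (2)"
    start: -255
    end: 173
    declared_length: 428
    declared_cpg_count: 17
    primers:
      name_fwd: D1-BS-P-F2Seq
      name_rev: D1-BS-CDS-R1Seq
      seq_fwd: AAATTAAGTGTAGTAGAGTGATGTTAT
      seq_rev: AAACACTAACAATCCCTCCAATTAC
      overhang_fwd: FO
      overhang_rev: RO
  - gene: nr5a2
    amplicon_id: "nr5a2 (1)"
    start: -450
    end: -148
    declared_length: 302
    declared_cpg_count: 10
    primers:
      name_fwd: sf1-BS-F1.Seq
      name_rev: sf1-BS-R1.Seq
      seq_fwd: TTTTGTGTGTTTTTATTTGTTTGTG
      seq_rev: TTCTTTCTCAATTCTTTTAAACTTTTAAAT
      overhang_fwd: FO
      overhang_rev: RO
  - gene: nr5a2
    amplicon_id: "nr5a2 (2)"
    start: -79
    end: 115
    declared_length: 194
    declared_cpg_count: 8
    primers:
      name_fwd: sf1-BS-F2.Seq
      name_rev: sf1-BS-R2.Seq
      seq_fwd: GGAAAAGAGATTGTTTAGTATAGTAATAGA
      seq_rev: TAAAAACACTAACCTTACAACTCTC
      overhang_fwd: FO
      overhang_rev: RO
  - gene: cyp19a1
    amplicon_id: "cyp19a1"
    start: -107
    end: 160
    declared_length: 267
    declared_cpg_count: 8
    primers:
      name_fwd: CYP19-BS-F.Seq
      name_rev: CYP19-BS-R.Seq
      seq_fwd: TGGTTGTTTATAAAGGGGAAGTTT
      seq_rev: CCAACAACAAACAAACAAATAACATA
      overhang_fwd: FO
      overhang_rev: RO
  - gene: amh
    amplicon_id: "amh"
    start: -258
    end: 83
    declared_length: 341
    declared_cpg_count: 6
    primers:
      name_fwd: amh-F.Seq
      name_rev: amh-R.Seq
      seq_fwd: TGGTGTGTGTTTGAATTAGAAAATT
      seq_rev: CCATAAAAAACATAAAAAACCACAC
      overhang_fwd: FO
      overhang_rev: RO
  - gene: foxl2
    amplicon_id: "foxl2 (1)"
    start: -282
    end: -27
    declared_length: 255
    declared_cpg_count: 9
    primers:
      name_fwd: F2-BS-P-F1.Seq
      name_rev: F2-BS-P-R1.Seq
      seq_fwd: AAAGGGTTGGGTTTATTGATTTATAA
      seq_rev: ATCCAAATACCAACAAACAAAACTT
      overhang_fwd: FO
      overhang_rev: RO
  - gene: foxl2
    amplicon_id: "foxl2 (2)"
    start: 374
    end: 682
    declared_length: 308
    declared_cpg_count: 18
    primers:
      name_fwd: F2-BS-CDS-F1.Seq
      name_rev: F2-BS-CDS-R1.Seq
      seq_fwd: AGTTTGTGAGGATATGTTTGAGAAG
      seq_rev: CCATACTCTACACCCTAAAATAAAAATTAT
      overhang_fwd: FO
      overhang_rev: RO
  - gene: sox8
    amplicon_id: "sox8 (1)"
    start: -195
    end: 173
    declared_length: 368
    declared_cpg_count: 26
    primers:
      name_fwd: S8-BS-P-F2.Seq
      name_rev: S8-BS-R.Seq
      seq_fwd: TAAATAGGGAAGTAGAAGGGAAATAA
      seq_rev: AAATCCAATTTCTTACCCAAACC
      overhang_fwd: FO
      overhang_rev: RO
  - gene: sox8
    amplicon_id: "sox8 (2)"
    start: 151
    end: 504
    declared_length: 353
    declared_cpg_count: 20
    primers:
      name_fwd: S8-BS-CDS-F1.Seq
      name_rev: S8-BS-R2.Seq
      seq_fwd: GTTTGGGTAAGAAATTGGATTT
      seq_rev: TAACTACTCTATTATTTTCATTTAATACAA
      overhang_fwd: FO
      overhang_rev: RO
  - gene: sox9
    amplicon_id: "sox9"
    start: -130
    end: 214
    declared_length: 344
    declared_cpg_count: 19
    primers:
      name_fwd: S9-BS-F2.Seq
      name_rev: S9-BS-R2.Seq
      seq_fwd: ATTTAGTTTTGTTAGTTAAGTTGTG
      seq_rev: TACAAACAAAAAACTTTTCTTCTTC
      overhang_fwd: FO
      overhang_rev: RO
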