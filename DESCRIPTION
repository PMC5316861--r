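Package: ampedit
Title: Quantification of CRISPR/Cas9 Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying CRISPR/Cas9 editing outcomes at a dystrophin-like
    locus from amplicon deep-sequencing reads. Provides a synthetic multi-exon fixture
    locus and amplicon model, a read simulator with known per-read ground truth
    (unmodified, NHEJ indels, HDR with silent marker substitutions, mixed HDR/NHEJ,
    exon-excision junctions, exon-skip transcripts, template contamination), quality
    trimming and global alignment with indel calling under cut-site quantification
    windows and amplicon end exclusions, per-read outcome classification and
    search-sequence genotyping, reading-frame and functional-ORF accounting of edited
    reads, and guide design utilities including brute-force off-target enumeration
    with single-base bulges and codon-preserving silent-PAM donor design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
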