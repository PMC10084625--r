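Package: eukscreen
Title: Detection and Quantification of Eukaryotes in Shotgun Metagenomes
    from Marker-Gene Alignments
Version: 0.1.0
Authors@R:
    person("Eukscreen", "Developers", email = "eukscreen@example.org",
           role = c("aut", "cre"))
Description: Post-processes read alignments against a eukaryotic
    marker-gene reference (BUSCO-style single-copy orthologs) to detect
    and quantify microbial eukaryotes in shotgun metagenomes without
    relying on mapping-quality filters. All alignments of every read are
    retained; markers and then taxa are grouped by Markov clustering of
    shared-alignment graphs, taxa supported mostly by inferior-identity
    markers are rejected, and remaining taxa are reported either as
    unambiguous hits or as merged "?"-prefixed ambiguous hits, with
    abundance expressed as copies per million (CPM). Also ships a
    truth-labelled read simulator and fixture generator, precision/recall
    scoring of mappings (including MAPQ-filter benchmarking), and a
    pairwise taxon "confusability" framework (emit/accept rates, PCA
    embedding, greedy geospatial subsampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    data.table,
    optparse,
    stats,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
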