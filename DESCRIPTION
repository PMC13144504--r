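Package: clonetopo
Title: Clonal Topography of Barcoded Tumors and Virtual Biopsy Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well biopsies capture the clonal composition
    of lineage-barcoded tumors. Provides a stochastic agent-based simulator of
    3D tumor growth on a lattice with heritable clone identities, virtual
    sampling of the simulated tumor (dissection into pieces, directional needle
    biopsies at two depths, and a plasma cell-free DNA draw model),
    demultiplexing and counting of barcode amplicon sequencing reads against a
    known barcode library, the quality-control filter chain used for barcode
    count matrices (low-count zeroing, depth filtering, replicate concordance,
    sporadic-barcode removal, pooling and normalization), clonal diversity and
    representativeness statistics (Shannon index, barcode detection and biomass
    capture percentages, dominant-clone calls, center/periphery partitions), and
    seed-deterministic synthetic-data generators (barcode libraries, patchy
    multi-piece clone profiles, overdispersed replicate count matrices, FASTQ)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
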