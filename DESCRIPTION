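Package: methtopo
Title: CpG Methylation State Prediction from Sequence Composition and
    3D Genome Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the binary methylation state of CpG dinucleotides
    from DNA sequence composition and three-dimensional genome topology.
    Features are extracted from a sequence window centred on the target
    CpG site (nucleotide ratios, IUPAC pattern frequencies, pseudo
    trinucleotide composition) and from distal windows anchored by Hi-C
    contacts (sequence composition and averaged RRBS percent-methylation
    of spatial neighbours). Classification is by a stacked denoising
    autoencoder with layer-wise unsupervised pre-training and supervised
    fine-tuning, with a support vector machine baseline. Includes
    balanced binary labelling from percent-methylation tracks,
    leave-one-out and stratified five-fold cross-validation drivers,
    random-window controls for the topological features, and a synthetic
    genome/methylation/Hi-C simulator with planted spatial-domain
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
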