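Package: poremae
Title: Self-Supervised Masked-Autoencoder Classification of Nanopore Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies proteins and other analytes from single-molecule nanopore
    current-blockade events using generative self-supervised learning. Variable-length
    translocation events are resampled or padded to a fixed length, segmented into
    non-overlapping subsequences at the average per-residue signal span, randomly
    masked, and reconstructed in latent space by an asymmetric multi-head-attention
    autoencoder; the pretrained encoder is then fine-tuned with a small classifier head
    under cross-entropy. Includes a seeded simulator of barcode-carrier, protein-binding
    and 42-residue peptide translocation events (class structure driven by residue
    volume differences), experiment runners for k-fold cross-validation, data-scarcity
    curves, mask-ratio sweeps and a CNN-backbone ablation, plus portable NDJSON/TSV
    event formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
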