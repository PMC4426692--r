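Package: perturbnet
Title: Perturbation Spreading and Silencing-Time Analysis on Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spreading of perturbations on protein-protein
    interaction networks with a communicating-vessels energy-diffusion model:
    energy injected at seed nodes flows along edges in proportion to energy
    differences and dissipates at a fixed per-node rate. Computes silencing
    times and perturbation-reach values per seed node, compares node groups
    (drug targets with and without side effects, disease gene sets) with
    rank-sum and Welch tests, summarises degree, closeness and betweenness
    centralities, measures geodesic distances between drug-target and
    disease-protein sets, and generates synthetic scale-free interactomes
    with planted annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
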