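Package: tumorpde
Title: Free-Boundary PDE Model of Tumor-Immune Dynamics Under PD-1 and
    TGF-beta Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a spherically symmetric free-boundary
    reaction-diffusion-advection model of the tumor microenvironment,
    coupling cancer cells, macrophages, dendritic cells, T-cell subsets
    and regulatory T cells with the cytokines and checkpoint species that
    mediate immunosuppression (IL-2, IL-10, IL-12, CCL2, TGF-beta, PD-1,
    PD-L1). Constant total cell density closes an internal-pressure
    velocity field that moves the tumor boundary. Includes a well-mixed
    ODE reduction used as a solver oracle, treatment arms for anti-PD-1
    and anti-TGF-beta antibodies with constant-rate dosing windows, and
    experiment drivers that compute treatment efficacy, hyperprogression
    maps over two cancer-specific parameters, regulatory T-cell
    comparisons across arms, and dose-plane efficacy maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
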