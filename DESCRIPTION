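Package: lipidflux
Title: Kinetic Modelling and Flux-Correlation Analysis of Bacterial Membrane
    Lipid Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic ordinary-differential-equation model of the late
    saturated fatty-acid, phospholipid and lipopolysaccharide synthesis
    pathways of Escherichia coli, with steady-state solvers, enzyme Vmax
    scans, metabolic control analysis, dynamic perturbation simulation
    (ppGpp inhibition of PlsB, acetyl-CoA steps), and a statistical
    pipeline correlating phospholipid flux with metabolite and enzyme
    abundances across steady-state growth conditions.  Includes a
    synthetic LC/MS-style condition-table generator for end-to-end
    testing of the correlation pipeline against planted trends.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
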