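Package: fepaudit
Title: Auditing the Free Energy Principle in Weakly Coupled Linear
    Stochastic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing partitioned linear Langevin systems
    (external, sensory, active and internal states), solving their
    non-equilibrium steady states exactly via continuous Lyapunov
    equations and approximately via weak-coupling power series, and
    quantitatively auditing the statistical requirements of the free
    energy principle: the Markov blanket condition on the stationary
    precision matrix, block-decoupling of the solenoidal flow matrix,
    the conditional-Gaussian inference geometry (surprise, variational
    free energy, synchronisation maps), and the divergence between true
    conditional-mode trajectories and marginal-flow surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
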