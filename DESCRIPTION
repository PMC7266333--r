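Package: devtraj
Title: Latent Subgroups of Developmental Milestone Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies latent subgroups of children with developmental
    delay from binary milestone-achievement records. Each child's sequence
    of achievements is modelled by conjugate beta-Bernoulli sequential
    updating; the resulting posterior-mean trajectory is summarised as a
    rescaled area between the child's step function and a gold-standard
    reference trajectory, per functional domain; and the logit-transformed
    areas are clustered with a Dirichlet process mixture of multivariate
    normals fitted by a stick-breaking slice sampler with label-switching
    moves. A consensus partition is extracted from the posterior similarity
    matrix with partitioning around medoids and the average silhouette
    width, and convergence is monitored with the Gelman-Rubin statistic.
    Includes synthetic-data generators for milestone cohorts and bivariate
    Gaussian cluster benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    MASS,
    mvtnorm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
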