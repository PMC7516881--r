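Package: gaussfr
Title: Fisher-Rao Geometry of Multivariate Normal Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the information geometry of the multivariate normal
    family under the Fisher-Rao metric. Provides exact closed-form geodesic
    distances on the classical submanifolds (common covariance, common mean,
    diagonal covariance, diagonal covariance with mean along an eigenvector),
    the closed form for pairs sharing a covariance matrix, a non-linear-system
    solver for pairs with mirrored covariance matrices, the explicit geodesic
    in natural coordinates, a geodesic-shooting boundary-value solver, the
    Calvo-Oller lower bound and three upper bounds with their envelope, and
    Fisher-Rao agglomerative clustering for simplifying diagonal Gaussian
    mixture models, with Monte-Carlo Kullback-Leibler model selection and
    pixel classification for image segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
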