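Package: cultopt
Title: Neural-Network and Genetic-Algorithm Optimization of Tissue-Culture Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing bioprocess and plant tissue-culture conditions from
    small designed experiments. Builds and decodes five-level central composite designs,
    fits a three-layer backpropagation neural network (tan-sigmoid hidden layer, linear
    output) with gradient-descent trainers including momentum and adaptive learning
    rate as well as Levenberg-Marquardt, selects the trainer and hidden-layer width by
    repeated k-fold cross-validation, maximizes the trained surrogate over the coded
    factor box with a real-coded genetic algorithm, and fits a full-quadratic response
    surface baseline by ordinary least squares. Includes a synthetic response-surface
    generator for end-to-end recovery testing and ships a 31-run melon differentiation
    dataset as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
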