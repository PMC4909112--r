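Package: splanchsim
Title: Whole-Body Simulation of Splanchnic Blood Flow, Glucose Absorption
    and Hormonal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physiologically based whole-body simulator coupling a
    Kirchhoff resistance-compliance model of the human circulation to
    glucose, insulin, glucagon and GLP-1 secretion, transport, degradation
    and metabolism. Intestinal glucose absorption (active SGLT1 plus
    paracellular diffusion) feeds the splanchnic circulation, where
    glucose-driven GLP-1 release dilates the superior mesenteric artery
    and potentiates insulin action on liver and periphery. Duodenal-gavage
    glucose tolerance protocols, GLP-1-deficiency scenarios and NAFLD/NASH
    portosystemic-shunt scenarios are built in, together with the
    response-surface and hyperbolic dose-response machinery used to
    quantify parameter sensitivities and interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
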