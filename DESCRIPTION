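Package: socialfear
Title: Firing-Rate Model of the Rodent Social-Fear Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic firing-rate simulator of the brain circuit that
    controls social avoidance in rodents (VMHvl, dPAG, mPFC, MDT, with MeA,
    vHIP and lPBN inputs, plus a lateral-septum variant). Implements leaky
    rate units with a rectified-tanh activation integrated by the Euler
    method, a simplified BCM plasticity rule with weight clipping, the
    three-phase social fear conditioning and extinction protocol, in-silico
    lesion and stimulation experiments (silencing, stimulation, connection
    block and scaling, plasticity freeze, MDT high- and low-frequency
    stimulation), unit classification into fear, extinction and persistent
    populations, and a weight sensitivity analysis. Network, protocol and
    manipulation configurations are plain YAML files; results export to CSV
    and JSON, and a command-line interface wraps the main entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
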