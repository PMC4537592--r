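Package: aeropath
Title: Flight Efficiency of Migratory Songbirds from Automated Telemetry
    and Winds Aloft
Version: 0.1.0
Authors@R:
    person("Aeropath", "Developers", email = "aeropath@example.org",
           role = c("aut", "cre"))
Description: Reconstructs migratory flight segments from automated
    VHF telemetry detection data (signal-strength peak event times,
    pulse-rate false-positive filtering, antenna-pattern crossing-point
    classification, great-circle geometry), annotates tracks with
    tailwind and crosswind components interpolated in space and time
    from layered reanalysis-style wind fields, infers the most likely
    flight altitude per flight stage by an AICc scan across atmospheric
    levels, and fits multilevel piecewise path models (Fisher's C,
    path AICc, Akaike weights, backward elimination) relating age,
    flight stage, and wind to flight duration and groundspeed. Includes
    a seeded synthetic-data generator producing paired observables and
    ground truth for recovery testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
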