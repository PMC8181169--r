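Package: biohybrid
Title: Mean-Field Models of Robot-Organism Biohybrid Collectives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic mean-field compartment models of three biohybrid
    collectives in which robots participate in the feedback loops of living
    organisms: honeybee aggregation around thermal/vibration/airflow emitting
    sensor-actuator units, zebrafish directional shoaling with a robotic
    conspecific, and bean-shoot growth steered by light. All three models share
    a common structure of individual and socially induced (mass-action)
    switching between two compartments, integrated with a fixed-step
    Runge-Kutta scheme under per-step frozen noise. Includes experiment presets
    reproducing the in-silico protocols, seeded replicate ensembles, summary
    metrics, a diffusion-coupled lattice scale-up, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
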