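Package: phloemflow
Title: Biophysical Modelling of Convective Phloem Unloading in Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state biophysical models of phloem unloading from
    protophloem sieve elements in growing root tips. Computes hydraulic
    resistance of simple (annular) and funnel-shaped plasmodesmata by
    low-Reynolds-number lubrication theory, the pressure and concentration
    differentials required to drive the unloading flux by bulk flow,
    diffusion, or membrane-mediated water removal, Patlak
    convection-diffusion coupling through nanopores, van 't Hoff osmotic
    equivalents, plasmodesmal census arithmetic across the sieve-element
    wall interfaces, and a leaky-tube model of axial flow deceleration
    used to locate the unloading zone from velocity profiles. Includes
    seeded generators for synthetic measurement sets and a
    configuration-driven scenario report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllGenerics.R'
    'AllClasses.R'
    'pd-geometry.R'
    'census.R'
    'hydraulics.R'
    'transport.R'
    'scenario.R'
    'leaky-tube.R'
    'synthetic.R'
    'config.R'
    'run-scenario.R'
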