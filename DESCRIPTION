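Package: plumetrace
Title: Probe-Laser Analysis of MALDI Ion-Packet Ejection and Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the ejection time of ions produced by
    matrix-assisted laser desorption/ionization (MALDI) from sheet-probe
    photodepletion experiments in a linear time-of-flight (TOF) mass
    spectrometer.  Provides the closed-form one-dimensional kinematics of a
    charged particle ejected into a uniform extraction field and its
    inversion for the ejection time, a seedable Monte-Carlo simulator of
    ion-packet ensembles depleted by a sheet-like probe laser, spectrum
    differencing to locate the missing segment carved by the probe, the
    forward/backward remnant-peak correction of the probe position, and
    aggregation of per-observation ejection times into per-species and
    per-voltage estimates with closed-loop parameter-recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
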