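Package: retinahaze
Title: Retina-Inspired Single-Image Haze Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-image haze removal built from a computational model of the
    retinal circuit: photoreceptor sampling into cone, rod and yellow channels,
    ON/OFF bipolar cells with difference-of-Gaussians receptive fields, AII
    amacrine modulation of cone bipolars by the rod pathway, and single-opponent
    ganglion cells whose non-classical receptive-field surround is built from
    mutually inhibiting subunits (disinhibition). Includes a Koschmieder-model
    haze synthesizer driven by disparity maps, mean-squared-error evaluation,
    in-silico electrophysiology experiments (area-response and dispersion
    protocols), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
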