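Package: discform
Title: Discriminative Learning Networks and Formant-Trajectory Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how paradigmatic uncertainty about
    inflectional functions relates to the fine phonetic detail of speech.
    Implements two-layer Rescorla-Wagner learning networks over sliding-window
    corpus events under two contrasting input-output structures (inflectional
    functions as network outputs versus as network inputs), activation-based
    uncertainty measures for word-final schwa tokens, a penalized B-spline
    trajectory-regression ladder with tensor-product smooths, grouped factor
    smooths, AR1 pre-whitening and marginal-likelihood model comparison, a
    crossed-random-intercept duration model, and a synthetic artificial-language
    generator with known ground truth for end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
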