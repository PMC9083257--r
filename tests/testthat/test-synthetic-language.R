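test_that("lexicon respects configured counts, inventories and determinism", {
  cfg <- language_config(n_word_types = 10, prop_schwa_final = 0.5, seed = 1)
  lex <- build_lexicon(cfg)
  expect_equal(nrow(lex), 10)
  expect_equal(sum(lex$schwa_final), 5)
  expect_identical(lex, build_lexicon(cfg))

  labels <- unlist(strsplit(lex$functions[lex$schwa_final], ";"))
  expect_lte(length(unique(labels)), 60)
  inv <- attr(lex, "function_inventory")
  expect_true(all(labels %in% inv))

  # schwa-final iff phones end in "5" iff functions nonempty
  last <- vapply(strsplit(lex$phones, " "), function(p) p[length(p)], "")
  expect_equal(last == "5", lex$schwa_final)
  expect_equal(nzchar(lex$functions), lex$schwa_final)
})

test_that("invalid configurations name the offending field", {
  expect_error(language_config(n_word_types = 0), "n_word_types")
  expect_error(language_config(prop_schwa_final = 1.2), "prop_schwa_final")
  expect_error(language_config(zipf_exponent = -1), "zipf_exponent")
  expect_error(language_config(class_mix = c(content = 0.5,
                                             complex_function = 0.5,
                                             simple_function = 0.5)),
               "class_mix")
})

test_that("corpus sampling honours token counts and utterance structure", {
  cfg <- language_config(n_word_types = 30, n_tokens = 1000, seed = 2)
  lex <- build_lexicon(cfg)
  corpus <- sample_corpus(lex, cfg)
  expect_equal(nrow(corpus), 1000)
  expect_identical(corpus, sample_corpus(lex, cfg))
  # positions contiguous within utterances
  by_utt <- split(corpus$position, corpus$utterance_id)
  expect_true(all(vapply(by_utt, function(p)
    identical(p, seq_along(p)), logical(1))))
  # schwa tokens have positive durations, others none
  expect_true(all(corpus$vowel_duration_s[corpus$schwa_final] > 0))
  expect_true(all(is.na(corpus$vowel_duration_s[!corpus$schwa_final])))
})

test_that("type frequencies follow the Zipfian law", {
  cfg <- language_config(n_word_types = 2, prop_schwa_final = 0,
                         zipf_exponent = 1, n_tokens = 1e5, seed = 3)
  lex <- build_lexicon(cfg)
  corpus <- sample_corpus(lex, cfg)
  freq <- sort(table(corpus$form), decreasing = TRUE)
  ratio <- as.numeric(freq[1] / freq[2])
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
})

test_that("zero context predictivity leaves context independent of the bundle", {
  cfg <- language_config(n_word_types = 30, n_tokens = 8000,
                         context_predictivity = 0, seed = 4)
  lex <- build_lexicon(cfg)
  corpus <- sample_corpus(lex, cfg)
  i <- which(corpus$schwa_final & corpus$position > 1)
  prev <- corpus$form[i - 1]
  bundle <- corpus$functions[i]
  set.seed(1)
  p <- suppressWarnings(
    stats::chisq.test(table(prev, bundle), simulate.p.value = TRUE,
                      B = 500))$p.value
  expect_gt(p, 0.05)
})

test_that("formant tracks realize the generating model exactly when noise is off", {
  cfg <- language_config(n_word_types = 20, n_tokens = 400, n_speakers = 1,
                         seed = 6)
  lex <- build_lexicon(cfg)
  corpus <- sample_corpus(lex, cfg)
  schwa <- corpus[corpus$schwa_final, ]
  truth0 <- formant_ground_truth(delta_uncertainty = 0, delta_duration = 0,
                                 ar1_coef = 0, noise_sd = 1e-12)
  # fix durations so tracks of one class collapse onto the base curve
  schwa$vowel_duration_s <- 0.06
  tracks <- generate_formant_tracks(schwa, truth0, cfg)
  one_class <- schwa$token_id[schwa$word_class == schwa$word_class[1]]
  sub <- tracks[tracks$token_id %in% one_class, ]
  tn <- unlist(lapply(split(sub$t_s, sub$token_id), function(t) t / max(t)),
               use.names = FALSE)
  sub <- sub[order(sub$token_id), ]
  curve_spread <- tapply(sub$F1_Hz, round(tn, 6), function(v) diff(range(v)))
  expect_lt(max(curve_spread), 1e-6)

  # two tokens identical except bundle frequency: F1 gap is delta * d(u)
  truth1 <- formant_ground_truth(delta_uncertainty = 40, delta_duration = 0,
                                 ar1_coef = 0, noise_sd = 1e-12)
  tracks1 <- generate_formant_tracks(schwa, truth1, cfg)
  u <- attr(tracks1, "latent")
  cls <- schwa$word_class == schwa$word_class[1]
  ids <- schwa$token_id[cls][1:2]
  uu <- u$predictability[match(ids, u$token_id)]
  f1_first <- vapply(ids, function(id)
    tracks1$F1_Hz[tracks1$token_id == id][1], numeric(1))
  expect_equal(unname(diff(f1_first)), 40 * diff(uu), tolerance = 1e-6)

  expect_error(generate_formant_tracks(corpus[!corpus$schwa_final, ][1:2, ],
                                       truth0, cfg),
               "schwa-final")
})

test_that("track noise has the configured AR1 autocorrelation", {
  one <- data.frame(token_id = "t1", utterance_id = "u1", position = 1,
                    speaker = "s01", form = "x5", phones = "x 5",
                    word_class = "content", functions = "Substantiv",
                    schwa_final = TRUE, vowel_duration_s = 100,
                    speaking_rate = 5.5, n_segments = 2,
                    stringsAsFactors = FALSE)
  truth <- formant_ground_truth(delta_uncertainty = 0, delta_duration = 0,
                                ar1_coef = 0.8, noise_sd = 1)
  cfg <- language_config(seed = 9)
  tr <- generate_formant_tracks(one, truth, cfg)
  noise <- tr$F1_Hz - mean(tr$F1_Hz)
  # remove the deterministic base curve before measuring autocorrelation
  tn <- tr$t_s / max(tr$t_s)
  noise <- stats::resid(stats::lm(tr$F1_Hz ~ poly(tn, 2)))
  rho_hat <- stats::cor(noise[-1], noise[-length(noise)])
  expect_equal(rho_hat, 0.8, tolerance = 0.02)
})

test_that("the latent predictability axis is standardized over schwa tokens", {
  cfg <- language_config(seed = 7, n_tokens = 1500)
  corpus <- sample_corpus(build_lexicon(cfg), cfg)
  u <- bundle_predictability(corpus[corpus$schwa_final, ])
  expect_lt(abs(mean(u)), 1e-10)
  expect_lt(abs(stats::sd(u) - 1), 1e-10)
})

test_that("generated tracks survive the default filters at >= 95%", {
  cfg <- language_config(seed = 8)
  corpus <- sample_corpus(build_lexicon(cfg), cfg)
  schwa <- corpus[corpus$schwa_final, ]
  tracks <- generate_formant_tracks(schwa, formant_ground_truth(), cfg)
  filt <- filter_tracks(tracks, schwa)
  expect_gte(filt$report$tokens_kept / filt$report$tokens_in, 0.95)
})

test_that("corpus, track and ground-truth files round-trip", {
  cfg <- language_config(n_word_types = 15, n_tokens = 120, seed = 10)
  lex <- build_lexicon(cfg)
  corpus <- sample_corpus(lex, cfg)
  schwa <- corpus[corpus$schwa_final, ]
  tracks <- generate_formant_tracks(schwa, formant_ground_truth(), cfg)
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "corpus.tsv")
  p2 <- file.path(tmp, "tracks.csv")
  write_corpus(corpus, p1)
  back <- read_corpus(p1)
  expect_equal(back$form, corpus$form)
  expect_equal(back$functions, corpus$functions)
  expect_equal(back$schwa_final, corpus$schwa_final)
  expect_equal(back$vowel_duration_s, corpus$vowel_duration_s,
               tolerance = 1e-12)
  write_tracks(tracks, p2)
  tr <- read_tracks(p2)
  expect_equal(tr$F1_Hz, tracks$F1_Hz, tolerance = 1e-12)
  p3 <- file.path(tmp, "truth.json")
  write_ground_truth(formant_ground_truth(), p3)
  expect_true(jsonlite::validate(paste(readLines(p3), collapse = "")))
})
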