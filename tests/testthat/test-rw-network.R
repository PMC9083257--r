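test_that("single delta-rule updates follow the stated arithmetic", {
  p <- learning_params(lambda_max = 1, eta_present = 0.01, eta_absent = 0.01)
  w <- apply_update(NULL, list(cues = "c", outcomes = "o"), p)
  expect_equal(w["c", "o"], 0.01)

  w2 <- apply_update(NULL, list(cues = c("c1", "c2"), outcomes = "o"), p)
  expect_equal(unname(w2[, "o"]), c(0.01, 0.01))

  # present cue, absent outcome: weight decays toward zero
  w3 <- .empty <- apply_update(NULL, list(cues = "c", outcomes = "o"), p)
  w3["c", "o"] <- 0.5
  w3 <- apply_update(w3, list(cues = "c", outcomes = "x"), p)
  expect_equal(w3["c", "o"], 0.495)

  expect_error(apply_update(NULL, list(cues = character(0), outcomes = "o"),
                            p), "nonempty")
})

test_that("training converges geometrically and shows blocking", {
  p <- learning_params()
  expect_equal(dim(rw_train(list(), p)), c(0L, 0L))

  ev <- rep(list(list(cues = "c", outcomes = "o")), 1e4)
  w <- rw_train(ev, p)
  expect_equal(w["c", "o"], 1, tolerance = 1e-6)

  # classical blocking: pretrain A -> o, then compound AB -> o
  pre <- rep(list(list(cues = "A", outcomes = "o")), 2000)
  comp <- rep(list(list(cues = c("A", "B"), outcomes = "o")), 2000)
  wb <- rw_train(c(pre, comp), p)
  expect_lt(abs(wb["B", "o"]), 0.01)
})

test_that("the learner matches the brute-force oracle weight for weight", {
  events <- random_events(300, n_cues = 40, n_outcomes = 30, seed = 21)
  p <- learning_params(eta_present = 0.05, eta_absent = 0.02)
  w <- rw_train(events, p)
  w_oracle <- rw_oracle(events, p)
  expect_identical(unname(unclass(w)[, ]), unname(w_oracle[, ]))
})

test_that("first acquisition is monotone and bounded by lambda", {
  p <- learning_params(lambda_max = 2, eta_present = 0.1, eta_absent = 0.1)
  w <- NULL
  prev <- 0
  for (i in 1:200) {
    w <- apply_update(w, list(cues = "c", outcomes = "o"), p)
    expect_gte(w["c", "o"], prev)
    expect_lte(w["c", "o"], 2)
    prev <- w["c", "o"]
  }
})

test_that("total activation sums the requested weight block", {
  w <- rw_train(list(list(cues = c("c1", "c2"), outcomes = c("o1", "o2"))),
                learning_params())
  w["c1", "o1"] <- 0.2; w["c2", "o1"] <- 0.3; w["c1", "o2"] <- 0.5
  w["c2", "o2"] <- 0
  expect_equal(total_activation(w, c("c1", "c2"), "o1"), 0.5)
  expect_equal(total_activation(w, "c1", c("o1", "o2")), 0.7)
  expect_equal(total_activation(w, "unknown", "o1"), 0)
  expect_equal(total_activation(w, character(0), "o1"), 0)
  # additivity over disjoint cue sets
  expect_equal(total_activation(w, c("c1", "c2"), c("o1", "o2")),
               total_activation(w, "c1", c("o1", "o2")) +
                 total_activation(w, "c2", c("o1", "o2")))
  # mean variant averages across outcomes
  expect_equal(total_activation(w, "c1", c("o1", "o2"), aggregate = "mean"),
               0.35)
})

test_that("corpus activations match independent recomputation and are local", {
  cfg <- language_config(n_word_types = 25, n_tokens = 300, seed = 22)
  corpus <- sample_corpus(build_lexicon(cfg), cfg)
  spec <- network_spec("functional_input")
  w <- rw_train(stream_events(corpus, spec), learning_params())
  act <- activations_for_corpus(w, corpus, spec)
  expect_equal(nrow(act), sum(corpus$schwa_final))

  events <- stream_events(corpus, spec)
  i <- which(corpus$schwa_final)[1]
  expect_equal(act$activation[1],
               total_activation(w, events[[i]]$cues, "g:ER"))

  # editing a token in an utterance without schwa tokens leaves records alone
  by_utt <- split(seq_len(nrow(corpus)), corpus$utterance_id)
  no_schwa <- by_utt[[which(!vapply(by_utt, function(r)
    any(corpus$schwa_final[r]), logical(1)))[1]]]
  corpus2 <- corpus
  corpus2$form[no_schwa[1]] <- "zzzz"
  act2 <- activations_for_corpus(w, corpus2, spec)
  expect_equal(act2$activation, act$activation)
})

test_that("danks equilibrium solves the normal equations", {
  p <- learning_params()
  ev <- c(rep(list(list(cues = "c", outcomes = "o")), 7),
          rep(list(list(cues = "c", outcomes = "x")), 3))
  weq <- danks_equilibrium(ev, p)
  expect_equal(weq["c", "o"], 0.7, tolerance = 1e-10)

  pre <- rep(list(list(cues = "A", outcomes = "o")), 50)
  comp <- rep(list(list(cues = c("A", "B"), outcomes = "o")), 50)
  wb <- danks_equilibrium(c(pre, comp), p)
  expect_lt(abs(wb["B", "o"]), 1e-8)

  # cues that never co-occur each recover their own conditional probability
  ev2 <- c(rep(list(list(cues = "a", outcomes = "o")), 4),
           rep(list(list(cues = "a", outcomes = "x")), 6),
           rep(list(list(cues = "b", outcomes = "o")), 9),
           rep(list(list(cues = "b", outcomes = "x")), 1))
  w2 <- danks_equilibrium(ev2, p)
  expect_equal(w2["a", "o"], 0.4, tolerance = 1e-10)
  expect_equal(w2["b", "o"], 0.9, tolerance = 1e-10)
})

test_that("long-run training approaches the analytic equilibrium", {
  base <- c(rep(list(list(cues = c("a", "b"), outcomes = "o")), 3),
            rep(list(list(cues = "a", outcomes = "x")), 4),
            rep(list(list(cues = c("b"), outcomes = "o")), 3))
  set.seed(31)
  stream <- base[sample(rep(seq_along(base), 8000))]
  p <- learning_params(eta_present = 5e-4, eta_absent = 5e-4)
  w <- rw_train(stream, p)
  weq <- danks_equilibrium(base, p)
  expect_lt(max(abs(unclass(w)[, ] - weq[rownames(w), colnames(w)])), 0.01)
})

test_that("weights round-trip losslessly through the triplet format", {
  events <- random_events(50, n_cues = 12, n_outcomes = 8, seed = 23)
  w <- rw_train(events, learning_params(eta_present = 0.07))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, tmp)
  back <- read_weights(tmp)
  expect_identical(dimnames(back), dimnames(w))
  expect_identical(unname(unclass(back)[, ]), unname(unclass(w)[, ]))
  expect_equal(attr(back, "params")$eta_present, 0.07)
})
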