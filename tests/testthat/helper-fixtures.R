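# Shared fixtures and independent oracles, built in code at test time.

# The five-word demonstration window "das ist dieser große mann" with the
# target "dieser" (demonstrative pronoun, masculine, nominative) in the
# center; phones follow the single-character convention with "5" = aschwa.
worked_example_window <- function() {
  data.frame(
    token_id = paste0("t", 1:5),
    utterance_id = "u1",
    position = 1:5,
    form = c("das", "ist", "dieser", "große", "mann"),
    phones = c("d a s", "I s t", "d i z 5", "g r o s @", "m a n"),
    word_class = c("other", "other", "complex_function", "other", "other"),
    functions = c("", "", "Demonstrativpronomen;Maskulin;Nominativ", "", ""),
    schwa_final = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    vowel_duration_s = c(NA, NA, 0.06, NA, NA),
    speaking_rate = 5.5,
    n_segments = c(3, 3, 4, 5, 3),
    stringsAsFactors = FALSE)
}

worked_example_diphones <- c("#d", "da", "as", "sI", "Is", "st", "td", "di",
                             "iz", "z5", "5g", "gr", "ro", "os", "s@", "@m",
                             "ma", "an", "n#")

# Independently coded brute-force delta-rule updater: explicit per-outcome,
# per-cue scalar updates. Kept structurally different from rw_train() on
# purpose; it is the oracle the learner is checked against.
rw_oracle <- function(events, params) {
  cues <- sort(unique(unlist(lapply(events, `[[`, "cues"))), method = "radix")
  outs <- sort(unique(unlist(lapply(events, `[[`, "outcomes"))),
               method = "radix")
  w <- matrix(0, length(cues), length(outs), dimnames = list(cues, outs))
  for (e in events) {
    ec <- sort(match(e$cues, cues))
    present <- outs %in% e$outcomes
    for (j in seq_along(outs)) {
      V <- sum(w[ec, j])
      delta <- if (present[j]) params$eta_present * (params$lambda_max - V)
      else params$eta_absent * (0 - V)
      for (ci in ec) w[ci, j] <- w[ci, j] + delta
    }
  }
  w
}

# Random event stream over bounded label inventories.
random_events <- function(n_events, n_cues = 50, n_outcomes = 50, seed = 1) {
  set.seed(seed)
  cues <- sprintf("c%02d", seq_len(n_cues))
  outs <- sprintf("o%02d", seq_len(n_outcomes))
  lapply(seq_len(n_events), function(i) {
    list(cues = sample(cues, sample(1:6, 1)),
         outcomes = sample(outs, sample(1:3, 1)),
         center_token_id = paste0("t", i))
  })
}

# Small synthetic world used by several module tests.
tiny_experiment_config <- function(seed = 5, ...) {
  experiment_config(
    language = language_config(n_word_types = 40, n_tokens = 500,
                               n_speakers = 4, seed = seed),
    ladder_models = "m1", ablation = FALSE,
    fit_control = list(maxit = 80, starts = 1), seed = seed, ...)
}

# Five-token track fixture with exactly two rule violations: one token too
# short, one token with all samples out of the F1 range.
violation_fixture <- function() {
  mk <- function(id, sp, t, f1, f2)
    data.frame(token_id = id, speaker = sp, t_s = t, F1_Hz = f1, F2_Hz = f2,
               stringsAsFactors = FALSE)
  tracks <- rbind(
    mk("a", "s1", c(0, .02, .04), c(500, 520, 540), c(1500, 1510, 1520)),
    mk("b", "s1", c(0, .02, .04), c(600, 610, 620), c(1400, 1410, 1420)),
    mk("c", "s1", c(0, .01), c(550, 560), c(1450, 1460)),        # too short
    mk("d", "s2", c(0, .02, .04), c(1200, 1250, 1300), c(1500, 1500, 1500)), # F1 out
    mk("e", "s2", c(0, .02, .04), c(450, 470, 490), c(1600, 1610, 1620)))
  durations <- c(a = 0.05, b = 0.05, c = 0.010, d = 0.05, e = 0.05)
  list(tracks = tracks, durations = durations,
       kept = c("a", "b", "e"))
}

# Simulated crossed-random-intercept data with known components.
simulate_lmm <- function(n = 2000, n_g1 = 50, n_g2 = 200, beta = c(0.5, 0.3),
                         sd_g1 = 0.3, sd_g2 = 0.2, sd_e = 0.1, seed = 1) {
  set.seed(seed)
  g1 <- sample(sprintf("a%02d", seq_len(n_g1)), n, replace = TRUE)
  g2 <- sample(sprintf("b%03d", seq_len(n_g2)), n, replace = TRUE)
  x <- rnorm(n)
  u <- stats::setNames(rnorm(n_g1, 0, sd_g1), sprintf("a%02d", seq_len(n_g1)))
  v <- stats::setNames(rnorm(n_g2, 0, sd_g2), sprintf("b%03d", seq_len(n_g2)))
  y <- beta[1] + beta[2] * x + u[g1] + v[g2] + rnorm(n, 0, sd_e)
  list(y = as.numeric(y), X = cbind(1, x = x), g1 = g1, g2 = g2)
}
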