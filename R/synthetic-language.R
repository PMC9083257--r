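#' Configuration for the synthetic artificial language
#'
#' Defines the statistical structure of a generated corpus: Zipfian word-type
#' frequencies, a fixed inventory of inflectional-function labels attached to
#' schwa-final word types, three word classes for schwa-final words, and
#' context words that are partially predictive of the target's function
#' bundle.
#'
#' @param n_word_types number of word types in the lexicon.
#' @param n_phones size of the phone inventory (single-character symbols; the
#'   schwa symbol \code{"5"} and the boundary symbol \code{"#"} are reserved
#'   and not part of this inventory).
#' @param n_functions size of the inflectional-function label inventory.
#' @param prop_schwa_final fraction of word types that are schwa-final and
#'   carry a function bundle.
#' @param zipf_exponent exponent of the Zipfian type-frequency distribution
#'   (probability of rank r proportional to r^-zipf_exponent).
#' @param n_speakers number of speakers.
#' @param n_tokens number of word tokens to sample.
#' @param context_predictivity probability that the word preceding a
#'   schwa-final target is drawn from a bundle-specific signal set, making
#'   context informative about the target's functions.
#' @param class_mix named fractions for the three schwa-word classes
#'   \code{content}, \code{complex_function}, \code{simple_function}; must sum
#'   to 1.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class \code{language_config}.
#' @export
language_config <- function(n_word_types = 80, n_phones = 20, n_functions = 60,
                            prop_schwa_final = 0.25, zipf_exponent = 1,
                            n_speakers = 6, n_tokens = 3000,
                            context_predictivity = 0.3,
                            class_mix = c(content = 0.48,
                                          complex_function = 0.09,
                                          simple_function = 0.43),
                            seed = 1L) {
  cfg <- list(
    n_word_types = check_count(n_word_types, "n_word_types"),
    n_phones = check_count(n_phones, "n_phones", min = 2),
    n_functions = check_count(n_functions, "n_functions"),
    prop_schwa_final = check_fraction(prop_schwa_final, "prop_schwa_final"),
    zipf_exponent = zipf_exponent,
    n_speakers = check_count(n_speakers, "n_speakers"),
    n_tokens = check_count(n_tokens, "n_tokens"),
    context_predictivity = check_fraction(context_predictivity,
                                          "context_predictivity"),
    class_mix = class_mix,
    seed = as.integer(seed)
  )
  if (!is.numeric(zipf_exponent) || length(zipf_exponent) != 1 ||
      zipf_exponent <= 0)
    stopf("configuration error: 'zipf_exponent' must be a real > 0")
  if (length(class_mix) != 3 ||
      !setequal(names(class_mix),
                c("content", "complex_function", "simple_function")))
    stopf("configuration error: 'class_mix' needs the three named classes")
  if (abs(sum(class_mix) - 1) > 1e-12)
    stopf("configuration error: 'class_mix' must sum to 1")
  if (any(class_mix < 0 | class_mix > 1))
    stopf("configuration error: 'class_mix' fractions must lie in [0, 1]")
  if (length(seed) != 1 || !is.finite(seed))
    stopf("configuration error: 'seed' must be a single integer")
  class(cfg) <- "language_config"
  cfg
}

#' Ground truth for synthetic formant-track generation
#'
#' Effect sizes used by \code{\link{generate_formant_tracks}}, recorded so that
#' recovery tests can compare pipeline estimates against the generating values.
#' Effects are expressed in Hz on the raw tracks (speaker normalization happens
#' downstream): \code{delta_uncertainty} is the F1 shift in Hz per one standard
#' deviation of the latent predictability axis (standardized log
#' function-bundle frequency); the same amount is subtracted from F2, so a
#' positive value lowers and retracts the vowel for well-supported bundles.
#'
#' @param delta_uncertainty Hz per SD of standardized log bundle frequency.
#' @param delta_duration Hz per unit of log duration (relative to a 60 ms
#'   reference, which is absorbed into the base curve).
#' @param speaker_offsets optional named numeric vector of per-speaker Hz
#'   offsets (applied to both formants); defaults to zero offsets.
#' @param ar1_coef lag-1 autocorrelation of the additive track noise,
#'   in (-1, 1).
#' @param noise_sd stationary standard deviation of the track noise in Hz.
#' @return an object of class \code{formant_ground_truth}.
#' @export
formant_ground_truth <- function(delta_uncertainty = 40, delta_duration = 50,
                                 speaker_offsets = NULL, ar1_coef = 0.6,
                                 noise_sd = 25) {
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stopf("configuration error: 'noise_sd' must be > 0")
  if (!is.finite(ar1_coef) || abs(ar1_coef) >= 1)
    stopf("configuration error: 'ar1_coef' must lie in (-1, 1)")
  out <- list(delta_uncertainty = delta_uncertainty,
              delta_duration = delta_duration,
              speaker_offsets = speaker_offsets,
              ar1_coef = ar1_coef, noise_sd = noise_sd)
  class(out) <- "formant_ground_truth"
  out
}

# Fixed pools the function-label inventory is assembled from; mirrors the
# grammatical-class x number x gender x case structure of German inflectional
# functions realized by word-final aschwa.
.function_pools <- function(n_functions) {
  gram <- c("Substantiv", "Adjektiv", "Artikel", "Demonstrativpronomen",
            "Possessivpronomen", "Personalpronomen", "Relativpronomen",
            "Adverb", "Komparativ", "Indefinitpronomen",
            "Interrogativpronomen", "Verbpartikel")
  num <- c("Singular", "Plural")
  gen <- c("Maskulin", "Feminin", "Neutrum")
  cas <- c("Nominativ", "Genitiv", "Dativ", "Akkusativ")
  pool <- c(gram, num, gen, cas)
  if (n_functions > length(pool))
    pool <- c(pool, sprintf("Funktion%02d", seq_len(n_functions - length(pool))))
  inv <- pool[seq_len(n_functions)]
  list(inventory = inv,
       class_like = setdiff(inv, c(num, gen, cas)),
       feature_like = intersect(inv, c(num, gen, cas)))
}

.phone_pool <- c("a", "e", "i", "o", "u", "I", "E", "O", "U", "y", "@",
                 "p", "b", "t", "d", "k", "g", "f", "v", "s", "z", "S",
                 "Z", "m", "n", "N", "l", "r", "R", "x", "h", "j", "w")

#' Build a synthetic lexicon
#'
#' Creates \code{n_word_types} entries. Schwa-final entries end in the schwa
#' symbol \code{"5"}, belong to one of the three word classes (allocated
#' according to \code{class_mix}), and carry a function bundle of 1--3 labels
#' drawn from the inventory. Bundles are shared across types (several types
#' realize the same bundle), mirroring the many-to-few mapping from word types
#' to inflectional functions. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{language_config}}.
#' @return a data frame of class \code{discform_lexicon} with columns
#'   \code{form}, \code{phones} (space-joined symbols), \code{word_class},
#'   \code{functions} (semicolon-joined labels), \code{schwa_final}.
#' @export
build_lexicon <- function(config) {
  if (!inherits(config, "language_config"))
    stopf("configuration error: 'config' must be a language_config")
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_word_types
    inv <- .phone_pool[seq_len(min(config$n_phones, length(.phone_pool)))]
    n_schwa <- round(n * config$prop_schwa_final)
    schwa_idx <- sort(sample.int(n, n_schwa))
    schwa <- seq_len(n) %in% schwa_idx

    phones <- vector("list", n)
    forms <- character(n)
    for (i in seq_len(n)) {
      len <- sample(2:5, 1)
      p <- sample(inv, len, replace = TRUE)
      if (schwa[i]) p <- c(p, "5") else
        while (p[length(p)] == "5") p[length(p)] <- sample(inv, 1)
      phones[[i]] <- p
      forms[i] <- tolower(paste0(p, collapse = ""))
    }
    # forms must be unique and lower-case (word cues are case-folded)
    dup <- duplicated(forms)
    while (any(dup)) {
      forms[dup] <- paste0(forms[dup], sample(letters, sum(dup), replace = TRUE))
      dup <- duplicated(forms)
    }

    # word classes: proportional allocation of class_mix over schwa types
    classes <- rep("other", n)
    if (n_schwa > 0) {
      mix <- config$class_mix[c("content", "complex_function", "simple_function")]
      cnt <- floor(mix * n_schwa)
      rem <- n_schwa - sum(cnt)
      if (rem > 0) {
        frac <- mix * n_schwa - cnt
        add <- order(frac, decreasing = TRUE)[seq_len(rem)]
        cnt[add] <- cnt[add] + 1
      }
      classes[schwa_idx] <- sample(rep(names(cnt), cnt))
    }

    # function bundles: a small set of distinct bundles shared across types
    pools <- .function_pools(config$n_functions)
    n_bundles <- max(2L, ceiling(n_schwa / 2.5))
    bundles <- vector("list", n_bundles)
    for (b in seq_len(n_bundles)) {
      size <- sample(1:3, 1)
      lab <- sample(pools$class_like, 1)
      if (size > 1 && length(pools$feature_like) > 0)
        lab <- c(lab, sample(pools$feature_like,
                             min(size - 1, length(pools$feature_like))))
      bundles[[b]] <- sort(unique(lab))
    }
    funs <- rep("", n)
    if (n_schwa > 0) {
      assign_b <- sample.int(n_bundles, n_schwa, replace = TRUE)
      funs[schwa_idx] <- vapply(bundles[assign_b],
                                paste0, "", collapse = ";")
    }

    lex <- data.frame(form = forms,
                      phones = vapply(phones, paste, "", collapse = " "),
                      word_class = classes,
                      functions = funs,
                      schwa_final = schwa,
                      stringsAsFactors = FALSE)
    attr(lex, "function_inventory") <- pools$inventory
    attr(lex, "phone_inventory") <- inv
    class(lex) <- c("discform_lexicon", "data.frame")
    lex
  })
}

#' Sample a token corpus from a lexicon
#'
#' Draws \code{n_tokens} tokens with Zipfian type frequencies, partitions them
#' into utterances of geometric length (mean 8, minimum 1), assigns one
#' speaker per utterance, and — with probability \code{context_predictivity} —
#' rewrites the word preceding each schwa-final target to a draw from a
#' bundle-specific signal set of non-schwa types, so that context carries
#' information about the target's function bundle. Schwa tokens receive
#' log-normal vowel durations scaled by local speaking rate.
#'
#' @param lexicon a \code{\link{build_lexicon}} result.
#' @param config the \code{\link{language_config}} used to build it.
#' @return a data frame of class \code{discform_corpus}, one row per token,
#'   ordered by utterance and position.
#' @export
sample_corpus <- function(lexicon, config) {
  if (nrow(lexicon) == 0) stopf("'lexicon' must be nonempty")
  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_tokens
    n_types <- nrow(lexicon)
    prob <- seq_len(n_types)^(-config$zipf_exponent)
    prob <- prob / sum(prob)

    # utterance lengths: 1 + geometric, mean 8
    lens <- integer(0)
    while (sum(lens) < n) lens <- c(lens, 1L + stats::rgeom(max(16, n %/% 4), 1 / 8))
    cum <- cumsum(lens)
    n_utt <- which(cum >= n)[1]
    lens <- lens[seq_len(n_utt)]
    lens[n_utt] <- lens[n_utt] - (cum[n_utt] - n)
    lens <- lens[lens > 0]

    type <- sample.int(n_types, n, replace = TRUE, prob = prob)
    utt <- rep(seq_along(lens), lens)
    pos <- unlist(lapply(lens, seq_len), use.names = FALSE)

    # bundle-specific signal sets among non-schwa types
    keys <- unique(lexicon$functions[lexicon$schwa_final])
    nons <- which(!lexicon$schwa_final)
    signal <- NULL
    if (length(keys) > 0 && length(nons) >= 2) {
      signal <- lapply(keys, function(k) sample(nons, 2))
      names(signal) <- keys
      cp <- config$context_predictivity
      if (cp > 0) {
        is_target <- lexicon$schwa_final[type] & pos > 1
        rewrite <- is_target & stats::runif(n) < cp
        for (i in which(rewrite)) {
          key <- lexicon$functions[type[i]]
          type[i - 1] <- sample(signal[[key]], 1)
        }
      }
    }

    speaker_of_utt <- sample.int(config$n_speakers, length(lens), replace = TRUE)
    base_rate <- stats::rnorm(config$n_speakers, 5.5, 0.5)
    speaker <- sprintf("s%02d", speaker_of_utt[utt])
    rate <- base_rate[speaker_of_utt[utt]] * exp(stats::rnorm(n, 0, 0.08))

    schwa <- lexicon$schwa_final[type]
    dur <- rep(NA_real_, n)
    dur[schwa] <- exp(stats::rnorm(sum(schwa), log(0.06), 0.45)) *
      (5.5 / rate[schwa])

    corpus <- data.frame(
      token_id = sprintf("t%06d", seq_len(n)),
      utterance_id = sprintf("u%05d", utt),
      position = pos,
      speaker = speaker,
      form = lexicon$form[type],
      phones = lexicon$phones[type],
      word_class = lexicon$word_class[type],
      functions = lexicon$functions[type],
      schwa_final = schwa,
      vowel_duration_s = dur,
      speaking_rate = rate,
      n_segments = lengths(strsplit(lexicon$phones[type], " ", fixed = TRUE)),
      stringsAsFactors = FALSE)
    class(corpus) <- c("discform_corpus", "data.frame")
    corpus
  })
}

#' Standardized log function-bundle frequency
#'
#' The latent predictability axis of the generator: per schwa token, the log
#' of its function bundle's token frequency, standardized to mean 0 and sd 1
#' over the supplied tokens. This is the quantity the activation measures are
#' expected to recover; the pipeline itself never reads it.
#'
#' @param tokens schwa-final rows of a \code{discform_corpus}.
#' @return numeric vector aligned with \code{tokens} rows.
#' @export
bundle_predictability <- function(tokens) {
  if (any(!tokens$schwa_final))
    stopf("domain error: all tokens must be schwa-final")
  freq <- table(tokens$functions)
  lf <- log(as.numeric(freq[tokens$functions]))
  if (length(lf) < 2 || stats::sd(lf) == 0) return(rep(0, length(lf)))
  as.numeric(scale(lf))
}

# class-specific u-shaped base curves (Hz), quadratic in normalized time;
# values stay inside F1 [350, 900], F2 [1100, 1900] before noise
.base_curves <- list(
  content          = c(f1_a = 700, f1_b = -120, f2_a = 1450, f2_b = 80),
  complex_function = c(f1_a = 680, f1_b = -160, f2_a = 1600, f2_b = 120),
  simple_function  = c(f1_a = 650, f1_b = -60,  f2_a = 1350, f2_b = 40))

.ar1_noise <- function(m, rho, sd) {
  innov <- stats::rnorm(m, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Generate synthetic formant tracks for schwa tokens
#'
#' Per token, samples F1/F2 at 100 Hz (minimum 3 samples) from a
#' class-specific u-shaped base curve plus a log-duration height shift, a
#' latent-predictability shift of \code{delta_uncertainty} Hz per SD
#' (added to F1, subtracted from F2), a per-speaker offset, and AR1 noise.
#'
#' @param tokens schwa-final rows of a \code{discform_corpus} with positive
#'   durations.
#' @param truth a \code{\link{formant_ground_truth}}.
#' @param config the generating \code{\link{language_config}} (supplies the
#'   seed).
#' @param seed optional seed override.
#' @return long data frame of class \code{discform_tracks} with columns
#'   \code{token_id}, \code{speaker}, \code{t_s}, \code{F1_Hz}, \code{F2_Hz};
#'   the latent predictability axis is attached as attribute \code{"latent"}.
#' @export
generate_formant_tracks <- function(tokens, truth, config,
                                    seed = derive_seed(config$seed, 3L)) {
  if (any(!tokens$schwa_final) ||
      any(!is.finite(tokens$vowel_duration_s) | tokens$vowel_duration_s <= 0))
    stopf("domain error: tokens must be schwa-final with positive duration")
  u <- bundle_predictability(tokens)
  offsets <- truth$speaker_offsets
  if (is.null(offsets)) {
    offsets <- stats::setNames(rep(0, length(unique(tokens$speaker))),
                               unique(tokens$speaker))
  }
  with_seed(seed, {
    res <- vector("list", nrow(tokens))
    for (i in seq_len(nrow(tokens))) {
      dur <- tokens$vowel_duration_s[i]
      m <- max(3L, 1L + floor(dur * 100))
      t_s <- seq(0, dur, length.out = m)
      tn <- if (dur > 0) t_s / dur else rep(0, m)
      cls <- tokens$word_class[i]
      if (!cls %in% names(.base_curves))
        stopf("domain error: unknown word class '%s'", cls)
      b <- .base_curves[[cls]]
      off <- offsets[tokens$speaker[i]]
      if (is.na(off)) off <- 0
      shift <- truth$delta_duration * (log(dur) - log(0.06)) + off
      f1 <- b["f1_a"] + b["f1_b"] * (2 * tn - 1)^2 +
        truth$delta_uncertainty * u[i] + shift
      f2 <- b["f2_a"] + b["f2_b"] * (2 * tn - 1)^2 -
        truth$delta_uncertainty * u[i] + shift
      if (truth$noise_sd > 0) {
        f1 <- f1 + .ar1_noise(m, truth$ar1_coef, truth$noise_sd)
        f2 <- f2 + .ar1_noise(m, truth$ar1_coef, truth$noise_sd)
      }
      res[[i]] <- data.frame(token_id = tokens$token_id[i],
                             speaker = tokens$speaker[i],
                             t_s = t_s, F1_Hz = as.numeric(f1),
                             F2_Hz = as.numeric(f2),
                             stringsAsFactors = FALSE)
    }
    tracks <- do.call(rbind, res)
    rownames(tracks) <- NULL
    attr(tracks, "latent") <- data.frame(token_id = tokens$token_id,
                                         predictability = u,
                                         bundle = tokens$functions,
                                         stringsAsFactors = FALSE)
    class(tracks) <- c("discform_tracks", "data.frame")
    tracks
  })
}

#' @rdname corpus_io
#' @param corpus a \code{discform_corpus}.
#' @param path file path.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(as.data.frame(corpus), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Corpus and track serialization
#'
#' The corpus is a UTF-8 tab-separated table (functions semicolon-joined);
#' tracks are long-format CSV; ground truth is a JSON sidecar.
#'
#' @name corpus_io
#' @export
read_corpus <- function(path) {
  corpus <- utils::read.delim(path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8", na.strings = "")
  corpus$functions[is.na(corpus$functions)] <- ""
  corpus$schwa_final <- as.logical(corpus$schwa_final)
  class(corpus) <- c("discform_corpus", "data.frame")
  corpus
}

#' @rdname corpus_io
#' @param tracks a \code{discform_tracks}.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_tracks <- function(path) {
  tracks <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tracks) <- c("discform_tracks", "data.frame")
  tracks
}

#' @rdname corpus_io
#' @param truth a \code{\link{formant_ground_truth}}.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
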