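#' Exclusion thresholds for raw formant tracks
#'
#' Defaults follow the standard cleaning of spontaneous-speech formant data:
#' vowels shorter than 18 ms are excluded, F1 measurements must lie in
#' 250--1000 Hz and F2 measurements in 1000--2000 Hz, and tokens keeping fewer
#' than 3 in-range samples are dropped.
#'
#' @param min_duration minimum vowel duration in seconds.
#' @param f1_range,f2_range admissible Hz ranges.
#' @param min_samples_per_token minimum surviving samples per token.
#' @return an object of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_duration = 0.018,
                              f1_range = c(250, 1000),
                              f2_range = c(1000, 2000),
                              min_samples_per_token = 3) {
  if (!is.finite(min_duration) || min_duration <= 0)
    stopf("configuration error: 'min_duration' must be > 0")
  for (nm in c("f1_range", "f2_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] >= r[2])
      stopf("configuration error: '%s' must be an ordered pair", nm)
  }
  out <- list(min_duration = min_duration, f1_range = f1_range,
              f2_range = f2_range,
              min_samples_per_token = check_count(min_samples_per_token,
                                                  "min_samples_per_token"))
  class(out) <- "filter_thresholds"
  out
}

#' Filter raw formant tracks
#'
#' Rules apply in a fixed precedence with no double counting: (1) tokens with
#' duration below \code{min_duration} are dropped whole; (2) individual
#' samples with F1 or F2 outside range are dropped; (3) tokens left with
#' fewer than \code{min_samples_per_token} samples are dropped. The report
#' counts tokens removed by each rule.
#'
#' @param tracks a \code{discform_tracks} data frame.
#' @param durations named numeric vector of vowel durations (seconds) by
#'   token id, or a \code{discform_corpus} to take them from.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return list with \code{tracks} (kept samples) and \code{report} (counts
#'   per rule, plus tokens in/out and samples dropped).
#' @export
filter_tracks <- function(tracks, durations,
                          thresholds = filter_thresholds()) {
  if (inherits(durations, "data.frame"))
    durations <- stats::setNames(durations$vowel_duration_s,
                                 durations$token_id)
  if (any(durations < 0, na.rm = TRUE))
    stopf("data error: negative vowel duration")
  tokens_in <- unique(tracks$token_id)
  dur <- durations[tokens_in]

  short <- tokens_in[!is.na(dur) & dur < thresholds$min_duration]
  keep <- !(tracks$token_id %in% short)
  stage2 <- tracks[keep, , drop = FALSE]

  in_range <- stage2$F1_Hz >= thresholds$f1_range[1] &
    stage2$F1_Hz <= thresholds$f1_range[2] &
    stage2$F2_Hz >= thresholds$f2_range[1] &
    stage2$F2_Hz <= thresholds$f2_range[2]
  n_samples_dropped <- sum(!in_range)
  affected <- unique(stage2$token_id[!in_range])
  stage3 <- stage2[in_range, , drop = FALSE]

  counts <- table(stage3$token_id)
  thin <- names(counts)[counts < thresholds$min_samples_per_token]
  # tokens that lost every sample to the range rule also fail the count rule
  gone <- setdiff(unique(stage2$token_id), unique(stage3$token_id))
  thin <- union(thin, gone)
  kept <- stage3[!(stage3$token_id %in% thin), , drop = FALSE]

  report <- list(
    tokens_in = length(tokens_in),
    tokens_kept = length(unique(kept$token_id)),
    dropped_duration = length(short),
    dropped_range = length(intersect(thin, affected)),
    dropped_sparse = length(setdiff(thin, affected)),
    samples_dropped_range = n_samples_dropped)
  class(kept) <- class(tracks)
  list(tracks = kept, report = report)
}

#' Normalize filtered formant tracks
#'
#' F1 is multiplied by -1 (so that higher values correspond to higher tongue
#' positions), then each of (-F1, F2) is centered and scaled to unit standard
#' deviation within speaker and dimension; per-token time is mapped affinely
#' onto [0, 1].
#'
#' @param tracks kept tracks from \code{\link{filter_tracks}}.
#' @return data frame of class \code{discform_prepped} with columns
#'   \code{token_id}, \code{speaker}, \code{normalized_time}, \code{f1_z},
#'   \code{f2_z}.
#' @export
normalize_tracks <- function(tracks) {
  neg_f1 <- -tracks$F1_Hz
  f2 <- tracks$F2_Hz
  f1_z <- f2_z <- numeric(nrow(tracks))
  for (sp in unique(tracks$speaker)) {
    i <- tracks$speaker == sp
    if (sum(i) < 2)
      stopf("data error: speaker '%s' has fewer than 2 samples", sp)
    s1 <- stats::sd(neg_f1[i]); s2 <- stats::sd(f2[i])
    if (s1 == 0 || s2 == 0)
      stopf("data error: zero within-speaker variance for speaker '%s'", sp)
    f1_z[i] <- (neg_f1[i] - mean(neg_f1[i])) / s1
    f2_z[i] <- (f2[i] - mean(f2[i])) / s2
  }
  nt <- stats::ave(tracks$t_s, tracks$token_id, FUN = function(t) {
    if (length(t) == 1 || max(t) == min(t)) return(rep(0, length(t)))
    (t - min(t)) / (max(t) - min(t))
  })
  out <- data.frame(token_id = tracks$token_id, speaker = tracks$speaker,
                    normalized_time = nt, f1_z = f1_z, f2_z = f2_z,
                    stringsAsFactors = FALSE)
  class(out) <- c("discform_prepped", "data.frame")
  out
}

#' Assemble the long modeling table
#'
#' One row per (token, time sample, formant dimension) with the factorial
#' predictor \code{dimension} (F1/F2), the six-level dimension-by-class
#' factor \code{dbc}, log vowel duration, speaker, the requested activation
#' column(s), and the z-scored response.
#'
#' @param prepped output of \code{\link{normalize_tracks}}.
#' @param activations data frame(s) from
#'   \code{\link{activations_for_corpus}}; a single data frame or a named
#'   list of them (names become column suffixes).
#' @param corpus the \code{discform_corpus} the tokens come from.
#' @return data frame of class \code{discform_model_table}.
#' @export
assemble_model_table <- function(prepped, activations, corpus) {
  if (inherits(activations, "data.frame"))
    activations <- list(activation = activations)
  tok <- unique(prepped$token_id)
  meta <- corpus[match(tok, corpus$token_id), , drop = FALSE]
  acts <- lapply(activations, function(a) {
    v <- a$activation[match(tok, a$token_id)]
    if (any(is.na(v)))
      stopf("join error: missing activation for token(s) %s",
            paste(utils::head(tok[is.na(v)], 5), collapse = ", "))
    v
  })
  base <- prepped
  i <- match(base$token_id, tok)
  rows <- function(dim_label, resp) {
    df <- data.frame(token_id = base$token_id,
                     time = base$normalized_time,
                     dimension = dim_label,
                     word_class = meta$word_class[i],
                     dbc = paste(dim_label, meta$word_class[i], sep = "."),
                     log_duration = log(meta$vowel_duration_s[i]),
                     speaker = base$speaker,
                     response = resp,
                     stringsAsFactors = FALSE)
    for (nm in names(acts)) df[[nm]] <- acts[[nm]][i]
    df
  }
  out <- rbind(rows("F1", base$f1_z), rows("F2", base$f2_z))
  out$dimension <- factor(out$dimension, levels = c("F1", "F2"))
  out$dbc <- factor(out$dbc)
  out$speaker <- factor(out$speaker)
  rownames(out) <- NULL
  class(out) <- c("discform_model_table", "data.frame")
  out
}

#' Token-level slice of the model table inputs
#'
#' One row per token with log duration, speaking rate, segment count,
#' speaker, word form and the activation columns — the input to the duration
#' analysis.
#'
#' @inheritParams assemble_model_table
#' @return a data frame, one row per schwa token present in \code{prepped}.
#' @export
token_table <- function(prepped, activations, corpus) {
  if (inherits(activations, "data.frame"))
    activations <- list(activation = activations)
  tok <- unique(prepped$token_id)
  meta <- corpus[match(tok, corpus$token_id), , drop = FALSE]
  df <- data.frame(token_id = tok,
                   speaker = meta$speaker,
                   word = meta$form,
                   word_class = meta$word_class,
                   log_duration = log(meta$vowel_duration_s),
                   speaking_rate = meta$speaking_rate,
                   n_segments = meta$n_segments,
                   stringsAsFactors = FALSE)
  for (nm in names(activations)) {
    v <- activations[[nm]]$activation[match(tok, activations[[nm]]$token_id)]
    if (any(is.na(v)))
      stopf("join error: missing activation for token(s) %s",
            paste(utils::head(tok[is.na(v)], 5), collapse = ", "))
    df[[nm]] <- v
  }
  df
}
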