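#' Specify a discriminative network structure
#'
#' Two contrasting input-output structures are supported. In the
#' \emph{functional output} structure, window word forms and diphones are cues
#' and the target's inflectional functions are outcomes (a placeholder outcome
#' ensures cue competition for targets without functions). In the
#' \emph{functional input} structure, the target's inflectional functions join
#' the word and diphone cues, and the outcomes are the target's word form plus
#' a gestural placeholder \code{g:ER} whenever the target is schwa-final.
#'
#' @param structure \code{"functional_output"} or \code{"functional_input"}.
#' @param include_function_cues ablation switch (functional_input only): when
#'   \code{FALSE}, inflectional-function cues are omitted.
#' @param window_size odd sliding-window size in words (default 5).
#' @param boundary_symbol phone symbol marking window edges (default
#'   \code{"#"}).
#' @return an object of class \code{network_spec}.
#' @export
network_spec <- function(structure = c("functional_output", "functional_input"),
                         include_function_cues = TRUE, window_size = 5,
                         boundary_symbol = "#") {
  structure <- match.arg(structure)
  window_size <- check_count(window_size, "window_size")
  if (window_size %% 2 == 0)
    stopf("configuration error: 'window_size' must be odd")
  if (!is.character(boundary_symbol) || nchar(boundary_symbol) != 1)
    stopf("configuration error: 'boundary_symbol' must be a single character")
  out <- list(structure = structure,
              include_function_cues = isTRUE(include_function_cues),
              window_size = as.integer(window_size),
              boundary_symbol = boundary_symbol)
  class(out) <- "network_spec"
  out
}

#' Extract diphone cues from a window of phone sequences
#'
#' Phone sequences of the window words are concatenated across word
#' boundaries, one boundary symbol is prepended and appended to the whole
#' window string, and every adjacent symbol pair is returned in order.
#' A window of total phone length L therefore yields exactly L + 1 diphones
#' (duplicates preserved; deduplication happens when diphones enter a cue
#' set).
#'
#' @param phone_sequences list of character vectors, one per word, in window
#'   order.
#' @param boundary_symbol boundary marker (default \code{"#"}).
#' @return character vector of two-symbol diphone strings.
#' @export
extract_diphones <- function(phone_sequences, boundary_symbol = "#") {
  symbols <- unlist(phone_sequences, use.names = FALSE)
  if (length(symbols) == 0)
    stopf("domain error: empty phone concatenation")
  symbols <- c(boundary_symbol, symbols, boundary_symbol)
  paste0(symbols[-length(symbols)], symbols[-1])
}

.split_phones <- function(x) strsplit(x, " ", fixed = TRUE)

.split_functions <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(f) f[nzchar(f)])
}

#' Build one learning event from a centered window
#'
#' The target (center) word form never serves as a cue in either structure;
#' diphones are drawn from all window words including the target. All word
#' cues are case-folded to lower case.
#'
#' @param window a slice of a \code{discform_corpus} (rows in window order).
#' @param spec a \code{\link{network_spec}}.
#' @param center index of the target word within \code{window}.
#' @return a list with elements \code{cues}, \code{outcomes} (character sets,
#'   lexicographically sorted) and \code{center_token_id}.
#' @export
build_event <- function(window, spec, center = (nrow(window) + 1L) %/% 2L) {
  n <- nrow(window)
  if (n == 0 || is.na(center) || center < 1 || center > n)
    stopf("domain error: window without a valid center")
  forms <- tolower(window$form)
  phones <- .split_phones(window$phones)
  diphones <- unique(extract_diphones(phones, spec$boundary_symbol))
  word_cues <- unique(forms[-center])
  funs <- .split_functions(window$functions[center])[[1]]
  schwa <- isTRUE(window$schwa_final[center])

  if (spec$structure == "functional_output") {
    cues <- c(paste0("w:", word_cues), paste0("d:", diphones))
    outcomes <- if (length(funs) > 0) paste0("fn:", funs) else "ph:NoFunction"
  } else {
    cues <- c(paste0("w:", word_cues), paste0("d:", diphones))
    if (spec$include_function_cues && schwa && length(funs) > 0)
      cues <- c(cues, paste0("f:", funs))
    outcomes <- paste0("o:", forms[center])
    if (schwa) outcomes <- c(outcomes, "g:ER")
  }
  list(cues = sort(unique(cues), method = "radix"),
       outcomes = sort(unique(outcomes), method = "radix"),
       center_token_id = window$token_id[center])
}

#' Stream learning events over a corpus
#'
#' Slides a window of \code{spec$window_size} words over each utterance (one
#' event per token, in corpus order). Windows never cross utterance
#' boundaries and are truncated near utterance edges; truncated windows still
#' receive a single boundary symbol at each edge.
#'
#' @param corpus a \code{discform_corpus}, ordered by utterance and position.
#' @param spec a \code{\link{network_spec}}.
#' @return a list of events of class \code{discform_events}.
#' @export
stream_events <- function(corpus, spec) {
  h <- (spec$window_size - 1L) %/% 2L
  idx_by_utt <- split(seq_len(nrow(corpus)), corpus$utterance_id)
  # preserve corpus order of utterances
  idx_by_utt <- idx_by_utt[unique(corpus$utterance_id)]
  events <- vector("list", nrow(corpus))
  k <- 0L
  for (rows in idx_by_utt) {
    L <- length(rows)
    slice <- corpus[rows, , drop = FALSE]
    for (i in seq_len(L)) {
      lo <- max(1L, i - h); hi <- min(L, i + h)
      k <- k + 1L
      events[[k]] <- build_event(slice[lo:hi, , drop = FALSE], spec,
                                 center = i - lo + 1L)
    }
  }
  class(events) <- "discform_events"
  events
}

#' @rdname events_io
#' @param events a \code{discform_events} list.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- data.frame(
    center_token_id = vapply(events, `[[`, "", "center_token_id"),
    cues = vapply(events, function(e) paste(e$cues, collapse = " "), ""),
    outcomes = vapply(events, function(e) paste(e$outcomes, collapse = " "), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Event serialization
#'
#' Events round-trip losslessly through a TSV with space-joined cue and
#' outcome label lists.
#'
#' @name events_io
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  events <- lapply(seq_len(nrow(df)), function(i) {
    list(cues = strsplit(df$cues[i], " ", fixed = TRUE)[[1]],
         outcomes = strsplit(df$outcomes[i], " ", fixed = TRUE)[[1]],
         center_token_id = df$center_token_id[i])
  })
  class(events) <- "discform_events"
  events
}
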