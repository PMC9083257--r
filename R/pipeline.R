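# End-to-end experiment: simulate -> events -> train both networks ->
# activations -> filter/normalize -> model ladder -> duration model ->
# network comparison.

#' Configuration for a full synthetic experiment
#'
#' Bundles the sub-configurations of every stage. The master \code{seed}
#' drives all randomness: the language config's seed is replaced by it and
#' every stage derives its own stream deterministically, so a bundle is
#' byte-reproducible from config alone.
#'
#' @param language a \code{\link{language_config}}.
#' @param truth a \code{\link{formant_ground_truth}}; when its speaker
#'   offsets are NULL they are drawn (sd 30 Hz) from a derived seed.
#' @param learning a \code{\link{learning_params}}.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @param window_size sliding-window size in words.
#' @param rho fixed AR1 coefficient for the trajectory models.
#' @param ladder_models which of m1--m4 the input and output ladders fit.
#' @param ablation also train the functional input network without
#'   inflectional-function cues (default TRUE).
#' @param ablation_models ladder models fitted for the ablation network
#'   (default \code{"m2"}).
#' @param fit_control optimizer control for \code{\link{fit_model}}.
#' @param out_dir optional directory for artifact files (corpus, tracks,
#'   weights, activations, reports, manifest); NULL keeps everything in
#'   memory.
#' @param seed master seed.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(language = language_config(),
                              truth = formant_ground_truth(),
                              learning = learning_params(),
                              thresholds = filter_thresholds(),
                              window_size = 5, rho = 0.8,
                              ladder_models = c("m1", "m2", "m3", "m4"),
                              ablation = TRUE, ablation_models = "m2",
                              fit_control = list(), out_dir = NULL,
                              seed = 1L) {
  if (length(seed) != 1 || !is.finite(seed))
    stopf("configuration error: master 'seed' must be a single integer")
  language$seed <- as.integer(seed)
  out <- list(language = language, truth = truth, learning = learning,
              thresholds = thresholds, window_size = window_size, rho = rho,
              ladder_models = ladder_models, ablation = isTRUE(ablation),
              ablation_models = ablation_models, fit_control = fit_control,
              out_dir = out_dir, seed = as.integer(seed))
  class(out) <- "experiment_config"
  out
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.stage_log <- function(log, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  c(log, list(entry))
}

#' Run the full experiment
#'
#' Simulates a corpus and formant tracks, trains the functional output and
#' functional input networks (plus the no-function-cue ablation when
#' requested), computes per-token activations, filters and normalizes the
#' tracks, fits the model ladder for each activation measure (the baseline
#' m0 is shared), fits the duration mixed model and rank correlations, and
#' assembles a network comparison. All artifacts are reproducible from
#' config + seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return a report bundle (list) with elements \code{corpus},
#'   \code{tracks}, \code{latent}, \code{weights}, \code{activations},
#'   \code{filter_report}, \code{model_table}, \code{tokens},
#'   \code{ladders}, \code{duration}, \code{correlations},
#'   \code{comparison}, \code{log}, \code{config}.
#' @export
run_experiment <- function(config) {
  log <- list()
  stage <- "simulate"
  bundle <- tryCatch({
    lex <- build_lexicon(config$language)
    corpus <- sample_corpus(lex, config$language)
    truth <- config$truth
    if (is.null(truth$speaker_offsets)) {
      spk <- sort(unique(corpus$speaker))
      truth$speaker_offsets <- with_seed(
        derive_seed(config$seed, 7L),
        stats::setNames(stats::rnorm(length(spk), 0, 30), spk))
    }
    schwa <- corpus[corpus$schwa_final, , drop = FALSE]
    tracks <- generate_formant_tracks(schwa, truth, config$language)
    log <- .stage_log(log, "simulate", n_tokens = nrow(corpus),
                      n_schwa = nrow(schwa), n_samples = nrow(tracks))

    stage <- "events_train"
    spec_out <- network_spec("functional_output",
                             window_size = config$window_size)
    spec_in <- network_spec("functional_input",
                            window_size = config$window_size)
    nets <- list(functional_output = spec_out, functional_input = spec_in)
    if (config$ablation)
      nets$ablation <- network_spec("functional_input",
                                    include_function_cues = FALSE,
                                    window_size = config$window_size)
    weights <- lapply(nets, function(sp)
      rw_train(stream_events(corpus, sp), config$learning))
    activations <- mapply(function(w, sp)
      activations_for_corpus(w, corpus, sp),
      weights, nets, SIMPLIFY = FALSE)
    log <- .stage_log(log, "events_train", networks = names(nets))

    stage <- "prep"
    filt <- filter_tracks(tracks, schwa, config$thresholds)
    prepped <- normalize_tracks(filt$tracks)
    tab <- assemble_model_table(prepped, activations, corpus)
    toks <- token_table(prepped, activations, corpus)
    log <- .stage_log(log, "prep", tokens_kept = filt$report$tokens_kept)

    stage <- "ladder"
    ladders <- list()
    ladders$functional_input <- ml_ladder(
      tab, "functional_input", models = config$ladder_models,
      rho = config$rho, control = config$fit_control)
    m0 <- ladders$functional_input$fits$m0
    ladders$functional_output <- ml_ladder(
      tab, "functional_output", models = config$ladder_models,
      rho = config$rho, m0_fit = m0, control = config$fit_control)
    if (config$ablation)
      ladders$ablation <- ml_ladder(
        tab, "ablation", models = config$ablation_models,
        rho = config$rho, m0_fit = m0, control = config$fit_control)
    log <- .stage_log(log, "ladder", networks = names(ladders))

    stage <- "duration"
    duration <- list(
      functional_input = duration_model(toks, "functional_input"),
      functional_output = duration_model(toks, "functional_output"))
    correlations <- list(
      functional_input = rank_correlation(toks$functional_input,
                                          exp(toks$log_duration)),
      functional_output = rank_correlation(toks$functional_output,
                                           exp(toks$log_duration)))
    log <- .stage_log(log, "duration", n_tokens = nrow(toks))

    list(corpus = corpus, tracks = tracks,
         latent = attr(tracks, "latent"), truth = truth,
         weights = weights, activations = activations,
         filter_report = filt$report, model_table = tab, tokens = toks,
         ladders = ladders, duration = duration,
         correlations = correlations, log = log, config = config)
  }, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
  bundle$comparison <- compare_networks(bundle)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

#' Compare the network ladders of a report bundle
#'
#' One row per (model, network) with the ML improvement over the shared
#' baseline m0 and the effective-degrees-of-freedom change — the tabular
#' analog of plotting ML-score differences per model for both activation
#' types (plus the ablation when it ran).
#'
#' @param bundle a \code{\link{run_experiment}} result (or any list with a
#'   \code{ladders} element).
#' @return data frame with columns \code{model}, \code{network},
#'   \code{delta_ml}, \code{delta_edf}.
#' @export
compare_networks <- function(bundle) {
  if (is.null(bundle$ladders) || length(bundle$ladders) == 0)
    stopf("missing ladder: run the ladder stage first")
  rows <- list()
  for (net in names(bundle$ladders)) {
    rep <- bundle$ladders[[net]]$report
    rep <- rep[rep$model != "m0", , drop = FALSE]
    rows[[net]] <- data.frame(model = rep$model, network = net,
                              delta_ml = rep$delta_ml,
                              delta_edf = rep$delta_edf,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Write the bundle's artifact files plus an md5 manifest and a JSON-lines
# stage log.
.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_corpus(bundle$corpus, fp("corpus.tsv"))
  write_tracks(bundle$tracks, fp("tracks.csv"))
  write_ground_truth(bundle$truth, fp("ground_truth.json"))
  for (net in names(bundle$weights))
    write_weights(bundle$weights[[net]], fp(sprintf("weights_%s.tsv", net)))
  acts <- do.call(rbind, bundle$activations)
  utils::write.csv(acts, fp("activations.csv"), row.names = FALSE)
  .write_json(bundle$filter_report, fp("filter_report.json"))
  utils::write.csv(bundle$model_table, fp("model_table.csv"),
                   row.names = FALSE)
  ladder_report <- lapply(bundle$ladders, function(l) l$report)
  .write_json(ladder_report, fp("ladder_report.json"))
  utils::write.csv(bundle$comparison, fp("comparison.csv"),
                   row.names = FALSE)
  dur <- lapply(bundle$duration, function(d)
    list(coefficients = d$coefficients, varcomp = as.list(d$varcomp)))
  .write_json(dur, fp("duration_fits.json"))
  con <- file(fp("stages.jsonl"), "w")
  for (entry in bundle$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  close(con)
  files <- setdiff(list.files(dir, full.names = TRUE),
                   fp("MANIFEST.json"))
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(names(manifest))
  .write_json(manifest, fp("MANIFEST.json"))
  invisible(dir)
}
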