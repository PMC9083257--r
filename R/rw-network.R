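#' Rescorla-Wagner learning parameters
#'
#' The delta rule updates the weight from every present cue to every outcome:
#' for present outcomes the target is \code{lambda_max}, for absent outcomes
#' it is 0, and the change is the learning rate times (target - V), where V is
#' the summed weight from the present cues computed before the update.
#'
#' @param lambda_max asymptote of learning (default 1).
#' @param eta_present learning rate alpha*beta1 for outcomes present in the
#'   event (default 0.01).
#' @param eta_absent learning rate alpha*beta2 for absent outcomes (default
#'   0.01).
#' @param outcome_universe \code{"declared"} (every outcome label registered
#'   in the full event stream) or \code{"seen_so_far"}. With zero-initialized
#'   weights the two produce identical weights — an outcome never yet seen has
#'   V = 0 and target 0, hence a zero update — so the flag is informational.
#' @return an object of class \code{learning_params}.
#' @export
learning_params <- function(lambda_max = 1, eta_present = 0.01,
                            eta_absent = 0.01,
                            outcome_universe = c("declared", "seen_so_far")) {
  if (!is.finite(lambda_max) || lambda_max <= 0)
    stopf("configuration error: 'lambda_max' must be > 0")
  for (nm in c("eta_present", "eta_absent")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v > 1)
      stopf("configuration error: '%s' must lie in (0, 1]", nm)
  }
  out <- list(lambda_max = lambda_max, eta_present = eta_present,
              eta_absent = eta_absent,
              outcome_universe = match.arg(outcome_universe))
  class(out) <- "learning_params"
  out
}

.empty_weights <- function(cues, outcomes, params) {
  w <- matrix(0, length(cues), length(outcomes),
              dimnames = list(cues, outcomes))
  attr(w, "params") <- params
  class(w) <- c("weight_matrix", "matrix", "array")
  w
}

.event_registries <- function(events) {
  all_of <- function(field)
    sort(unique(c(character(0),
                  unlist(lapply(events, `[[`, field), use.names = FALSE))),
         method = "radix")
  list(cues = all_of("cues"), outcomes = all_of("outcomes"))
}

#' Apply one delta-rule update
#'
#' Updates \code{weights} in response to a single event. Weights for absent
#' cues are unchanged; labels not yet in the registries are added with zero
#' weights. Summation of V(o) over present cues runs in lexicographic cue
#' order, making results bit-reproducible.
#'
#' @param weights a \code{weight_matrix} (cue x outcome), or \code{NULL} to
#'   start from an empty matrix.
#' @param event a list with \code{cues} and \code{outcomes} character vectors.
#' @param params a \code{\link{learning_params}}.
#' @return the updated \code{weight_matrix}.
#' @export
apply_update <- function(weights, event, params = learning_params()) {
  if (length(event$cues) == 0 || length(event$outcomes) == 0)
    stopf("domain error: event cues and outcomes must be nonempty")
  if (is.null(weights))
    weights <- .empty_weights(character(0), character(0), params)
  new_cues <- setdiff(event$cues, rownames(weights))
  new_out <- setdiff(event$outcomes, colnames(weights))
  if (length(new_cues) || length(new_out)) {
    cues <- sort(c(rownames(weights), new_cues), method = "radix")
    outs <- sort(c(colnames(weights), new_out), method = "radix")
    w2 <- .empty_weights(cues, outs, params)
    if (nrow(weights) && ncol(weights))
      w2[rownames(weights), colnames(weights)] <- weights
    weights <- w2
  }
  ci <- sort(match(event$cues, rownames(weights)))
  oi <- match(event$outcomes, colnames(weights))
  V <- colSums(weights[ci, , drop = FALSE])
  target <- numeric(ncol(weights))
  target[oi] <- params$lambda_max
  rate <- rep(params$eta_absent, ncol(weights))
  rate[oi] <- params$eta_present
  delta <- rate * (target - V)
  if (any(!is.finite(delta)))
    stopf("numeric error: non-finite weight update")
  weights[ci, ] <- weights[ci, , drop = FALSE] +
    rep(delta, each = length(ci))
  weights
}

#' Train a two-layer network with the delta rule
#'
#' A single pass over the events in stream order (the corpus schedule), fully
#' deterministic: the cue and outcome registries are pre-scanned from the
#' whole stream and sorted lexicographically, and all sums run in that fixed
#' order. Additional passes (for equilibrium studies) re-iterate the same
#' stream.
#'
#' @param events a \code{discform_events} list (or any list of cue/outcome
#'   events).
#' @param params a \code{\link{learning_params}}.
#' @param passes number of passes over the stream (default 1).
#' @return a \code{weight_matrix} over all labels encountered.
#' @export
rw_train <- function(events, params = learning_params(), passes = 1L) {
  reg <- .event_registries(events)
  w <- .empty_weights(reg$cues, reg$outcomes, params)
  if (length(events) == 0) return(w)
  ci_list <- lapply(events, function(e) sort(match(e$cues, reg$cues)))
  oi_list <- lapply(events, function(e) match(e$outcomes, reg$outcomes))
  K <- length(reg$outcomes)
  lambda <- params$lambda_max
  ep <- params$eta_present
  ea <- params$eta_absent
  wm <- unclass(w)
  for (p in seq_len(passes)) {
    for (e in seq_along(events)) {
      ci <- ci_list[[e]]
      oi <- oi_list[[e]]
      V <- colSums(wm[ci, , drop = FALSE])
      target <- numeric(K)
      target[oi] <- lambda
      rate <- rep(ea, K)
      rate[oi] <- ep
      delta <- rate * (target - V)
      if (any(!is.finite(delta)))
        stopf("numeric error: non-finite weights at event %d (pass %d)", e, p)
      wm[ci, ] <- wm[ci, , drop = FALSE] + rep(delta, each = length(ci))
    }
  }
  attr(wm, "params") <- params
  class(wm) <- c("weight_matrix", "matrix", "array")
  wm
}

#' Summed activation from a cue set to an outcome set
#'
#' Returns the sum of weights over all (cue, outcome) pairs; labels absent
#' from the weight matrix read as zero. For the functional output network the
#' outcome set is the target's inflectional functions; for the functional
#' input network it is the gestural placeholder \code{g:ER} alone.
#'
#' @param weights a \code{weight_matrix}.
#' @param cue_set,outcome_set character label vectors.
#' @param aggregate \code{"sum"} (default) or \code{"mean"} across the
#'   outcome set (sensitivity variant).
#' @return a single finite number.
#' @export
total_activation <- function(weights, cue_set, outcome_set,
                             aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  ci <- sort(match(sort(unique(cue_set), method = "radix"),
                   rownames(weights)))
  oi <- sort(match(sort(unique(outcome_set), method = "radix"),
                   colnames(weights)))
  ci <- ci[!is.na(ci)]
  oi <- oi[!is.na(oi)]
  if (length(ci) == 0 || length(oi) == 0) return(0)
  per_outcome <- colSums(weights[ci, oi, drop = FALSE])
  if (aggregate == "mean") mean(per_outcome) else sum(per_outcome)
}

#' Activations for every schwa token of a corpus
#'
#' Rebuilds each schwa token's sliding-window cue set and sums the trained
#' weights to the structure-appropriate outcome set.
#'
#' @param weights a \code{weight_matrix} trained under \code{spec}.
#' @param corpus a \code{discform_corpus}.
#' @param spec the \code{\link{network_spec}} used for training.
#' @param aggregate passed to \code{\link{total_activation}} (functional
#'   output only; the functional input outcome set is a single label).
#' @return data frame with columns \code{token_id}, \code{network},
#'   \code{activation}, one row per schwa-final token.
#' @export
activations_for_corpus <- function(weights, corpus, spec,
                                   aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  events <- stream_events(corpus, spec)
  schwa <- which(corpus$schwa_final)
  funs <- .split_functions(corpus$functions)
  act <- vapply(schwa, function(i) {
    e <- events[[i]]
    outcome_set <- if (spec$structure == "functional_output") {
      if (length(funs[[i]]) > 0) paste0("fn:", funs[[i]]) else "ph:NoFunction"
    } else "g:ER"
    total_activation(weights, e$cues, outcome_set, aggregate = aggregate)
  }, numeric(1))
  data.frame(token_id = corpus$token_id[schwa],
             network = spec$structure,
             activation = act,
             stringsAsFactors = FALSE)
}

#' Analytic equilibrium of the delta rule (Danks fixed point)
#'
#' Solves, per outcome, the least-squares normal equations C w = lambda b,
#' where C is the cue co-occurrence frequency matrix over the event multiset
#' and b the cue-with-outcome frequency vector, using the Moore-Penrose
#' pseudo-inverse when C is singular. This is the expected fixed point of the
#' update when \code{eta_present == eta_absent}, and serves as an independent
#' oracle for the iterative learner.
#'
#' @param events list of cue/outcome events (a multiset; order irrelevant).
#' @param params a \code{\link{learning_params}} (supplies lambda).
#' @return a \code{weight_matrix} of equilibrium weights.
#' @export
danks_equilibrium <- function(events, params = learning_params()) {
  reg <- .event_registries(events)
  n_c <- length(reg$cues)
  n_o <- length(reg$outcomes)
  C <- matrix(0, n_c, n_c)
  B <- matrix(0, n_c, n_o)
  for (e in events) {
    ci <- match(e$cues, reg$cues)
    oi <- match(e$outcomes, reg$outcomes)
    C[ci, ci] <- C[ci, ci] + 1
    B[ci, oi] <- B[ci, oi] + 1
  }
  N <- length(events)
  W <- params$lambda_max * (MASS::ginv(C / N) %*% (B / N))
  dimnames(W) <- list(reg$cues, reg$outcomes)
  attr(W, "params") <- params
  class(W) <- c("weight_matrix", "matrix", "array")
  W
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d cues x %d outcomes, %d nonzero\n",
              nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

#' @rdname weights_io
#' @param weights a \code{weight_matrix}.
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  params <- attr(weights, "params")
  header <- jsonlite::toJSON(list(params = unclass(params),
                                  cues = rownames(weights),
                                  outcomes = colnames(weights)),
                             auto_unbox = TRUE, digits = NA)
  nz <- which(weights != 0, arr.ind = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  writeLines("cue\toutcome\tweight", con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%s\t%s\t%.17g",
                       rownames(weights)[nz[, 1]],
                       colnames(weights)[nz[, 2]],
                       weights[nz]), con)
  }
  invisible(path)
}

#' Weight-matrix serialization
#'
#' Sparse triplet TSV (cue, outcome, weight at full precision) with a JSON
#' header line carrying the learning parameters and the complete label
#' registries; the round-trip is lossless including all-zero rows/columns.
#'
#' @name weights_io
#' @export
read_weights <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  params <- structure(header$params, class = "learning_params")
  w <- .empty_weights(as.character(header$cues),
                      as.character(header$outcomes), params)
  if (length(lines) > 2) {
    trip <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
    w[cbind(match(trip$cue, rownames(w)),
            match(trip$outcome, colnames(w)))] <- trip$weight
  }
  w
}
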