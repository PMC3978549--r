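# The personal-story classifier that gates posts into the searchable
# index. Two modes behind one contract: a calibrated noise model pinned to
# a stated precision/recall operating point (the default, reproducing the
# upstream system's behaviour), and a trainable bag-of-words baseline.

#' Calibrated story-filter noise model
#'
#' Emulates a story classifier with a fixed operating point (default
#' precision 0.66, recall 0.5): selects `TP = round(recall * n_stories)`
#' true stories uniformly at random, plus
#' `FP = round(TP * (1 - precision) / precision)` non-story posts
#' uniformly at random. Deriving the false-positive count from precision
#' and TP (rather than flipping per post) makes the calibration exact at
#' any corpus size, up to integer rounding.
#'
#' @param corpus Corpus with gold story labels (see [is_story()]).
#' @param precision_target,recall_target Target operating point.
#' @param seed Optional integer seed for the random selections.
#' @return Character vector of flagged post ids.
#' @export
noise_filter <- function(corpus, precision_target = 0.66,
                         recall_target = 0.5, seed = NULL) {
  stopifnot(precision_target > 0, precision_target <= 1,
            recall_target >= 0, recall_target <= 1)
  story_ids <- corpus$id[is_story(corpus)]
  other_ids <- setdiff(corpus$id, story_ids)
  tp <- round(recall_target * length(story_ids))
  fp <- round(tp * (1 - precision_target) / precision_target)
  if (fp > length(other_ids)) {
    stop(sprintf(
      "non-story pool too small for requested precision: need %d false positives, have %d posts",
      fp, length(other_ids)), call. = FALSE)
  }
  pick <- function() {
    flagged_tp <- story_ids[sample.int(length(story_ids), tp)]
    flagged_fp <- if (fp > 0) other_ids[sample.int(length(other_ids), fp)] else character()
    sort(c(flagged_tp, flagged_fp))
  }
  if (is.null(seed)) pick() else with_seed(seed, pick())
}

#' Precision and recall of a flagged set
#'
#' Exact confusion counts of a flagged id set against the gold story id
#' set: `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)` (each
#' `NA` when its denominator is zero).
#'
#' @param flagged_ids,gold_ids Character id vectors from one corpus.
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
evaluate_filter <- function(flagged_ids, gold_ids) {
  tp <- length(intersect(flagged_ids, gold_ids))
  fp <- length(setdiff(flagged_ids, gold_ids))
  fn <- length(setdiff(gold_ids, flagged_ids))
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}

#' Train a bag-of-words story classifier
#'
#' A multinomial naive Bayes model over [tokenize()]d text with Laplace
#' smoothing -- a linear classifier in log space, provided as a
#' trainable baseline alongside the calibrated [noise_filter()]. The fit
#' is deterministic given the training data.
#'
#' @param texts Character vector of training posts.
#' @param labels Character vector in `{"story", "nonstory"}`.
#' @return A `story_classifier` model (vocabulary, class log priors,
#'   per-class log conditional probabilities).
#' @export
train_story_classifier <- function(texts, labels) {
  stopifnot(length(texts) == length(labels),
            all(labels %in% c("story", "nonstory")))
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  tokens <- lapply(texts, tokenize)
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  count_class <- function(cls) {
    tk <- unlist(tokens[labels == cls], use.names = FALSE)
    tab <- table(factor(tk, levels = vocab))
    as.numeric(tab)
  }
  n_story <- count_class("story")
  n_non <- count_class("nonstory")
  model <- list(
    version = 1L,
    vocab = vocab,
    log_prior = c(story = log(mean(labels == "story")),
                  nonstory = log(mean(labels == "nonstory"))),
    log_cond = cbind(
      story = log((n_story + 1) / (sum(n_story) + length(vocab))),
      nonstory = log((n_non + 1) / (sum(n_non) + length(vocab)))
    )
  )
  rownames(model$log_cond) <- vocab
  structure(model, class = "story_classifier")
}

#' Classify a post as story or non-story
#'
#' Posterior probability of the story class under the trained model;
#' decision threshold 0.5. Text with no in-vocabulary tokens (including
#' empty text) is classified `"nonstory"` by documented default.
#'
#' @param model A [train_story_classifier()] model.
#' @param text A single post text.
#' @return `"story"` or `"nonstory"`.
#' @export
classify_story <- function(model, text) {
  tk <- tokenize(text)
  tk <- tk[tk %in% model$vocab]
  if (length(tk) == 0L) return("nonstory")
  tab <- table(tk)
  counts <- as.numeric(tab)
  ll <- model$log_prior +
    c(sum(counts * model$log_cond[names(tab), "story"]),
      sum(counts * model$log_cond[names(tab), "nonstory"]))
  p_story <- 1 / (1 + exp(ll[["nonstory"]] - ll[["story"]]))
  if (p_story > 0.5) "story" else "nonstory"
}

#' Serialize a story classifier
#'
#' Models are stored as a versioned JSON file holding the vocabulary and
#' weights; flagged id sets as plain text, one id per line.
#'
#' @param model A [train_story_classifier()] model.
#' @param path File path.
#' @return `read_classifier()` returns the model; writers return `path`
#'   invisibly.
#' @export
write_classifier <- function(model, path) {
  obj <- list(version = model$version, vocab = model$vocab,
              log_prior = as.list(model$log_prior),
              log_cond_story = unname(model$log_cond[, "story"]),
              log_cond_nonstory = unname(model$log_cond[, "nonstory"]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    version = obj$version,
    vocab = obj$vocab,
    log_prior = unlist(obj$log_prior),
    log_cond = cbind(story = obj$log_cond_story,
                     nonstory = obj$log_cond_nonstory)
  )
  rownames(model$log_cond) <- model$vocab
  structure(model, class = "story_classifier")
}

#' @rdname write_classifier
#' @param ids Character vector of flagged post ids.
#' @export
write_flagged_ids <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_flagged_ids <- function(path) {
  readLines(path, warn = FALSE)
}
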