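# Vector-space retrieval: bespoke inverted index with tf-idf weighting,
# cosine ranking, and Rocchio relevance feedback. Sparse vectors are named
# numeric vectors (term -> weight) with no zero entries stored.

#' Tokenize free text
#'
#' Lowercases, splits on non-alphanumeric characters, and keeps tokens of
#' length at least 2; all-digit tokens must have length at least 3, so
#' "911" survives while stray two-digit numbers do not. No stemming, no
#' stopword removal.
#'
#' @param text A single string.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("I felt confused!")  # "I" is dropped by the length rule
#' tokenize("called 911.")
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  digit <- grepl("^[0-9]+$", toks)
  toks[(digit & nchar(toks) >= 3L) | (!digit & nchar(toks) >= 2L)]
}

# ---- sparse vector helpers ----------------------------------------------

sv_norm <- function(v) sqrt(sum(v^2))

sv_normalize <- function(v) {
  n <- sv_norm(v)
  if (n > 0) v / n else v
}

sv_drop_zero <- function(v) v[v != 0]

# sum of sparse vectors given as a list
sv_sum <- function(vs) {
  if (length(vs) == 0L) return(stats::setNames(numeric(0), character(0)))
  all_terms <- unique(unlist(lapply(vs, names), use.names = FALSE))
  out <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (v in vs) out[names(v)] <- out[names(v)] + v
  out
}

sv_dot <- function(a, b) {
  shared <- intersect(names(a), names(b))
  sum(a[shared] * b[shared])
}

#' Build a tf-idf index over a corpus
#'
#' Indexes every post as an L2-normalised tf-idf vector with weights
#' `w = (1 + ln tf) * ln(N / df)`. Terms occurring in every document get
#' idf 0 and are dropped. An inverted posting list supports fast cosine
#' scoring.
#'
#' @param posts Data frame with columns `id` (unique) and `text`.
#' @return A `story_index` object: `N`, `df` (per-term document
#'   frequency), `vectors` (per-document sparse vectors), `postings`
#'   (term -> named weight vector over documents).
#' @export
build_index <- function(posts) {
  if (anyDuplicated(posts$id)) {
    stop("duplicate post ids: ",
         paste(unique(posts$id[duplicated(posts$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(posts) == 0L) {
    return(structure(list(N = 0L,
                          df = stats::setNames(integer(0), character(0)),
                          vectors = list(), postings = list()),
                     class = "story_index"))
  }
  tokens <- lapply(posts$text, tokenize)
  tfs <- lapply(tokens, function(tk) {
    if (length(tk) == 0L) return(stats::setNames(integer(0), character(0)))
    tab <- table(tk)
    stats::setNames(as.integer(tab), names(tab))
  })
  N <- nrow(posts)
  df <- table(unlist(lapply(tfs, names), use.names = FALSE))
  df <- stats::setNames(as.integer(df), names(df))
  idf <- log(N / df)
  vectors <- lapply(tfs, function(tf) {
    w <- (1 + log(tf)) * idf[names(tf)]
    sv_normalize(sv_drop_zero(w))
  })
  names(vectors) <- posts$id
  # inverted postings: term -> (doc id -> weight)
  term_of <- unlist(lapply(vectors, names), use.names = FALSE)
  doc_of <- rep(posts$id, lengths(vectors))
  wt_of <- unlist(vectors, use.names = FALSE)
  postings <- split(stats::setNames(wt_of, doc_of), term_of)
  structure(list(N = N, df = df, vectors = vectors, postings = postings),
            class = "story_index")
}

#' @export
print.story_index <- function(x, ...) {
  cat("<story_index>", x$N, "documents,", length(x$df), "terms\n")
  invisible(x)
}

#' Turn free text into a query vector
#'
#' Weights the query's terms by the index's tf-idf scheme (terms absent
#' from the index are dropped) and L2-normalises.
#'
#' @param index A [build_index()] result.
#' @param text Query text, e.g. the prototype story.
#' @return A sparse query vector.
#' @export
query_vector <- function(index, text) {
  tk <- tokenize(text)
  tk <- tk[tk %in% names(index$df)]
  if (length(tk) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(tk)
  tf <- stats::setNames(as.integer(tab), names(tab))
  w <- (1 + log(tf)) * log(index$N / index$df[names(tf)])
  sv_normalize(sv_drop_zero(w))
}

#' Ranked cosine search
#'
#' Scores every indexed document against the query by cosine similarity
#' (both sides are unit vectors, so the dot product suffices) and returns
#' the top `k`. Ties are broken by ascending document id for
#' reproducibility; excluded ids are never returned.
#'
#' @param index A [build_index()] result.
#' @param query Sparse query vector.
#' @param k Number of results (k larger than the corpus returns all).
#' @param exclude Character vector of ids to omit (e.g. already judged).
#' @return Data frame with columns `id` and `score`, best first.
#' @export
search_index <- function(index, query, k = 10, exclude = character()) {
  stopifnot(k >= 1)
  scores <- stats::setNames(numeric(index$N), names(index$vectors))
  for (t in names(query)) {
    p <- index$postings[[t]]
    if (!is.null(p)) scores[names(p)] <- scores[names(p)] + query[[t]] * p
  }
  if (length(exclude) > 0L) scores <- scores[!names(scores) %in% exclude]
  ord <- order(-scores, names(scores))
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = names(scores)[top], score = unname(scores[top]),
             stringsAsFactors = FALSE)
}

#' Rocchio feedback parameters
#'
#' Weights for the original query (`alpha`), the relevant centroid
#' (`beta`) and the irrelevant centroid (`gamma`). Defaults are the
#' classical SMART values.
#'
#' @param alpha,beta,gamma Non-negative reals.
#' @return List of class `rocchio_params`.
#' @export
rocchio_params <- function(alpha = 1.0, beta = 0.75, gamma = 0.15) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "rocchio_params")
}

#' Rocchio query update
#'
#' Moves the query toward the centroid of judged-relevant documents and
#' away from the centroid of judged-irrelevant ones:
#' `q' = alpha*q0 + (beta/|R|) sum(R) - (gamma/|I|) sum(I)`, with empty
#' sets contributing nothing. Negative weights are clipped to zero and
#' the result is re-normalised to unit length.
#'
#' @param q0 Original sparse query vector.
#' @param relevant,irrelevant Lists of document sparse vectors.
#' @param params A [rocchio_params()].
#' @return Updated sparse query vector.
#' @export
rocchio_update <- function(q0, relevant = list(), irrelevant = list(),
                           params = rocchio_params()) {
  parts <- list(params$alpha * q0)
  if (length(relevant) > 0L) {
    parts <- c(parts, list(params$beta / length(relevant) * sv_sum(relevant)))
  }
  if (length(irrelevant) > 0L) {
    parts <- c(parts, list(-params$gamma / length(irrelevant) * sv_sum(irrelevant)))
  }
  q <- sv_sum(parts)
  q[q < 0] <- 0
  sv_normalize(sv_drop_zero(q))
}

#' Judgment oracle from gold labels
#'
#' Returns a judge function for [run_feedback_session()] that marks a
#' post relevant iff it is a planted stroke narrative, standing in for
#' the human relevance judge in automated runs. A `skip_ids` set is
#' marked skip, mirroring the study's handling of stories whose patient
#' sex was unidentifiable or whose blogs denied access.
#'
#' @param corpus A synthetic corpus with gold labels.
#' @param skip_ids Ids to be judged `"skip"`.
#' @return Function mapping a post id to
#'   `"relevant"`, `"irrelevant"` or `"skip"`.
#' @export
gold_judge <- function(corpus, skip_ids = character()) {
  stroke_ids <- corpus$id[is_stroke_story(corpus)]
  function(id) {
    if (id %in% skip_ids) "skip"
    else if (id %in% stroke_ids) "relevant"
    else "irrelevant"
  }
}

#' Run a relevance-feedback retrieval session
#'
#' Iterates search and judgment: each round retrieves the top `batch`
#' unjudged documents, collects a judgment (relevant / irrelevant / skip)
#' for each, logs precision-at-batch, and updates the query by
#' [rocchio_update()] using only the relevant and irrelevant documents.
#' Skipped documents contribute nothing to the update; like all judged
#' documents they are only excluded from later result pages.
#'
#' @param index A [build_index()] result.
#' @param prototype Prototype story text used as the initial query.
#' @param judge Function mapping a post id to a judgment label.
#' @param batch Results presented per round.
#' @param rounds Number of feedback rounds.
#' @param params A [rocchio_params()].
#' @return A `retrieval_log`: list with per-round entries (query vector,
#'   result ids, judgments, precision) and the cumulative relevant ids.
#' @export
run_feedback_session <- function(index, prototype, judge, batch = 10,
                                 rounds = 3, params = rocchio_params()) {
  if (index$N == 0L) stop("empty index", call. = FALSE)
  q <- query_vector(index, prototype)
  judged <- character()
  log <- vector("list", rounds)
  relevant_ids <- character()
  for (r in seq_len(rounds)) {
    res <- search_index(index, q, k = batch, exclude = judged)
    if (nrow(res) == 0L) {
      log[[r]] <- list(query = q, result_ids = character(),
                       judgments = character(), precision = NA_real_)
      next
    }
    jd <- vapply(res$id, judge, character(1))
    if (!all(jd %in% c("relevant", "irrelevant", "skip"))) {
      stop("judge returned an invalid label", call. = FALSE)
    }
    log[[r]] <- list(query = q, result_ids = res$id, judgments = unname(jd),
                     precision = mean(jd == "relevant"))
    judged <- c(judged, res$id)
    relevant_ids <- c(relevant_ids, res$id[jd == "relevant"])
    rel_vecs <- index$vectors[res$id[jd == "relevant"]]
    irr_vecs <- index$vectors[res$id[jd == "irrelevant"]]
    q <- rocchio_update(q, unname(rel_vecs), unname(irr_vecs), params)
  }
  structure(list(rounds = log,
                 precision = vapply(log, `[[`, numeric(1), "precision"),
                 relevant_ids = relevant_ids,
                 judged_ids = judged),
            class = "retrieval_log")
}

#' @export
print.retrieval_log <- function(x, ...) {
  cat("<retrieval_log>", length(x$rounds), "rounds; precision@batch:",
      paste(sprintf("%.2f", x$precision), collapse = ", "), "\n")
  invisible(x)
}
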