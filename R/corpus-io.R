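# Newline-delimited JSON corpus serialization (one post per line, UTF-8).
# Missing record fields are dropped on write and restored as NA on read,
# so write-then-read is the identity on valid corpora.

clean_record_for_json <- function(rec) {
  fields <- coded_schema()$fields
  out <- list()
  for (f in fields) {
    v <- rec[[f]]
    if (!is.null(v) && !is.na(v)) out[[f]] <- v
  }
  out
}

profile_to_json <- function(profile) {
  if (is.null(profile)) return(NULL)
  obj <- list(distractor_class = profile$distractor_class)
  if (!is.null(profile$topic)) obj$topic <- profile$topic
  if (!is.null(profile$voice) && !is.na(profile$voice)) obj$voice <- profile$voice
  if (!is.null(profile$gold)) obj$gold <- clean_record_for_json(profile$gold)
  obj
}

json_to_profile <- function(obj) {
  if (is.null(obj)) return(NULL)
  profile <- list(gold = NULL,
                  voice = obj$voice %||% NA_character_,
                  distractor_class = obj$distractor_class)
  if (!is.null(obj$topic)) profile$topic <- obj$topic
  if (!is.null(obj$gold)) {
    rec <- empty_coded_record()
    for (f in names(obj$gold)) {
      v <- obj$gold[[f]]
      rec[[f]] <- if (f == "age_years") as.integer(v) else v
    }
    profile$gold <- rec
  }
  profile
}

#' Write a corpus as newline-delimited JSON
#'
#' One post per line with fields `id`, `date`, `text` and, for synthetic
#' corpora, the `gold` story profile. UTF-8 throughout. Reading a
#' written file back reproduces the corpus exactly.
#'
#' @param corpus Corpus data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    obj <- list(id = corpus$id[i], date = corpus$date[i], text = corpus$text[i])
    gold <- profile_to_json(corpus$gold[[i]])
    if (!is.null(gold)) obj$gold <- gold
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) {
    warning("empty corpus file: ", path, call. = FALSE)
    corpus <- data.frame(id = character(), date = character(),
                         text = character(), stringsAsFactors = FALSE)
    corpus$gold <- list()
    return(corpus)
  }
  posts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj)) {
      stop(sprintf("malformed JSON at line %d of %s", i, path), call. = FALSE)
    }
    for (f in c("id", "text")) {
      if (is.null(obj[[f]]) || !nzchar(obj[[f]])) {
        stop(sprintf("line %d of %s: missing or empty '%s'", i, path, f),
             call. = FALSE)
      }
    }
    posts[[i]] <- obj
  }
  ids <- vapply(posts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate post id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  corpus <- data.frame(
    id = ids,
    date = vapply(posts, function(p) p$date %||% NA_character_, character(1)),
    text = vapply(posts, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  corpus$gold <- lapply(posts, function(p) json_to_profile(p$gold))
  corpus
}
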