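test_that("tokenizer applies the length and digit rules", {
  expect_equal(tokenize("I felt confused!"), c("felt", "confused"))
  expect_equal(tokenize("called 911."), c("called", "911"))
  expect_equal(tokenize("a 12 x2 no"), c("x2", "no"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("  !!  "), character())
})

test_that("index weights match hand-computed tf-idf", {
  idx <- build_index(toy_posts())
  # document frequencies: apple 1, banana 2, cherry 2, date 1; N = 3
  w_apple <- (1 + log(2)) * log(3)      # d1: tf 2
  w_banana_d1 <- log(3 / 2)             # d1: tf 1
  v1 <- c(apple = w_apple, banana = w_banana_d1)
  v1 <- v1 / sqrt(sum(v1^2))
  expect_equal(sort(idx$vectors$d1), sort(v1), tolerance = 1e-12)
  expect_equal(unname(sapply(idx$vectors, function(v) sqrt(sum(v^2)))),
               rep(1, 3), tolerance = 1e-12)
})

test_that("terms present in every document are dropped", {
  posts <- data.frame(id = c("a", "b", "c"),
                      text = c("common alpha", "common beta", "common gamma"),
                      stringsAsFactors = FALSE)
  idx <- build_index(posts)
  expect_false(any(vapply(idx$vectors, function(v) "common" %in% names(v),
                          logical(1))))
  # a single surviving term gives a unit vector
  expect_equal(unname(idx$vectors$a["alpha"]), 1)
})

test_that("duplicate document ids are a hard error", {
  posts <- data.frame(id = c("a", "a"), text = c("x y", "z w"),
                      stringsAsFactors = FALSE)
  expect_error(build_index(posts), "duplicate")
})

test_that("search matches brute-force cosine enumeration", {
  posts <- data.frame(
    id = sprintf("p%d", 1:5),
    text = c("stroke hospital sudden", "golf swing round", "stroke golf luck",
             "hospital ward visit", "sudden spin fall"),
    stringsAsFactors = FALSE
  )
  idx <- build_index(posts)
  q <- query_vector(idx, "stroke hospital")
  res <- search_index(idx, q, k = 5)
  brute <- vapply(idx$vectors, function(v) {
    shared <- intersect(names(v), names(q))
    sum(v[shared] * q[shared])
  }, numeric(1))
  expected <- names(sort(-brute))  # ties broken by id via stable name order
  ord <- order(-brute, names(brute))
  expect_equal(res$id, names(brute)[ord])
  expect_equal(res$score, unname(brute[ord]), tolerance = 1e-12)
})

test_that("a document used as its own query ranks first with score 1", {
  co <- small_corpus(301, 10, 20, 20)
  idx <- build_index(co)
  doc <- co$id[5]
  res <- search_index(idx, idx$vectors[[doc]], k = 3)
  expect_equal(res$id[1], doc)
  expect_equal(res$score[1], 1, tolerance = 1e-9)
})

test_that("k beyond the corpus returns everything; exclusions never return", {
  idx <- build_index(toy_posts())
  q <- query_vector(idx, "banana cherry")
  expect_equal(nrow(search_index(idx, q, k = 10)), 3L)
  res <- search_index(idx, q, k = 10, exclude = c("d1", "d2"))
  expect_equal(res$id, "d3")
})

test_that("ranking is invariant under document insertion order", {
  co <- small_corpus(302, 15, 30, 30)
  idx1 <- build_index(co)
  idx2 <- build_index(co[rev(seq_len(nrow(co))), ])
  q <- query_vector(idx1, prototype_story())
  expect_equal(search_index(idx1, q, k = 25), search_index(idx2, q, k = 25))
})

test_that("Rocchio update follows the formula on a hand example", {
  q0 <- c(a = 1)
  r <- c(a = 0.5, b = 0.5)
  i <- c(b = 1)
  out <- rocchio_update(q0, list(r), list(i),
                        rocchio_params(alpha = 1, beta = 0.75, gamma = 0.15))
  pre <- c(a = 1 + 0.75 * 0.5, b = 0.75 * 0.5 - 0.15)  # {a: 1.375, b: 0.225}
  expect_equal(sort(out), sort(pre / sqrt(sum(pre^2))), tolerance = 1e-12)
})

test_that("Rocchio degenerate and clipping behaviour", {
  q0 <- c(x = 0.6, y = 0.8)
  expect_equal(rocchio_update(q0, list(), list()), q0)   # alpha = 1 identity
  r <- c(z = 1)
  expect_equal(rocchio_update(q0, list(r), list(),
                              rocchio_params(alpha = 0, beta = 1, gamma = 0)),
               r)                                         # pure substitution
  # a strong negative term is clipped to zero, not stored
  out <- rocchio_update(c(a = 0.1), list(), list(c(a = 1, b = 1)),
                        rocchio_params(alpha = 1, beta = 0, gamma = 10))
  expect_false("a" %in% names(out))
  expect_false("b" %in% names(out))
})

test_that("sparse Rocchio equals a dense-vector implementation", {
  dense_rocchio <- function(q0, R, I, a, b, g, vocab) {
    densify <- function(v) { d <- setNames(numeric(length(vocab)), vocab); d[names(v)] <- v; d }
    q <- a * densify(q0)
    if (length(R)) q <- q + b * Reduce(`+`, lapply(R, densify)) / length(R)
    if (length(I)) q <- q - g * Reduce(`+`, lapply(I, densify)) / length(I)
    q[q < 0] <- 0
    n <- sqrt(sum(q^2))
    if (n > 0) q <- q / n
    q[q != 0]
  }
  with_seed(77, {
    for (rep in 1:25) {
      vocab <- paste0("t", seq_len(sample(10:50, 1)))
      rand_sv <- function() {
        k <- sample(seq_len(min(8, length(vocab))), 1)
        setNames(round(runif(k), 3), sample(vocab, k))
      }
      q0 <- rand_sv()
      R <- replicate(sample(0:3, 1), rand_sv(), simplify = FALSE)
      I <- replicate(sample(0:3, 1), rand_sv(), simplify = FALSE)
      pars <- rocchio_params(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
      got <- rocchio_update(q0, R, I, pars)
      want <- dense_rocchio(q0, R, I, pars$alpha, pars$beta, pars$gamma, vocab)
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-12)
    }
  })
})

test_that("feedback session semantics: judged exclusion, all-irrelevant drift", {
  co <- small_corpus(303, 25, 50, 50)
  idx <- build_index(co)
  all_irr <- function(id) "irrelevant"
  lg <- run_feedback_session(idx, prototype_story(), all_irr,
                             batch = 10, rounds = 3)
  expect_length(lg$relevant_ids, 0L)
  seen <- unlist(lapply(lg$rounds, `[[`, "result_ids"))
  expect_false(anyDuplicated(seen) > 0)
  # the query moves away from judged documents
  first_batch <- lg$rounds[[1]]$result_ids
  q1 <- lg$rounds[[1]]$query
  q3 <- lg$rounds[[3]]$query
  sim <- function(q, ids) mean(vapply(idx$vectors[ids], function(v) {
    shared <- intersect(names(v), names(q)); sum(v[shared] * q[shared])
  }, numeric(1)))
  expect_lt(sim(q3, first_batch), sim(q1, first_batch))
})

test_that("a single-round session is a plain judged search", {
  co <- small_corpus(304, 20, 30, 30)
  idx <- build_index(co)
  lg <- run_feedback_session(idx, prototype_story(), gold_judge(co),
                             batch = 10, rounds = 1)
  expect_length(lg$rounds, 1L)
  plain <- search_index(idx, query_vector(idx, prototype_story()), k = 10)
  expect_equal(lg$rounds[[1]]$result_ids, plain$id)
  expect_error(run_feedback_session(build_index(toy_posts()[0, ]),
                                    "x", gold_judge(co)), "empty index")
})

test_that("skip judgments never touch the query, only the queue", {
  co <- small_corpus(305, 30, 60, 60)
  idx <- build_index(co)
  base <- gold_judge(co)
  first_page <- search_index(idx, query_vector(idx, prototype_story()), k = 10)
  skip_set <- first_page$id[c(2, 5)]
  skipper <- gold_judge(co, skip_ids = skip_set)
  lg <- run_feedback_session(idx, prototype_story(), skipper,
                             batch = 10, rounds = 3)
  # every round's query must equal the Rocchio update driven only by the
  # non-skip judgments of the previous round
  q <- query_vector(idx, prototype_story())
  for (r in seq_along(lg$rounds)) {
    expect_equal(lg$rounds[[r]]$query, q, tolerance = 1e-12)
    jd <- lg$rounds[[r]]$judgments
    ids <- lg$rounds[[r]]$result_ids
    q <- rocchio_update(q, unname(idx$vectors[ids[jd == "relevant"]]),
                        unname(idx$vectors[ids[jd == "irrelevant"]]))
  }
  # skipped docs are excluded from later pages
  later <- unlist(lapply(lg$rounds[-1], `[[`, "result_ids"))
  expect_false(any(skip_set %in% later))
  # treating the same docs as irrelevant instead does move the query
  lg_irr <- run_feedback_session(idx, prototype_story(), base,
                                 batch = 10, rounds = 2)
  if (any(lg$rounds[[1]]$judgments == "skip")) {
    expect_false(isTRUE(all.equal(lg$rounds[[2]]$query, lg_irr$rounds[[2]]$query)))
  }
})
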