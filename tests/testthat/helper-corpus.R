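# Shared fixtures, built in code at test time.

file_bytes <- function(path) readBin(path, "raw", file.size(path))

# A small corpus with enough of every post class for filter/retrieval tests.
small_corpus <- function(seed = 101, n_stroke = 40, n_other = 80, n_non = 80,
                         mode = "sampled") {
  generate_corpus(corpus_config(
    n_stroke_stories = n_stroke, n_other_stories = n_other,
    n_nonstory_posts = n_non, mode = mode, seed = seed
  ))
}

# Deterministic toy posts for index arithmetic.
toy_posts <- function() {
  data.frame(
    id = c("d1", "d2", "d3"),
    text = c("apple banana apple", "banana cherry", "cherry date"),
    stringsAsFactors = FALSE
  )
}

# Table 4, first-person section, as a counts matrix (sex x mental status).
t4_first_counts <- function() {
  matrix(c(27, 16, 21, 28), nrow = 2,
         dimnames = list(c("female", "male"), c("yes", "no")))
}
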