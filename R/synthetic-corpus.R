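# Synthetic weblog corpus generator: plants stroke narratives with gold
# codes among personal-story and non-story distractors, reproducing the
# marginal structure observed in the reference tables (narrator split,
# sex split, stroke-type mix, per-sex symptom prevalences, age bands).

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the
#' previous RNG state afterwards. All stochastic stages of the package
#' funnel their randomness through one such root seed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Largest-remainder integer apportionment
#'
#' Splits `n` units across categories proportionally to `weights` with
#' zero total error: each category gets the floor of its exact share and
#' the remaining units go to the categories with the largest fractional
#' parts (ties broken in category order). This is the documented rule for
#' resolving margins that are not exactly attainable, e.g. an odd total
#' with a 0.5 fraction.
#'
#' @param n Non-negative integer total.
#' @param weights Named non-negative weights (normalised internally).
#' @return Named integer vector summing to `n`.
#' @export
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    top <- order(-(q - base))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Per-sex symptom prevalence table
#'
#' Marginal probabilities for each of the 13 symptoms, split by patient
#' sex. The defaults are the observed per-sex report rates for women
#' (n=91) and men (n=83): e.g. impaired speech or comprehension 59/91 for
#' women and 47/83 for men. Hemiparesis enters through its two flags,
#' body and face, whose marginal rates count the "both body and face"
#' presentations in each.
#'
#' @param female,male Named numeric vectors of probabilities covering
#'   exactly the 13 symptom keys of [symptom_taxonomy()].
#' @return A 13 x 2 numeric matrix with columns `female`, `male`.
#' @export
prevalence_table <- function(female, male) {
  keys <- names(symptom_taxonomy())
  if (!setequal(names(female), keys) || !setequal(names(male), keys)) {
    stop("prevalence table must cover exactly the 13-symptom taxonomy",
         call. = FALSE)
  }
  m <- cbind(female = female[keys], male = male[keys])
  if (any(m < 0 | m > 1)) stop("prevalences must lie in [0, 1]", call. = FALSE)
  rownames(m) <- keys
  m
}

#' @rdname prevalence_table
#' @export
prevalence_defaults <- function() {
  prevalence_table(
    female = c(
      hemiparesis_body = 66 / 91, hemiparesis_face = 38 / 91,
      impaired_speech_or_comprehension = 59 / 91,
      visual_disturbance = 11 / 91, ataxia_discoordination = 16 / 91,
      vertigo = 13 / 91, balance_difficulty = 7 / 91,
      pain_excl_headache = 5 / 91, mental_status_change = 39 / 91,
      headache = 16 / 91, lightheadedness = 5 / 91,
      other_neurologic = 13 / 91, nonneurologic = 4 / 91
    ),
    male = c(
      hemiparesis_body = 59 / 83, hemiparesis_face = 30 / 83,
      impaired_speech_or_comprehension = 47 / 83,
      visual_disturbance = 5 / 83, ataxia_discoordination = 11 / 83,
      vertigo = 13 / 83, balance_difficulty = 8 / 83,
      pain_excl_headache = 5 / 83, mental_status_change = 27 / 83,
      headache = 11 / 83, lightheadedness = 3 / 83,
      other_neurologic = 9 / 83, nonneurologic = 5 / 83
    )
  )
}

#' Synthetic corpus configuration
#'
#' The study conditions the generator emulates. Defaults encode the
#' observed margins: narrator split 97/191 first person, patient sex
#' split 91/174 female among symptom-reporting stories, stroke-type mix
#' 67:29:78 ischemic:hemorrhagic:undiagnosed, per-sex symptom
#' prevalences (see [prevalence_defaults()]), the seven-band age
#' distribution, and the assistance/delay/treatment rates. Post dates
#' are drawn uniformly over 2010--2011.
#'
#' @param n_stroke_stories,n_other_stories,n_nonstory_posts Post counts
#'   per class (stroke narrative, non-medical personal story, non-story).
#' @param narrator_first_fraction Proportion of stroke stories narrated
#'   by the patient.
#' @param female_fraction Proportion of stroke stories about female
#'   patients.
#' @param stroke_type_mix Proportions over ischemic, hemorrhagic and
#'   unknown (no reported diagnosis); must sum to 1.
#' @param symptom_prevalence A [prevalence_table()].
#' @param age_band_weights Proportions over the 7 age bands.
#' @param age_reported_fraction Probability that a story reports the
#'   patient's age at all.
#' @param witness_fraction Probability that a third-person narrator
#'   witnessed the stroke.
#' @param relation_weights Proportions over the third-person narrator
#'   relations (adult child, spouse, other relative, friend, stranger).
#' @param sought_assistance_rate,immediate_treatment_rate Probabilities
#'   for the assistance and treatment fields.
#' @param delayed_by_sex Named probabilities (female, male) of a delay
#'   before seeking assistance, given assistance was sought.
#' @param mode `"exact_margins"` reproduces the configured narrator, sex
#'   and stroke-type counts exactly (largest-remainder rounding);
#'   `"sampled"` draws them as independent categorical samples.
#' @param seed Integer seed controlling the whole corpus.
#' @return A validated list of class `corpus_config`.
#' @export
corpus_config <- function(n_stroke_stories = 200,
                          n_other_stories = 900,
                          n_nonstory_posts = 900,
                          narrator_first_fraction = 97 / 191,
                          female_fraction = 91 / 174,
                          stroke_type_mix = c(ischemic = 67 / 174,
                                              hemorrhagic = 29 / 174,
                                              unknown = 78 / 174),
                          symptom_prevalence = prevalence_defaults(),
                          age_band_weights = c(3, 14, 24, 27, 11, 3, 3) / 85,
                          age_reported_fraction = 85 / 174,
                          witness_fraction = 40 / 94,
                          relation_weights = c(adult_child = 39, spouse = 24,
                                               other_relative = 15, friend = 5,
                                               stranger = 11) / 94,
                          sought_assistance_rate = 0.96,
                          immediate_treatment_rate = 0.90,
                          delayed_by_sex = c(female = 35 / 80, male = 24 / 76),
                          mode = c("sampled", "exact_margins"),
                          seed = 1L) {
  cfg <- list(
    n_stroke_stories = as.integer(n_stroke_stories),
    n_other_stories = as.integer(n_other_stories),
    n_nonstory_posts = as.integer(n_nonstory_posts),
    narrator_first_fraction = narrator_first_fraction,
    female_fraction = female_fraction,
    stroke_type_mix = stroke_type_mix,
    symptom_prevalence = symptom_prevalence,
    age_band_weights = stats::setNames(age_band_weights, .age_bands),
    age_reported_fraction = age_reported_fraction,
    witness_fraction = witness_fraction,
    relation_weights = relation_weights,
    sought_assistance_rate = sought_assistance_rate,
    immediate_treatment_rate = immediate_treatment_rate,
    delayed_by_sex = delayed_by_sex,
    mode = match.arg(mode),
    seed = as.integer(seed)
  )
  class(cfg) <- "corpus_config"
  validate_corpus_config(cfg)
  cfg
}

validate_corpus_config <- function(cfg) {
  counts <- c(cfg$n_stroke_stories, cfg$n_other_stories, cfg$n_nonstory_posts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("corpus counts must be non-negative", call. = FALSE)
  }
  props <- c(cfg$narrator_first_fraction, cfg$female_fraction,
             cfg$age_reported_fraction, cfg$witness_fraction,
             cfg$sought_assistance_rate, cfg$immediate_treatment_rate,
             cfg$delayed_by_sex)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  for (w in list(cfg$stroke_type_mix, cfg$age_band_weights,
                 cfg$relation_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (!setequal(names(cfg$stroke_type_mix), .stroke_types)) {
    stop("stroke_type_mix must cover ischemic, hemorrhagic, unknown",
         call. = FALSE)
  }
  prevalence_table(cfg$symptom_prevalence[, "female"],
                   cfg$symptom_prevalence[, "male"])
  invisible(cfg)
}

#' Sample a gold-coded story profile
#'
#' Draws the 13 symptom flags as independent Bernoulli draws at the
#' configured per-sex rates (independence across symptoms is a documented
#' simplification: only marginal rates are calibrated), plus age,
#' witness/relation (third person only) and the assistance, delay and
#' treatment fields. Uses the current RNG state.
#'
#' @param prev A [prevalence_table()].
#' @param sex `"female"` or `"male"`.
#' @param narrator `"first"` or `"third"`.
#' @param stroke_type `"ischemic"`, `"hemorrhagic"` or `"unknown"`.
#' @param config A [corpus_config()] supplying the remaining field rates.
#' @return A story profile: list with `gold` (coded record as a named
#'   list), `voice`, and `distractor_class = "none"`.
#' @export
sample_profile <- function(prev, sex = c("female", "male"),
                           narrator = c("first", "third"),
                           stroke_type = "unknown",
                           config = corpus_config()) {
  sex <- match.arg(sex)
  narrator <- match.arg(narrator)
  stopifnot(stroke_type %in% .stroke_types)
  g <- empty_coded_record()
  g$narrator <- narrator
  g$patient_sex <- sex
  g$stroke_type <- stroke_type
  for (s in rownames(prev)) g[[s]] <- stats::runif(1) < prev[s, sex]
  if (stats::runif(1) < config$age_reported_fraction) {
    band <- sample(.age_bands, 1L, prob = config$age_band_weights)
    i <- match(band, .age_bands)
    lo <- .age_band_breaks[i]
    hi <- if (is.finite(.age_band_breaks[i + 1])) .age_band_breaks[i + 1] - 1 else 95
    g$age_years <- as.integer(sample(seq.int(lo, hi), 1L))
    g$age_band <- band
  }
  if (narrator == "third") {
    g$witness <- stats::runif(1) < config$witness_fraction
    g$relation <- sample(names(config$relation_weights), 1L,
                         prob = config$relation_weights)
  }
  g$sought_assistance <- stats::runif(1) < config$sought_assistance_rate
  if (isTRUE(g$sought_assistance)) {
    g$delayed_assistance <- stats::runif(1) < config$delayed_by_sex[[sex]]
    g$immediate_treatment <- stats::runif(1) < config$immediate_treatment_rate
  }
  list(gold = g, voice = narrator, distractor_class = "none")
}

assign_margin <- function(n, weights, mode) {
  if (n == 0L) return(character())
  if (mode == "exact_margins") {
    counts <- largest_remainder(n, weights)
    sample(rep(names(counts), counts))
  } else {
    sample(names(weights), n, replace = TRUE, prob = weights)
  }
}

#' Generate a synthetic weblog corpus
#'
#' Produces an ordered corpus of posts: planted stroke narratives with
#' gold coded records, non-medical personal-story distractors (travel,
#' sports, work, non-stroke emergency visits) and non-story posts, in a
#' seeded random order. In `exact_margins` mode the gold narrator, sex
#' and stroke-type counts equal the configured counts exactly (see
#' [largest_remainder()]); in `sampled` mode they are categorical draws.
#' The same configuration and seed always yield a byte-identical corpus.
#'
#' @param config A [corpus_config()].
#' @return A data frame with columns `id`, `date`, `text` and a `gold`
#'   list-column holding each post's story profile.
#' @export
generate_corpus <- function(config = corpus_config()) {
  validate_corpus_config(config)
  lex <- story_lexicons()
  with_seed(config$seed, {
    n_s <- config$n_stroke_stories
    narr <- assign_margin(n_s, c(first = config$narrator_first_fraction,
                                 third = 1 - config$narrator_first_fraction),
                          config$mode)
    sex <- assign_margin(n_s, c(female = config$female_fraction,
                                male = 1 - config$female_fraction),
                         config$mode)
    typ <- assign_margin(n_s, config$stroke_type_mix, config$mode)
    profiles <- vector("list", n_s + config$n_other_stories + config$n_nonstory_posts)
    for (i in seq_len(n_s)) {
      profiles[[i]] <- sample_profile(config$symptom_prevalence, sex[i],
                                      narr[i], typ[i], config)
    }
    topics <- names(lex$distractor_topics)
    for (i in seq_len(config$n_other_stories)) {
      profiles[[n_s + i]] <- list(gold = NULL, voice = NA_character_,
                                  distractor_class = "other_story",
                                  topic = sample1(topics))
    }
    for (i in seq_len(config$n_nonstory_posts)) {
      profiles[[n_s + config$n_other_stories + i]] <-
        list(gold = NULL, voice = NA_character_, distractor_class = "nonstory")
    }
    ord <- sample.int(length(profiles))
    profiles <- profiles[ord]
    days <- seq(as.Date("2010-01-01"), as.Date("2011-12-31"), by = "day")
    n <- length(profiles)
    ids <- sprintf("post-%05d", seq_len(n))
    dates <- format(days[sample.int(length(days), n, replace = TRUE)])
    texts <- character(n)
    for (i in seq_len(n)) {
      texts[i] <- render_story(profiles[[i]], lex)
      if (!is.null(profiles[[i]]$gold)) profiles[[i]]$gold$story_id <- ids[i]
    }
    corpus <- data.frame(id = ids, date = dates, text = texts,
                         stringsAsFactors = FALSE)
    corpus$gold <- profiles
    corpus
  })
}

#' Gold-truth helpers for synthetic corpora
#'
#' `is_story()` flags posts that are personal stories (planted stroke
#' narratives and non-medical story distractors); `is_stroke_story()`
#' flags the stroke narratives only; `gold_records()` extracts the gold
#' coded records of the stroke narratives as a data frame.
#'
#' @param corpus A corpus data frame from [generate_corpus()] or
#'   [read_corpus()].
#' @return Logical vector, or (for `gold_records()`) a coded-records
#'   data frame.
#' @export
is_story <- function(corpus) {
  vapply(corpus$gold, function(g) {
    !is.null(g) && g$distractor_class %in% c("none", "other_story")
  }, logical(1))
}

#' @rdname is_story
#' @export
is_stroke_story <- function(corpus) {
  vapply(corpus$gold, function(g) {
    !is.null(g) && identical(g$distractor_class, "none")
  }, logical(1))
}

#' @rdname is_story
#' @export
gold_records <- function(corpus) {
  recs <- lapply(corpus$gold[is_stroke_story(corpus)], function(g) g$gold)
  as_coded_df(recs)
}
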