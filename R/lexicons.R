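# Phrase pools for the synthetic corpus. Every symptom phrase is a
# multi-word noun phrase unique to its symptom: no phrase is a substring of
# a phrase in another lexicon, and none occurs in the distractor or filler
# pools. auto_code() relies on this to invert render_story() exactly.

#' Phrase lexicons for story rendering and auto-coding
#'
#' The phrase pools used by [render_story()] to realise gold symptom flags
#' as surface text, and by [auto_code()] to invert them. Includes the
#' 13 per-symptom lexicons, narrator/sex/stroke-type surface markers, the
#' non-medical distractor topics (travel, sports, work, and a
#' non-stroke emergency-room visit), and non-story filler material.
#'
#' @return Nested list of character vectors.
#' @export
story_lexicons <- function() {
  list(
    symptoms = list(
      hemiparesis_body = c(
        "no strength down one side of the body",
        "an arm and a leg that refused to move",
        "one side of the body going completely limp"
      ),
      hemiparesis_face = c(
        "a drooping face on one side",
        "a sagging lopsided smile",
        "numbness across half the face"
      ),
      impaired_speech_or_comprehension = c(
        "slurred speech that made no sense",
        "garbled words that came out wrong",
        "trouble understanding simple sentences"
      ),
      visual_disturbance = c(
        "double vision",
        "a gray curtain falling over one eye",
        "blurred sight in one eye"
      ),
      ataxia_discoordination = c(
        "clumsy uncoordinated movements",
        "hands fumbling and missing every object"
      ),
      vertigo = c(
        "the room spinning violently",
        "a sudden spinning sensation"
      ),
      balance_difficulty = c(
        "trouble keeping balance when standing",
        "staggering as if the floor were tilting"
      ),
      pain_excl_headache = c(
        "a sharp pain shooting down the neck",
        "a deep ache spreading through one shoulder"
      ),
      mental_status_change = c(
        "sudden confusion and disorientation",
        "a blackout with loss of consciousness",
        "a fog where thinking clearly became impossible"
      ),
      headache = c(
        "the worst headache of a lifetime",
        "a thunderclap headache",
        "a pounding headache unlike any before"
      ),
      lightheadedness = c(
        "feeling lightheaded and faint",
        "a woozy lightheaded spell"
      ),
      other_neurologic = c(
        "waves of nausea and relentless hiccups",
        "a strange weakness all over the body"
      ),
      nonneurologic = c(
        "chest pain with palpitations",
        "shortness of breath and a racing heart"
      )
    ),
    narrator_third_markers = c(
      "my husband", "my wife", "my mother", "my father",
      "my aunt", "my uncle", "my friend", "a stranger"
    ),
    sex_markers = list(
      female = c("i am a woman", "my wife", "my mother", "my aunt", " she "),
      male = c("i am a man", "my husband", "my father", "my uncle", " he ")
    ),
    stroke_type_markers = list(
      ischemic = c("ischemic stroke"),
      hemorrhagic = c("hemorrhagic stroke"),
      unknown = c("it was a stroke")
    ),
    first_openers = c(
      "So this finally gets written down: the day of my stroke.",
      "I have been meaning to blog about the morning everything changed.",
      "People keep asking what my stroke was like, so here it is.",
      "This post is hard to write, but my stroke story matters."
    ),
    third_openers = c(
      "%s had a stroke %s, and I still think about it daily.",
      "I want to write about the day %s had a stroke %s.",
      "%s suffered a stroke %s and our family is still processing it."
    ),
    when_phrases = c(
      "last spring", "last winter", "a few months ago", "earlier this year",
      "around the holidays"
    ),
    symptom_templates_first = c(
      "I had %s.", "I remember %s.", "Out of nowhere there was %s.",
      "Then came %s."
    ),
    symptom_templates_third = c(
      "%s had %s.", "%s described %s.", "At some point %s experienced %s."
    ),
    distractor_topics = list(
      travel = c(
        "We finally took that road trip along the coast.",
        "The hostel in Lisbon was noisy but charming.",
        "I missed my connecting flight in Denver and slept at the gate.",
        "The hiking trail wound past three waterfalls.",
        "Street food in Bangkok ruined all other food for me.",
        "Our rental car broke down outside a tiny mountain village.",
        "The museum queue wrapped twice around the block.",
        "I filled two memory cards with photos of the old town."
      ),
      sports = c(
        "I shaved two strokes off my golf round on Saturday.",
        "Swim practice was brutal; my freestyle stroke is finally smoothing out.",
        "The marathon training plan says twenty miles this weekend.",
        "Our rec league team lost in the final minute again.",
        "By a stroke of luck the rain held off until the ninth inning.",
        "My backstroke turn still loses me half a second every lap.",
        "The coach made us run bleachers until sunset.",
        "New running shoes, same slow splits."
      ),
      work = c(
        "The quarterly report ate my entire week.",
        "Our team shipped the release two days early for once.",
        "The office moved floors and nobody can find the printer.",
        "I presented to the board and my slides froze twice.",
        "Performance reviews are the worst part of the season.",
        "The new hire asked the question everyone was afraid to ask.",
        "Budget meetings ran long every single day.",
        "I finally cleaned out four years of old email."
      ),
      stroke_mention = c(
        "October is stroke awareness month, so our clinic ran a refresher session on the warning signs.",
        "The session covered the signs of a stroke: slurred speech, a numb arm, sudden confusion, dizzy spells, and trouble keeping balance.",
        "The take-home advice was to call 911 and wait for the paramedics instead of driving.",
        "If you ever notice slurred speech, sudden confusion, or weakness on one side, call 911 right away.",
        "Grandpa survived a stroke long before I was born, and the family still retells the hospital story.",
        "The instructor said treatment works best when patients reach the emergency room fast.",
        "A scan at the hospital is how a stroke gets diagnosed, the nurse explained.",
        "We practiced what to tell the 911 dispatcher during the first aid course.",
        "A stroke can cause a terrible headache, dizzy spells, or trouble with speech, the pamphlet said.",
        "The fundraiser for the rehabilitation ward raised two thousand dollars.",
        "The panel answered audience questions about blood pressure and recovery."
      ),
      er_visit = c(
        "I slipped on the icy porch and snapped my wrist.",
        "Someone called 911 and the paramedics were kind about it.",
        "The emergency room was packed and the wait was endless.",
        "The x ray confirmed a clean break, cast for six weeks.",
        "A kidney stone sent me to the hospital at two in the morning.",
        "The triage nurse took one look and moved me up the queue.",
        "They wheeled me past a dozen curtained beds.",
        "Discharge papers, crutches, and a long taxi ride home."
      )
    ),
    distractor_openers = c(
      "Quick update from my corner of the world.",
      "It has been a while since my last post, so here goes.",
      "What a week this turned out to be.",
      "Writing this from the kitchen table with cold coffee."
    ),
    nonstory_pool = c(
      "Top ten tips for keeping houseplants alive through winter.",
      "This slow cooker recipe needs only five ingredients.",
      "The city council approved the new bike lane proposal on Tuesday.",
      "Review: the budget laptop that punches above its price.",
      "Five stretches to do before every workout, according to trainers.",
      "Local farmers market extends its hours for the summer season.",
      "How to descale a kettle with pantry staples.",
      "The library announces a new interlibrary loan system.",
      "Ranking this year's pumpkin spice products from worst to best.",
      "A beginner guide to composting in a small apartment.",
      "The commuter rail schedule changes take effect next month.",
      "Three common mistakes when repotting succulents."
    )
  )
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

# Patient noun as seen from the narrator, by relation and patient sex.
patient_noun <- function(relation, sex) {
  switch(relation,
    spouse = if (sex == "female") "My wife" else "My husband",
    adult_child = if (sex == "female") "My mother" else "My father",
    other_relative = if (sex == "female") "My aunt" else "My uncle",
    friend = "My friend",
    stranger = "A stranger",
    stop("unknown relation: ", relation, call. = FALSE)
  )
}

#' Render a story profile as blog-post text
#'
#' Realises a [sample_profile()] result as free text using the phrase
#' lexicons. Every gold-flagged symptom contributes at least one phrase
#' from that symptom's lexicon; first-person texts use first-person
#' patient pronouns and carry an explicit sex marker, while third-person
#' texts name a patient other than the narrator (spouse, parent, other
#' relative, friend, or stranger) and use she/he pronouns. Stroke type,
#' assistance, delay and treatment fields are realised as marker
#' sentences so the lexicon auto-coder can invert them. Uses the current
#' R random number generator state for phrase choice.
#'
#' @param profile A story profile (see [sample_profile()]).
#' @param lexicons Phrase lexicons, defaulting to [story_lexicons()].
#' @return A single string of sentences.
#' @export
render_story <- function(profile, lexicons = story_lexicons()) {
  if (!identical(profile$distractor_class, "none")) {
    return(render_distractor(profile, lexicons))
  }
  g <- profile$gold
  flagged <- names(symptom_taxonomy())[vapply(names(symptom_taxonomy()),
                                              function(s) isTRUE(g[[s]]), logical(1))]
  unknown <- setdiff(flagged, names(lexicons$symptoms))
  if (length(unknown) > 0L) {
    stop("no lexicon for symptom key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  first <- identical(profile$voice, "first")
  out <- character()
  if (first) {
    out <- c(out, sample1(lexicons$first_openers))
    sexword <- if (g$patient_sex == "female") "woman" else "man"
    out <- c(out, if (!is.na(g$age_years)) {
      sprintf("For context, I am a %s of %d.", sexword, g$age_years)
    } else {
      sprintf("For context, I am a %s.", sexword)
    })
  } else {
    noun <- patient_noun(g$relation, g$patient_sex)
    out <- c(out, sprintf(sample1(lexicons$third_openers), noun,
                          sample1(lexicons$when_phrases)))
    pron_sex <- if (g$patient_sex == "female") "She" else "He"
    # guaranteed pronoun sentence so the patient's sex is always recoverable
    out <- c(out, sprintf("%s collapsed without any warning.", pron_sex))
    out <- c(out, if (!is.na(g$age_years)) {
      sprintf("%s is %d years old.", pron_sex, g$age_years)
    } else {
      character()
    })
    out <- c(out, if (isTRUE(g$witness)) {
      "I was right there and saw the whole thing happen."
    } else if (isFALSE(g$witness)) {
      "I was not there myself and only heard about it afterwards."
    } else {
      character()
    })
  }
  for (s in flagged) {
    phrase <- sample1(lexicons$symptoms[[s]])
    out <- c(out, if (first) {
      sprintf(sample1(lexicons$symptom_templates_first), phrase)
    } else {
      pron <- if (g$patient_sex == "female") "she" else "he"
      tmpl <- sample1(lexicons$symptom_templates_third)
      # sentence-initial pronoun is capitalised
      s0 <- sprintf(tmpl, pron, phrase)
      paste0(toupper(substring(s0, 1, 1)), substring(s0, 2))
    })
  }
  if (isTRUE(g$sought_assistance)) {
    out <- c(out, "Someone called 911 and the paramedics arrived.",
             if (first) "I was taken to the emergency room." else
               "The ambulance went straight to the emergency room.")
    if (isTRUE(g$delayed_assistance)) {
      out <- c(out, "Looking back, we waited far too long before seeking help.")
    } else if (isFALSE(g$delayed_assistance)) {
      out <- c(out, "We did not hesitate and got help right away.")
    }
  }
  out <- c(out, switch(g$stroke_type,
    ischemic = "The neurologist said it was an ischemic stroke, a clot blocking a vessel.",
    hemorrhagic = "The scan showed a hemorrhagic stroke, bleeding in the brain.",
    unknown = "At the hospital the doctors confirmed it was a stroke."
  ))
  if (isTRUE(g$immediate_treatment)) {
    out <- c(out, "Treatment started immediately on arrival.")
  } else if (isFALSE(g$immediate_treatment)) {
    out <- c(out, "It took a long while at the hospital before treatment began.")
  }
  out <- c(out, if (first) {
    "I am writing this down so other people recognize the warning signs."
  } else {
    "I am sharing this so other families recognize the warning signs."
  })
  paste(out, collapse = " ")
}

render_distractor <- function(profile, lexicons) {
  if (identical(profile$distractor_class, "other_story")) {
    topic <- lexicons$distractor_topics[[profile$topic]]
    n <- sample.int(5L, 1L) + 1L
    paste(c(sample1(lexicons$distractor_openers),
            topic[sample.int(length(topic), min(n, length(topic)))]),
          collapse = " ")
  } else {
    pool <- lexicons$nonstory_pool
    n <- sample.int(3L, 1L) + 1L
    paste(pool[sample.int(length(pool), min(n, length(pool)))], collapse = " ")
  }
}

#' The prototype stroke story used to seed retrieval
#'
#' A short fictional first-person stroke narrative written in a colloquial
#' blog style. It deliberately packs in keywords for traditional and
#' nontraditional symptoms alongside emergency-response vocabulary
#' ("911", "emergency room", "paramedics", "diagnosed with stroke"), so
#' that its tf-idf vector lands near real stroke narratives on the first
#' round of retrieval, before any relevance feedback.
#'
#' @return A single string.
#' @export
prototype_story <- function() {
  path <- system.file("extdata", "prototype_story.txt", package = "strokestory")
  paste(readLines(path, warn = FALSE), collapse = " ")
}
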