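{
  "version": 1,
  "table1": {
    "title": "Age distribution for women (n=40) and men (n=45) patients reporting age",
    "bands": ["0-17", "18-29", "30-44", "45-64", "65-75", "76-84", "85+"],
    "women": [2, 9, 16, 8, 3, 0, 2],
    "men": [1, 5, 8, 19, 8, 3, 1]
  },
  "table2": {
    "title": "Profiles of narrators for women (n=100) and men (n=91) patients",
    "n": {"women": 100, "men": 91},
    "sections": {
      "narrator": {"rows": ["first", "third"], "women": [52, 48], "men": [45, 46]},
      "witness": {"rows": ["yes", "no"], "women": [19, 29], "men": [21, 25]},
      "relative": {"rows": ["adult_child", "other_relative", "spouse"], "women": [24, 10, 6], "men": [15, 5, 18]},
      "nonrelative": {"rows": ["friend", "stranger"], "women": [2, 6], "men": [3, 5], "no_test": true}
    }
  },
  "table3": {
    "title": "Stroke symptoms reported for women (n=91) and men (n=83) patients",
    "n": {"women": 91, "men": 83},
    "rows": [
      {"key": "hemiparesis", "class": "traditional", "women": 68, "men": 63},
      {"key": "body", "parent": "hemiparesis", "women": 30, "men": 33},
      {"key": "face", "parent": "hemiparesis", "women": 2, "men": 4},
      {"key": "both_body_and_face", "parent": "hemiparesis", "women": 36, "men": 26},
      {"key": "impaired_speech_or_comprehension", "class": "traditional", "women": 59, "men": 47},
      {"key": "visual_disturbance", "class": "traditional", "women": 11, "men": 5},
      {"key": "ataxia_discoordination", "class": "traditional", "women": 16, "men": 11},
      {"key": "vertigo", "class": "traditional", "women": 13, "men": 13},
      {"key": "balance_difficulty", "class": "traditional", "women": 7, "men": 8},
      {"key": "pain_excl_headache", "class": "nontraditional", "women": 5, "men": 5},
      {"key": "mental_status_change", "class": "nontraditional", "women": 39, "men": 27},
      {"key": "headache", "class": "nontraditional", "women": 16, "men": 11},
      {"key": "lightheadedness", "class": "nontraditional", "women": 5, "men": 3},
      {"key": "other_neurologic", "class": "nontraditional", "women": 13, "men": 9},
      {"key": "nonneurologic", "class": "nontraditional", "women": 4, "men": 5}
    ]
  },
  "table4": {
    "title": "Reports of mental status change for women (n=91) and men (n=83) patients by narrator",
    "n": {"women": 91, "men": 83},
    "sections": {
      "first": {"rows": ["yes", "no"], "women": [27, 21], "men": [16, 28]},
      "third": {"rows": ["yes", "no"], "women": [12, 31], "men": [11, 28]}
    }
  },
  "table5": {
    "title": "Reports of nontraditional symptoms (excluding mental status change) for women (n=91) and men (n=82) patients by narrator",
    "n": {"women": 91, "men": 82},
    "sections": {
      "first": {"rows": ["ge1", "none"], "women": [22, 26], "men": [19, 25]},
      "third": {"rows": ["ge1", "none"], "women": [12, 31], "men": [9, 30]}
    }
  },
  "table6": {
    "title": "Reports of stroke symptoms by ischemic (n=67) and hemorrhagic (n=29) stroke",
    "n": {"ischemic": 67, "hemorrhagic": 29},
    "rows": [
      {"key": "hemiparesis", "class": "traditional", "ischemic": 56, "hemorrhagic": 20},
      {"key": "body", "parent": "hemiparesis", "ischemic": 19, "hemorrhagic": 9},
      {"key": "face", "parent": "hemiparesis", "ischemic": 5, "hemorrhagic": 0},
      {"key": "both_body_and_face", "parent": "hemiparesis", "ischemic": 32, "hemorrhagic": 11},
      {"key": "impaired_speech_or_comprehension", "class": "traditional", "ischemic": 42, "hemorrhagic": 19},
      {"key": "visual_disturbance", "class": "traditional", "ischemic": 8, "hemorrhagic": 3},
      {"key": "ataxia_discoordination", "class": "traditional", "ischemic": 13, "hemorrhagic": 2},
      {"key": "vertigo", "class": "traditional", "ischemic": 18, "hemorrhagic": 1},
      {"key": "balance_difficulty", "class": "traditional", "ischemic": 5, "hemorrhagic": 2},
      {"key": "pain_excl_headache", "class": "nontraditional", "ischemic": 3, "hemorrhagic": 4},
      {"key": "mental_status_change", "class": "nontraditional", "ischemic": 21, "hemorrhagic": 14},
      {"key": "headache", "class": "nontraditional", "ischemic": 7, "hemorrhagic": 11},
      {"key": "lightheadedness", "class": "nontraditional", "ischemic": 5, "hemorrhagic": 0},
      {"key": "other_neurologic", "class": "nontraditional", "ischemic": 10, "hemorrhagic": 5},
      {"key": "nonneurologic", "class": "nontraditional", "ischemic": 5, "hemorrhagic": 2}
    ]
  },
  "in_text": {
    "stories_total": 191,
    "first_person_stories": 97,
    "third_person_stories": 94,
    "female_all": 100,
    "male_all": 91,
    "stories_with_symptoms": 174,
    "female_sympt": 91,
    "male_sympt": 83,
    "first_person_sympt": 92,
    "third_person_sympt": 82,
    "ischemic_n": 67,
    "hemorrhagic_n": 29,
    "msc_by_narrator": {"rows": ["first", "third"], "yes": [43, 23], "no": [49, 59]},
    "nontrad_excl_msc_by_narrator": {"rows": ["first", "third"], "ge1": [41, 21], "none": [51, 61]},
    "nontrad_any_by_stroke_type": {"rows": ["hemorrhagic", "ischemic"], "ge1": [23, 36], "none": [6, 31]},
    "delayed_by_sex": {"rows": ["women", "men"], "delayed": [35, 24], "not_delayed": [45, 52]},
    "printed_p": {
      "table2_narrator": ".72",
      "table2_witness": ".55",
      "table2_relative": ".008",
      "table4_first": ".056",
      "table4_third": ".97",
      "table6_headache": ".002",
      "table6_vertigo_text": ".008",
      "msc_by_narrator": ".01",
      "delayed_by_sex": ".12",
      "nontrad_excl_msc_by_narrator": ".006",
      "nontrad_any_by_stroke_type": ".001"
    },
    "irreproducible_p": ["nontrad_excl_msc_by_narrator", "nontrad_any_by_stroke_type"]
  }
}
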