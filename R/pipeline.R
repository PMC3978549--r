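# End-to-end driver: simulate -> filter -> retrieve (gold judge) ->
# auto-code -> tabulate -> test, with every stochastic stage seeded from
# one root seed and a manifest of output checksums for reproducibility.

#' Pipeline configuration
#'
#' Bundles the stage configurations. The root `seed` propagates to every
#' stochastic stage (corpus generation and the noise filter draw
#' stage-local generators at fixed offsets from it); retrieval and
#' coding are deterministic given their inputs.
#'
#' @param corpus A [corpus_config()].
#' @param filter List with `precision_target` and `recall_target`.
#' @param retrieval List with `batch`, `rounds` and [rocchio_params()]
#'   fields `alpha`, `beta`, `gamma`.
#' @param seed Root integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = corpus_config(),
                            filter = list(precision_target = 0.66,
                                          recall_target = 0.5),
                            retrieval = list(batch = 25, rounds = 4,
                                             alpha = 1.0, beta = 0.75,
                                             gamma = 0.15),
                            seed = 1L) {
  corpus$seed <- as.integer(seed)
  cfg <- list(corpus = corpus, filter = filter, retrieval = retrieval,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may specify any subset of the [pipeline_config()] and
#' [corpus_config()] fields; unspecified fields keep their defaults.
#' The schema is validated on load.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  corpus_args <- raw$corpus %||% list()
  if (!is.null(corpus_args$stroke_type_mix)) {
    corpus_args$stroke_type_mix <- unlist(corpus_args$stroke_type_mix)
  }
  if (!is.null(corpus_args$relation_weights)) {
    corpus_args$relation_weights <- unlist(corpus_args$relation_weights)
  }
  if (!is.null(corpus_args$delayed_by_sex)) {
    corpus_args$delayed_by_sex <- unlist(corpus_args$delayed_by_sex)
  }
  corpus <- do.call(corpus_config, corpus_args)
  defaults <- pipeline_config()
  pipeline_config(
    corpus = corpus,
    filter = utils::modifyList(defaults$filter, raw$filter %||% list()),
    retrieval = utils::modifyList(defaults$retrieval, raw$retrieval %||% list()),
    seed = raw$seed %||% defaults$seed
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate, filter, retrieve (with the gold-label judge),
#' auto-code, tabulate and test, writing all artefacts to `out_dir`:
#' `corpus.jsonl`, `flagged_ids.txt`, `session.json`,
#' `coded_records.csv`, a `report/` directory of count tables with
#' chi-square p-values, and `manifest.json`. Re-running with an
#' identical configuration reproduces identical file checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if missing.
#' @return The run manifest (config hash, package version, per-file
#'   md5 checksums), invisibly also written as JSON.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- stage("simulate", {
    co <- generate_corpus(config$corpus)
    write_corpus(co, file.path(out_dir, "corpus.jsonl"))
    co
  })
  flagged <- stage("filter", {
    ids <- noise_filter(corpus, config$filter$precision_target,
                        config$filter$recall_target, seed = config$seed + 1L)
    write_flagged_ids(ids, file.path(out_dir, "flagged_ids.txt"))
    ids
  })
  log <- stage("retrieve", {
    idx <- build_index(corpus[corpus$id %in% flagged, , drop = FALSE])
    rp <- rocchio_params(config$retrieval$alpha, config$retrieval$beta,
                         config$retrieval$gamma)
    lg <- run_feedback_session(idx, prototype_story(), gold_judge(corpus),
                               batch = config$retrieval$batch,
                               rounds = config$retrieval$rounds, params = rp)
    session <- list(
      rounds = lapply(lg$rounds, function(r) {
        list(result_ids = r$result_ids, judgments = r$judgments,
             precision = r$precision)
      }),
      precision = lg$precision,
      relevant_ids = lg$relevant_ids
    )
    jsonlite::write_json(session, file.path(out_dir, "session.json"),
                         auto_unbox = TRUE, digits = NA)
    lg
  })
  coded <- stage("code", {
    rel <- corpus[corpus$id %in% log$relevant_ids, , drop = FALSE]
    recs <- do.call(rbind, lapply(seq_len(nrow(rel)), function(i) {
      r <- auto_code(rel$text[i])
      r$story_id <- rel$id[i]
      r
    }))
    if (is.null(recs) || nrow(recs) == 0L) {
      stop("empty selection: no relevant stories retrieved", call. = FALSE)
    }
    write_coded_csv(recs, file.path(out_dir, "coded_records.csv"))
    recs
  })
  report <- stage("tabulate", {
    tabs <- list()
    tabs$narrator_by_sex <- crosstab(coded, "narrator", "patient_sex")
    tabs$msc_by_sex_first <- crosstab(coded, "patient_sex", "mental_status_change",
                                      filter = function(d) d$narrator == "first")
    tabs$msc_by_sex_third <- crosstab(coded, "patient_sex", "mental_status_change",
                                      filter = function(d) d$narrator == "third")
    tabs$msc_by_narrator <- crosstab(coded, "narrator", "mental_status_change")
    tabs$nontrad_excl_msc_by_narrator <-
      crosstab(coded, "narrator", "any_nontraditional_excl_msc")
    tabs$nontrad_by_stroke_type <-
      crosstab(coded, "stroke_type", "any_nontraditional",
               filter = function(d) d$stroke_type %in% c("ischemic", "hemorrhagic"))
    tabs
  })
  results <- stage("test", {
    lapply(report, function(tab) {
      tr <- safe_p(tab)
      df <- as.data.frame.matrix(tab$counts)
      df <- cbind(row = rownames(tab$counts), df, stringsAsFactors = FALSE)
      df$p_value <- c(if (is.null(tr)) NA_real_ else tr$p,
                      rep(NA_real_, nrow(df) - 1L))
      df
    })
  })
  write_report(results, file.path(out_dir, "report"))
  files <- c("corpus.jsonl", "flagged_ids.txt", "session.json",
             "coded_records.csv", file.path("report", "report.md"))
  manifest <- list(
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("strokestory")),
    seed = config$seed,
    checksums = as.list(stats::setNames(
      vapply(files, function(f) unname(tools::md5sum(file.path(out_dir, f))),
             character(1)),
      files
    )),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  stripped <- rapply(unclass(config), function(x) x, how = "list")
  writeLines(as.character(jsonlite::toJSON(stripped, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}
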