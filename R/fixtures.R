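# The shipped count fixture: the published tables (age distribution,
# narrator profiles, symptom counts by sex and by stroke type, and the
# in-text contingency counts), stored exactly as printed, plus the
# machinery that re-derives every percentage and chi-square p-value from
# those counts.

.fixture_md5 <- "1c2ea9ad4e78b952457bdba9d0fad4dd"

#' Load the published count tables
#'
#' Reads the versioned JSON asset holding the printed counts of the six
#' reference tables and the in-text contingency counts, verifies the
#' file checksum, and validates the internal margins (subtype counts sum
#' to their parent, section counts sum to the stated group sizes).
#'
#' @param path Path to the asset; defaults to the copy shipped with the
#'   package.
#' @param verify_checksum Set `FALSE` only when deliberately loading a
#'   modified asset.
#' @return Nested list of tables (see the asset for the layout).
#' @export
load_fixture_tables <- function(path = system.file("extdata", "study_tables.json",
                                                   package = "strokestory"),
                                verify_checksum = TRUE) {
  if (!file.exists(path)) stop("fixture asset not found: ", path, call. = FALSE)
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .fixture_md5)) {
      stop("fixture asset checksum mismatch: file has been modified",
           call. = FALSE)
    }
  }
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_fixture(fx)
  fx
}

validate_fixture <- function(fx) {
  chk <- function(ok, what) if (!ok) stop("fixture margin check failed: ", what,
                                          call. = FALSE)
  chk(sum(fx$table1$women) == 40 && sum(fx$table1$men) == 45,
      "table1 column totals")
  s2 <- fx$table2$sections
  chk(sum(s2$narrator$women) == fx$table2$n$women &&
        sum(s2$narrator$men) == fx$table2$n$men, "table2 narrator totals")
  chk(sum(s2$witness$women) == s2$narrator$women[2] &&
        sum(s2$witness$men) == s2$narrator$men[2], "table2 witness totals")
  chk(sum(s2$relative$women) + sum(s2$nonrelative$women) == s2$narrator$women[2] &&
        sum(s2$relative$men) + sum(s2$nonrelative$men) == s2$narrator$men[2],
      "table2 relation totals")
  for (tb in c("table3", "table6")) {
    rows <- fx[[tb]]$rows
    sub <- rows[!is.na(rows$parent) & rows$parent == "hemiparesis", ]
    parent <- rows[rows$key == "hemiparesis", ]
    for (col in setdiff(names(fx[[tb]]$n), NULL)) {
      chk(sum(sub[[col]]) == parent[[col]], paste(tb, "hemiparesis subtypes", col))
      chk(all(rows[[col]] <= fx[[tb]]$n[[col]]), paste(tb, "counts within n", col))
    }
  }
  for (sec in c("first", "third")) {
    chk(sum(fx$table4$sections[[sec]]$women, fx$table4$sections[[sec]]$men) ==
          fx$in_text[[paste0(sec, "_person_sympt")]],
        paste("table4", sec, "totals"))
  }
  invisible(fx)
}

# one-decimal percentage, rounding halves away from zero (publication style)
percent1 <- function(n, den) floor(1000 * n / den + 0.5) / 10

mk_counts <- function(yes, no, rows, cols) {
  m <- rbind(yes, no)
  dimnames(m) <- list(rows, cols)
  m
}

# chi-square p on a counts matrix, NA when a margin is empty
safe_p <- function(counts) {
  tryCatch(suppressWarnings(pearson_chi2(counts)),
           error = function(e) NULL)
}

p_cols <- function(tr) {
  if (is.null(tr)) {
    list(p_value = NA_real_, p_printed = NA_character_)
  } else {
    list(p_value = tr$p, p_printed = tr$p_printed_3dp)
  }
}

symptom_table_report <- function(tb, cols) {
  rows <- tb$rows
  parent <- rows[rows$key == "hemiparesis", ]
  out <- vector("list", nrow(rows))
  sub_counts <- NULL
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    is_sub <- !is.na(r$parent)
    den <- if (is_sub) c(parent[[cols[1]]], parent[[cols[2]]]) else
      c(tb$n[[cols[1]]], tb$n[[cols[2]]])
    if (is_sub) {
      p <- NA_real_; pp <- NA_character_
      if (is.null(sub_counts)) {
        # one test over the full subtype distribution, attached to its first row
        sub <- rows[!is.na(rows$parent), ]
        m <- as.matrix(sub[, cols]); rownames(m) <- sub$key
        tr <- safe_p(m)
        pc <- p_cols(tr); p <- pc$p_value; pp <- pc$p_printed
        sub_counts <- m
      }
    } else {
      m <- mk_counts(c(r[[cols[1]]], r[[cols[2]]]),
                     c(den[1] - r[[cols[1]]], den[2] - r[[cols[2]]]),
                     c("yes", "no"), cols)
      tr <- safe_p(t(m))
      pc <- p_cols(tr); p <- pc$p_value; pp <- pc$p_printed
    }
    row_out <- data.frame(key = r$key,
                          class = if (is_sub) "subtype" else r$class,
                          stringsAsFactors = FALSE)
    row_out[[paste0(cols[1], "_n")]] <- r[[cols[1]]]
    row_out[[paste0(cols[1], "_pct")]] <- percent1(r[[cols[1]]], den[1])
    row_out[[paste0(cols[2], "_n")]] <- r[[cols[2]]]
    row_out[[paste0(cols[2], "_pct")]] <- percent1(r[[cols[2]]], den[2])
    row_out$p_value <- p
    row_out$p_printed <- pp
    out[[i]] <- row_out
  }
  do.call(rbind, out)
}

two_col_section_report <- function(sections, dens, labels = c("women", "men")) {
  out <- list()
  for (sec in names(sections)) {
    s <- sections[[sec]]
    den <- dens[[sec]]
    m <- rbind(s[[labels[1]]], s[[labels[2]]])
    counts <- t(m)  # rows = section rows, cols = labels
    dimnames(counts) <- list(s$rows, labels)
    tr <- if (isTRUE(s$no_test)) NULL else safe_p(counts)
    pc <- p_cols(tr)
    df <- data.frame(section = sec, row = s$rows, stringsAsFactors = FALSE)
    df[[paste0(labels[1], "_n")]] <- s[[labels[1]]]
    df[[paste0(labels[1], "_pct")]] <- percent1(s[[labels[1]]], den[1])
    df[[paste0(labels[2], "_n")]] <- s[[labels[2]]]
    df[[paste0(labels[2], "_pct")]] <- percent1(s[[labels[2]]], den[2])
    df$p_value <- c(pc$p_value, rep(NA_real_, length(s$rows) - 1L))
    df$p_printed <- c(pc$p_printed, rep(NA_character_, length(s$rows) - 1L))
    out[[sec]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reproduce the published tables from their printed counts
#'
#' Re-derives every percentage (to one decimal) and every chi-square
#' p-value (Pearson, no continuity correction) in the six reference
#' tables and the headline in-text statistics, using only the printed
#' counts in the fixture asset. The two in-text p-values that do not
#' follow from their printed counts (printed .006 and .001; Pearson
#' gives .009 and .018) are reported as recomputed, with the printed
#' value alongside and a `reproduces_printed` flag.
#'
#' @param fixture A [load_fixture_tables()] result.
#' @param which Which of the six tables to include.
#' @return Named list of data frames (`table1` ... `table6`, `in_text`).
#' @export
reproduce_tables <- function(fixture = load_fixture_tables(), which = 1:6) {
  stopifnot(all(which %in% 1:6))
  out <- list()
  if (1 %in% which) {
    t1 <- fixture$table1
    out$table1 <- data.frame(
      band = t1$bands,
      women_n = t1$women, women_pct = percent1(t1$women, sum(t1$women)),
      men_n = t1$men, men_pct = percent1(t1$men, sum(t1$men)),
      stringsAsFactors = FALSE
    )
  }
  if (2 %in% which) {
    n2 <- fixture$table2$n
    third <- c(fixture$table2$sections$narrator$women[2],
               fixture$table2$sections$narrator$men[2])
    rel <- c(sum(fixture$table2$sections$relative$women),
             sum(fixture$table2$sections$relative$men))
    nonrel <- c(sum(fixture$table2$sections$nonrelative$women),
                sum(fixture$table2$sections$nonrelative$men))
    out$table2 <- two_col_section_report(
      fixture$table2$sections,
      dens = list(narrator = c(n2$women, n2$men), witness = third,
                  relative = rel, nonrelative = nonrel)
    )
  }
  if (3 %in% which) {
    out$table3 <- symptom_table_report(fixture$table3, c("women", "men"))
  }
  if (4 %in% which) {
    n4 <- fixture$table4$sections
    dens <- lapply(n4, function(s) c(sum(s$women), sum(s$men)))
    out$table4 <- two_col_section_report(n4, dens)
  }
  if (5 %in% which) {
    n5 <- fixture$table5$sections
    dens <- lapply(n5, function(s) c(sum(s$women), sum(s$men)))
    out$table5 <- two_col_section_report(n5, dens)
  }
  if (6 %in% which) {
    out$table6 <- symptom_table_report(fixture$table6, c("ischemic", "hemorrhagic"))
  }
  out$in_text <- in_text_report(fixture$in_text)
  out
}

in_text_report <- function(it) {
  two_by_two <- function(obj, yes_field, no_field) {
    m <- cbind(obj[[yes_field]], obj[[no_field]])
    dimnames(m) <- list(obj$rows, c(yes_field, no_field))
    m
  }
  entries <- list(
    list(name = "female_share_symptomatic",
         label = sprintf("%d/%d", it$female_sympt, it$stories_with_symptoms),
         value = percent1(it$female_sympt, it$stories_with_symptoms),
         counts = NULL, printed = NA_character_),
    list(name = "first_person_share",
         label = sprintf("%d/%d", it$first_person_stories, it$stories_total),
         value = percent1(it$first_person_stories, it$stories_total),
         counts = NULL, printed = NA_character_),
    list(name = "nontrad_first_person",
         label = sprintf("%d/%d", it$nontrad_excl_msc_by_narrator$ge1[1],
                         it$first_person_sympt),
         value = percent1(it$nontrad_excl_msc_by_narrator$ge1[1],
                          it$first_person_sympt),
         counts = NULL, printed = NA_character_),
    list(name = "nontrad_third_person",
         label = sprintf("%d/%d", it$nontrad_excl_msc_by_narrator$ge1[2],
                         it$third_person_sympt),
         value = percent1(it$nontrad_excl_msc_by_narrator$ge1[2],
                          it$third_person_sympt),
         counts = NULL, printed = NA_character_),
    list(name = "msc_by_narrator", label = "43/92 vs 23/82", value = NA_real_,
         counts = two_by_two(it$msc_by_narrator, "yes", "no"),
         printed = it$printed_p$msc_by_narrator),
    list(name = "delayed_by_sex", label = "35/80 vs 24/76", value = NA_real_,
         counts = two_by_two(it$delayed_by_sex, "delayed", "not_delayed"),
         printed = it$printed_p$delayed_by_sex),
    list(name = "nontrad_excl_msc_by_narrator", label = "41/92 vs 21/82",
         value = NA_real_,
         counts = two_by_two(it$nontrad_excl_msc_by_narrator, "ge1", "none"),
         printed = it$printed_p$nontrad_excl_msc_by_narrator),
    list(name = "nontrad_any_by_stroke_type", label = "23/29 vs 36/67",
         value = NA_real_,
         counts = two_by_two(it$nontrad_any_by_stroke_type, "ge1", "none"),
         printed = it$printed_p$nontrad_any_by_stroke_type)
  )
  rows <- lapply(entries, function(e) {
    if (is.null(e$counts)) {
      data.frame(name = e$name, cell = e$label, value = e$value,
                 p_value = NA_real_, p_printed = NA_character_,
                 p_published = e$printed, reproduces_printed = NA,
                 stringsAsFactors = FALSE)
    } else {
      tr <- safe_p(e$counts)
      pc <- p_cols(tr)
      published <- e$printed
      # compare at the precision of the published rendering
      repro <- if (is.na(published)) NA else {
        digits <- nchar(sub("^\\.", "", published))
        fp <- format_p(tr$p)
        rendered <- if (digits <= 2) fp[["p_2dp"]] else fp[["p_3dp"]]
        identical(rendered, published)
      }
      data.frame(name = e$name, cell = e$label, value = NA_real_,
                 p_value = pc$p_value, p_printed = pc$p_printed,
                 p_published = published, reproduces_printed = repro,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

df_to_markdown <- function(df) {
  fmt <- function(x) {
    x <- vapply(x, function(v) {
      if (is.na(v)) "" else if (is.numeric(v)) format(v, digits = 4) else as.character(v)
    }, character(1))
    x
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(fmt(r), collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write a table report to disk
#'
#' One CSV per table plus a combined Markdown report.
#'
#' @param report A [reproduce_tables()] result (or any named list of
#'   data frames).
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  md <- character()
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    md <- c(md, paste0("## ", nm), "", df_to_markdown(report[[nm]]), "")
  }
  mdp <- file.path(dir, "report.md")
  writeLines(md, mdp)
  invisible(c(paths, mdp))
}
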