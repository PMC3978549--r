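test_that("crosstab counts non-missing pairs in schema order", {
  rec <- expand_table_records(t4_first_counts(), "patient_sex",
                              "mental_status_change",
                              fixed = list(narrator = "first"))
  tab <- crosstab(rec, "patient_sex", "mental_status_change")
  expect_equal(unname(tab$counts), matrix(c(27, 16, 21, 28), 2))
  expect_equal(rownames(tab$counts), c("female", "male"))
  expect_equal(colnames(tab$counts), c("yes", "no"))
  expect_equal(tab$N, 92L)

  # records with a missing column variable drop out of N
  rec2 <- rec
  rec2$mental_status_change[1:5] <- NA
  expect_equal(crosstab(rec2, "patient_sex", "mental_status_change")$N, 87L)

  # filter predicate selects the analysis subset; empty selection errors
  mixed <- rbind(rec, transform(rec, narrator = "third"))
  tfirst <- crosstab(mixed, "patient_sex", "mental_status_change",
                     filter = function(d) d$narrator == "first")
  expect_equal(tfirst$counts, tab$counts)
  expect_error(crosstab(rec, "patient_sex", "mental_status_change",
                        filter = function(d) d$narrator == "third"),
               "empty selection")
})

test_that("Pearson chi-square follows the expected-count formula", {
  flat <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  tr <- pearson_chi2(t4_first_counts())
  expect_equal(tr$statistic, 3.6469, tolerance = 1e-4)
  expect_equal(tr$df, 1L)
  expect_equal(tr$p_printed_3dp, ".056")

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  expect_warning(pearson_chi2(matrix(c(2, 3, 30, 40), 2)), "below 5")
})

test_that("Pearson agrees with the stats::chisq.test oracle, uncorrected", {
  with_seed(13, {
    for (i in 1:20) {
      m <- matrix(rpois(4, 20) + 1, 2)
      got <- suppressWarnings(pearson_chi2(m))
      ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
    m3 <- matrix(rpois(6, 15) + 1, 3)
    expect_equal(suppressWarnings(pearson_chi2(m3))$p,
                 suppressWarnings(stats::chisq.test(m3, correct = FALSE))$p.value,
                 tolerance = 1e-12)
  })
})

test_that("asymptotic p is consistent with a Monte Carlo permutation p", {
  m <- t4_first_counts()
  mc <- with_seed(4, stats::chisq.test(m, simulate.p.value = TRUE, B = 10000))
  got <- pearson_chi2(m)
  se <- sqrt(mc$p.value * (1 - mc$p.value) / 10000)
  expect_lt(abs(got$p - mc$p.value), 0.01 + 3 * se)
})

test_that("chi-square survival function honours the closed forms", {
  expect_equal(chi2_sf(0, 1), 1)
  x <- 9.6987
  expect_equal(chi2_sf(x, 2), exp(-x / 2), tolerance = 1e-12)
  expect_equal(chi2_sf(3.647, 1), 2 * (1 - pnorm(sqrt(3.647))), tolerance = 1e-12)
})

test_that("p-values render in publication style", {
  expect_equal(unname(format_p(0.0561)["p_3dp"]), ".056")
  expect_equal(unname(format_p(0.0112)["p_2dp"]), ".01")
  expect_equal(unname(format_p(1)), c("1.00", "1.000"))
  expect_equal(unname(format_p(0.9761)["p_3dp"]), ".976")
})

test_that("logistic fit recovers the closed-form 2x2 MLE and flags degeneracy", {
  rec <- expand_table_records(t4_first_counts(), "patient_sex",
                              "mental_status_change")
  y <- as.numeric(rec$mental_status_change)
  x <- as.numeric(rec$patient_sex == "female")
  fit <- fit_logistic(y, cbind(sex = x))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["sex"]), log(27 * 28 / (21 * 16)),
               tolerance = 1e-8)
  # cross-check against the glm formula interface
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)

  expect_error(fit_logistic(rep(1, 10), cbind(x = rnorm(10))), "degenerate")
  # complete separation is flagged, not silently returned
  ys <- c(rep(0, 10), rep(1, 10))
  xs <- c(rep(0, 10), rep(1, 10))
  sep <- fit_logistic(ys, cbind(x = xs))
  expect_false(sep$converged)
})

test_that("score test equals Pearson chi-square on random 2x2 tables", {
  with_seed(29, {
    for (i in 1:50) {
      m <- matrix(rpois(4, 15) + 1, 2,
                  dimnames = list(c("female", "male"), c("yes", "no")))
      rec <- expand_table_records(
        m, "patient_sex", "mental_status_change",
        fixed = list(narrator = "first")
      )
      y <- as.numeric(rec$mental_status_change)
      x <- as.numeric(rec$patient_sex == rownames(m)[1])
      fit <- fit_logistic(y, cbind(x = x))
      chi <- suppressWarnings(pearson_chi2(m))
      expect_equal(fit$score_stat, chi$statistic, tolerance = 1e-10)
      expect_equal(fit$score_p, chi$p, tolerance = 1e-10)
    }
  })
})

test_that("logistic slope converges to the generating log odds ratio", {
  b0 <- -0.4; b1 <- 0.9
  n <- 5000
  slopes <- with_seed(55, replicate(10, {
    x <- rbinom(n, 1, 0.5)
    p <- plogis(b0 + b1 * x)
    y <- rbinom(n, 1, p)
    unname(fit_logistic(y, cbind(x = x))$coefficients["x"])
  }))
  expect_lt(abs(mean(slopes) - b1), 0.05)
})

test_that("expanded records reproduce their source table", {
  m <- matrix(c(2, 2, 2, 2), 2,
              dimnames = list(c("female", "male"), c("yes", "no")))
  rec <- expand_table_records(m, "patient_sex", "headache")
  expect_equal(nrow(rec), 8L)
  back <- crosstab(rec, "patient_sex", "headache")
  expect_equal(unname(back$counts), unname(m))
})

test_that("end-to-end: exact-margins corpus, auto-coded, reproduces its margins", {
  cfg <- corpus_config(n_stroke_stories = 120, n_other_stories = 10,
                       n_nonstory_posts = 10, mode = "exact_margins",
                       seed = 61)
  co <- generate_corpus(cfg)
  coded <- do.call(rbind, lapply(co$text[is_stroke_story(co)], auto_code))
  tab <- crosstab(coded, "narrator", "patient_sex")
  nf <- largest_remainder(120, c(first = cfg$narrator_first_fraction,
                                 third = 1 - cfg$narrator_first_fraction))
  sx <- largest_remainder(120, c(female = cfg$female_fraction,
                                 male = 1 - cfg$female_fraction))
  expect_equal(unname(tab$row_margin), unname(as.numeric(nf)))
  expect_equal(unname(tab$col_margin), unname(as.numeric(sx)))
  ty <- table(coded$stroke_type)
  expect_equal(as.vector(ty[names(cfg$stroke_type_mix)]),
               as.vector(largest_remainder(120, cfg$stroke_type_mix)))
})
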