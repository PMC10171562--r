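# Longitudinal sample container, delimited readers/writers, model archives.

test_that("longitudinal_sample validates its invariants", {
  p <- comp_to_sphere(c(0.2, 0.5, 0.3))
  s <- longitudinal_sample(c("a", "b"),
                           list(c(1, 2), 3),
                           list(rbind(p, p), matrix(p, 1)))
  expect_s3_class(s, "longitudinal_sample")
  expect_equal(n_subjects(s), 2)
  expect_output(print(s), "2 subjects")

  expect_error(longitudinal_sample(c("a", "a"), list(1, 1),
                                   list(matrix(p, 1), matrix(p, 1))),
               "duplicate")
  expect_error(longitudinal_sample("a", list(c(2, 1)), list(rbind(p, p))),
               "sorted")
  expect_error(longitudinal_sample("a", list(1), list(matrix(c(1, 1, 1), 1))),
               "non-unit")
  expect_error(longitudinal_sample("a", list(numeric(0)),
                                   list(matrix(numeric(0), 0, 3))),
               "no observations")
  expect_error(longitudinal_sample("a", list(c(1, 2)), list(matrix(p, 1))),
               "shape mismatch")
})

test_that("subset_subjects keeps data aligned and handles repeats", {
  params <- default_scenario(); params$n_subjects <- c(10, 5); params$seed <- 3L
  s <- generate_sample(params)$sample
  sub <- subset_subjects(s, c(2, 2, 7))
  expect_equal(n_subjects(sub), 3)
  expect_equal(sub$times[[1]], sub$times[[2]])
  expect_equal(sub$obs[[1]], sub$obs[[2]])
  expect_equal(sub$times[[3]], s$times[[7]])
  expect_equal(sub$group[3], s$group[7])
  expect_false(anyDuplicated(sub$ids) > 0)
  expect_error(subset_subjects(s, "nope"), "unknown subject")
})

test_that("reader handles volume mode, unit conversion, and delimiters", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,csf,gm,wm",
               "s1,24,200,700,100",
               "s1,36,150,650,200",
               "s2,30,100,600,300"), f)
  s <- read_longitudinal_table(f, mode = "volumes", unit = "months")
  expect_equal(n_subjects(s), 2)
  expect_equal(s$times[[1]], c(2, 3))
  expect_equal(sphere_to_comp(s$obs[[1]][1, ]), c(0.2, 0.7, 0.1),
               tolerance = 1e-12)

  # tab-delimited with group column, proportions in years
  ft <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tage\tcsf\tgm\twm\tgroup",
               "a\t2.5\t0.2\t0.7\t0.1\tg1",
               "b\t3.5\t0.1\t0.6\t0.3\tg2"), ft)
  st <- read_longitudinal_table(ft)
  expect_equal(st$group, c("g1", "g2"))
  expect_equal(st$times[[2]], 3.5)

  # rows arrive unsorted per subject and get ordered by age
  fu <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,csf,gm,wm",
               "s1,5,0.2,0.7,0.1",
               "s1,2,0.1,0.6,0.3"), fu)
  su <- read_longitudinal_table(fu)
  expect_equal(su$times[[1]], c(2, 5))
  expect_equal(sphere_to_comp(su$obs[[1]][1, ]), c(0.1, 0.6, 0.3),
               tolerance = 1e-12)
})

test_that("reader rejects malformed tables with row-level messages", {
  wr <- function(lines) { f <- tempfile(fileext = ".csv"); writeLines(lines, f); f }
  hdr <- "subject_id,age,csf,gm,wm"
  expect_error(read_longitudinal_table(wr(c("subject_id,age,csf,gm",
                                            "s1,2,0.2,0.8"))),
               "missing required column")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,2,0.2,0.7,0.1",
                                            "s1,3,0.3,0.3,0.2"))),
               "sum to 1.*row\\(s\\) 2")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,2,-0.1,0.8,0.3"))),
               "negative tissue value.*row\\(s\\) 1")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,-2,0.2,0.7,0.1"))),
               "non-positive age")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,2,NA,0.7,0.1"))),
               "non-finite tissue")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,2,0,0,0")),
                                       mode = "volumes"),
               "zero row total")
  expect_error(read_longitudinal_table(wr(c(hdr, "s1,2,0.2,0.7,0.1",
                                            "s1,2,0.2,0.7,0.1"))),
               "duplicate \\(subject, age\\)")
  expect_error(read_longitudinal_table(wr(c(paste0(hdr, ",group"),
                                            "s1,2,0.2,0.7,0.1,g1",
                                            "s1,3,0.2,0.7,0.1,g2"))),
               "inconsistent group")
  expect_error(read_longitudinal_table(tempfile()), "cannot read")
})

test_that("write-then-read round trip reproduces a generated cohort", {
  params <- default_scenario(); params$n_subjects <- c(15, 10); params$seed <- 9L
  s <- generate_sample(params)$sample
  f <- tempfile(fileext = ".csv")
  write_longitudinal_table(s, f)
  s2 <- read_longitudinal_table(f)
  expect_identical(s2$ids, s$ids)
  expect_identical(s2$group, s$group)
  for (i in seq_along(s$ids)) {
    expect_equal(s2$times[[i]], s$times[[i]], tolerance = 1e-15)
    expect_equal(s2$obs[[i]], s$obs[[i]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("model archive round-trips bit-exactly", {
  params <- default_scenario(); params$n_subjects <- c(40, 20); params$seed <- 11L
  # small cohort: sigma2 may clip to 0, so score systems are ridge-stabilized
  fit <- suppressWarnings(fit_rfpca(generate_sample(params)$sample))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  rfpca_save(fit, f1)
  fit2 <- rfpca_load(f1)
  rfpca_save(fit2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(fit2$grid, fit$grid)
  expect_identical(unname(fit2$mu), unname(fit$mu))
  expect_identical(fit2$Gamma, fit$Gamma)
  expect_identical(fit2$lambda, fit$lambda)
  expect_identical(unname(fit2$phi), unname(fit$phi))
  expect_identical(fit2$sigma2, fit$sigma2)
  expect_identical(fit2$K, as.integer(fit$K))
  expect_identical(unname(fit2$scores), unname(as.matrix(fit$scores)))
  expect_identical(fit2$ids, fit$ids)
  expect_identical(fit2$pool$obs, unname(fit$pool$obs))

  # loaded model predicts identically to the in-memory one
  tt <- c(3, 5); Y <- fit$pool$obs[1:2, ]
  expect_identical(suppressWarnings(conditional_scores(fit2, tt, Y)),
                   suppressWarnings(conditional_scores(fit, tt, Y)))
  expect_error(rfpca_load(f <- {
    g <- tempfile(); writeLines('{"format":"other"}', g); g
  }), "not a comptraj model archive")
})

test_that("JSON reports are parseable and strip non-serializable members", {
  f <- tempfile(fileext = ".json")
  write_report_json(list(p_value = 0.0123, stat = 1.5,
                         fn = function(x) x, note = "ok"), f)
  rep <- jsonlite::fromJSON(readLines(f))
  expect_equal(rep$p_value, 0.0123)
  expect_null(rep$fn)
  expect_equal(rep$note, "ok")
})
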