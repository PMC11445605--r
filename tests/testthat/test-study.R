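make_measurements <- function(plates, plate_id = "p1") {
  purrr::imap(plates, function(plate, i) {
    dplyr::mutate(plate, plate_id = plate_id,
                  observer_id = sprintf("obs%02d", as.integer(i)),
                  chromosome_index = dplyr::row_number())
  }) |>
    dplyr::bind_rows()
}

test_that("build_study_table yields one row per observer for one plate", {
  m <- make_measurements(list(`1` = toy_mixed, `2` = toy_asym,
                              `3` = toy_symmetric))
  study <- build_study_table(m)
  expect_s3_class(study, "observer_study")
  expect_equal(nrow(study), 3)
  expect_equal(study$THL, c(8, 10, 8))
  expect_equal(glance(study)$n_observers, 3)
  expect_equal(glance(study)$plate_id, "p1")

  # identical measurements give identical rows
  m2 <- make_measurements(list(`1` = toy_asym, `2` = toy_asym))
  study2 <- build_study_table(m2)
  expect_equal(dplyr::select(tibble::as_tibble(study2), -"observer_id")[1, ],
               dplyr::select(tibble::as_tibble(study2), -"observer_id")[2, ])
})

test_that("build_study_table rejects mixed plates and duplicate keys", {
  m <- make_measurements(list(`1` = toy_mixed))
  other <- dplyr::mutate(make_measurements(list(`1` = toy_asym)),
                         plate_id = "p2", observer_id = "obs99")
  expect_error(build_study_table(dplyr::bind_rows(m, other)), "one plate")

  dup <- dplyr::bind_rows(m, m)   # same observer, same chromosome indices
  expect_error(build_study_table(dup), "Duplicated chromosome_index")
})

test_that("observers with invalid rows are excluded with a warning", {
  bad <- dplyr::mutate(make_measurements(list(`1` = toy_mixed)),
                       observer_id = "bad",
                       long_arm = replace(long_arm, 1, NA_real_))
  good <- make_measurements(list(`1` = toy_asym, `2` = toy_symmetric))
  expect_warning(study <- build_study_table(dplyr::bind_rows(good, bad)),
                 "Excluding observer")
  expect_equal(nrow(study), 2)
  expect_false("bad" %in% study$observer_id)
})

test_that("trait_cv matches hand arithmetic and flags degenerate traits", {
  tab <- tibble::tibble(
    observer_id = c("a", "b", "c"),
    THL = c(8, 10, 12), M_CA = c(40, 41, 42),
    CV_CL = c(20, 20, 20), CV_CI = c(15, 18, 21)
  )
  disp <- trait_cv(tab)
  expect_s3_class(disp, "trait_dispersion")
  thl <- disp[disp$trait == "THL", ]
  expect_equal(thl$mean, 10)
  expect_equal(thl$sd, 2)
  expect_equal(thl$cv, 20)
  expect_equal(thl$median, 10)
  expect_equal(c(thl$min, thl$q1, thl$q3, thl$max), c(8, 9, 11, 12))
  expect_equal(thl$values[[1]], c(8, 10, 12))
  # identical values: zero dispersion, CV exactly 0
  expect_equal(disp$cv[disp$trait == "CV_CL"], 0)
  # quartiles are the linear-interpolation (type 7) quantiles
  expect_equal(disp$q1[disp$trait == "CV_CI"],
               unname(quantile(c(15, 18, 21), 0.25, type = 7)))

  expect_error(trait_cv(tab[1, ]), "At least 2")
  tab0 <- dplyr::mutate(tab, M_CA = c(-1, 0, 1))
  expect_error(trait_cv(tab0), "zero mean")
  expect_error(trait_cv(dplyr::select(tab, -"CV_CI")), "not found")
})

test_that("trait_cv is invariant to observer order and to trait rescaling", {
  withr::local_seed(11)
  tab <- tibble::tibble(
    observer_id = sprintf("o%d", 1:10),
    THL = runif(10, 30, 45), M_CA = runif(10, 20, 35),
    CV_CL = runif(10, 15, 30), CV_CI = runif(10, 10, 25)
  )
  shuffled <- tab[sample(10), ]
  expect_equal(dplyr::select(tibble::as_tibble(trait_cv(shuffled)), -"values"),
               dplyr::select(tibble::as_tibble(trait_cv(tab)), -"values"),
               tolerance = 1e-12)
  rescaled <- dplyr::mutate(tab, THL = THL * 7.3)
  expect_equal(trait_cv(rescaled)$cv[1], trait_cv(tab)$cv[1],
               tolerance = 1e-12)
})

test_that("pearson_matrix reproduces textbook cases", {
  tab <- tibble::tibble(
    observer_id = c("a", "b", "c"),
    THL = c(1, 2, 3), M_CA = c(2, 4, 6),
    CV_CL = c(6, 4, 2), CV_CI = c(1, 2, 2.5)
  )
  cm <- pearson_matrix(tab)
  expect_equal(cm$r["THL", "M_CA"], 1)
  expect_equal(cm$r["THL", "CV_CL"], -1)
  expect_equal(cm$p["THL", "M_CA"], 0)

  # hand covariance arithmetic: cov-sum 4 over sqrt(5 * 5)
  tab4 <- tibble::tibble(
    observer_id = letters[1:4],
    THL = c(1, 2, 3, 4), M_CA = c(1, 3, 2, 4),
    CV_CL = c(2, 1, 4, 3), CV_CI = c(5, 2, 8, 3)
  )
  cm4 <- pearson_matrix(tab4)
  expect_equal(cm4$r["THL", "M_CA"], 0.8, tolerance = 1e-12)
})

test_that("pearson_matrix is symmetric, bounded and matches cor.test", {
  withr::local_seed(22)
  tab <- tibble::tibble(
    observer_id = sprintf("o%d", 1:15),
    THL = runif(15, 30, 45), M_CA = runif(15, 20, 35),
    CV_CL = runif(15, 15, 30), CV_CI = runif(15, 10, 25)
  )
  cm <- pearson_matrix(tab)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$p, t(cm$p))
  expect_true(all(abs(cm$r) <= 1))
  expect_true(all(diag(cm$r) == 1))
  expect_true(all(is.na(diag(cm$p))))
  ct <- stats::cor.test(tab$THL, tab$M_CA)
  expect_equal(cm$r["THL", "M_CA"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["THL", "M_CA"], ct$p.value, tolerance = 1e-12)

  # Bonferroni flag multiplies p by the 6 distinct pairs (capped at 1)
  cmb <- pearson_matrix(tab, bonferroni = TRUE)
  expect_equal(cmb$p["THL", "M_CA"],
               min(1, cm$p["THL", "M_CA"] * 6), tolerance = 1e-12)
})

test_that("pearson_matrix rejects too-few observers and constant traits", {
  tab <- tibble::tibble(observer_id = c("a", "b"),
                        THL = c(1, 2), M_CA = c(2, 1),
                        CV_CL = c(1, 3), CV_CI = c(2, 4))
  expect_error(pearson_matrix(tab), "At least 3")
  tab3 <- tibble::tibble(observer_id = c("a", "b", "c"),
                         THL = c(1, 2, 3), M_CA = c(5, 5, 5),
                         CV_CL = c(1, 3, 2), CV_CI = c(2, 4, 1))
  expect_error(pearson_matrix(tab3), "M_CA")
})

test_that("p values fall monotonically in |r| at fixed n", {
  n <- 15
  r_grid <- seq(0.05, 0.95, by = 0.1)
  p_of_r <- function(r) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  # construct vectors with exactly the requested correlation via rotation
  withr::local_seed(33)
  x <- rnorm(n); e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  ps <- purrr::map_dbl(r_grid, function(r) {
    y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    oracle_pearson(x, y)$p
  })
  expect_true(all(diff(ps) < 0))
  expect_equal(ps, purrr::map_dbl(r_grid, p_of_r), tolerance = 1e-9)
})

test_that("pearson_matrix agrees with the direct-formula oracle on random tables", {
  withr::local_seed(44)
  for (i in 1:100) {
    tab <- tibble::tibble(
      observer_id = sprintf("o%d", 1:15),
      THL = rnorm(15, 40, 4), M_CA = rnorm(15, 28, 3),
      CV_CL = rnorm(15, 22, 2), CV_CI = rnorm(15, 16, 2)
    )
    cm <- pearson_matrix(tab)
    for (pair in list(c("THL", "M_CA"), c("THL", "CV_CI"),
                      c("CV_CL", "CV_CI"))) {
      o <- oracle_pearson(tab[[pair[1]]], tab[[pair[2]]])
      expect_equal(cm$r[pair[1], pair[2]], o$r, tolerance = 1e-12)
      expect_equal(cm$p[pair[1], pair[2]], o$p, tolerance = 1e-12)
    }
  }
})

test_that("tidy and glance summarise the correlation object", {
  m <- make_measurements(list(`1` = toy_mixed, `2` = toy_asym,
                              `3` = toy_symmetric, `4` = rand_plate(4)))
  study <- build_study_table(m)
  cm <- pearson_matrix(study)
  td <- tidy(cm)
  expect_equal(nrow(td), 6)
  expect_named(td, c("trait_x", "trait_y", "r", "p", "significance"))
  expect_true(all(td$significance %in%
                    c("highly significant", "marginally significant",
                      "not significant")))
  gl <- glance(cm)
  expect_equal(gl$n_observers, 4)
  expect_equal(gl$n_pairs, 6)
})

test_that("scatter_export returns flagged per-observer pairs with r attached", {
  m <- make_measurements(list(`1` = toy_mixed, `2` = toy_asym,
                              `3` = toy_symmetric))
  study <- build_study_table(m)
  sc <- scatter_export(study, "THL", "M_CA", highlight = "obs02")
  expect_equal(nrow(sc), 3)
  expect_equal(sc$x, study$THL)
  expect_equal(sc$y, study$M_CA)
  expect_equal(sc$highlighted, c(FALSE, TRUE, FALSE))
  expect_equal(attr(sc, "r"),
               oracle_pearson(study$THL, study$M_CA)$r, tolerance = 1e-12)

  # no highlight: no flags; unknown trait or id are surfaced
  expect_false(any(scatter_export(study)$highlighted))
  expect_error(scatter_export(study, "THL", "nope"), "not found")
  expect_warning(scatter_export(study, highlight = "ghost"), "ghost")
})

test_that("study results survive a CSV round trip unchanged", {
  withr::local_seed(55)
  m <- make_measurements(list(`1` = rand_plate(9), `2` = rand_plate(9),
                              `3` = rand_plate(9), `4` = rand_plate(9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  m2 <- read_measurements(path)
  study1 <- build_study_table(m)
  study2 <- build_study_table(m2)
  expect_equal(tibble::as_tibble(study2), tibble::as_tibble(study1),
               tolerance = 1e-15)
  cm1 <- pearson_matrix(study1); cm2 <- pearson_matrix(study2)
  expect_equal(cm2$r, cm1$r)
  expect_equal(cm2$p, cm1$p)
})
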