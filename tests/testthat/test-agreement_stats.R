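test_that("coincidence matrix matches hand-enumerated pair counts", {
  perfect <- tibble::tibble(patient_id = c(1, 1, 2, 2),
                            reader_id = c("a", "b", "a", "b"),
                            score = c(1, 1, 2, 2))
  o <- coincidence_matrix(perfect)
  expect_equal(unclass(o)[, ], matrix(c(2, 0, 0, 2), 2, 2,
                                      dimnames = list(1:2, 1:2)))
  expect_equal(attr(o, "n_pairable"), 4)

  disagree <- tibble::tibble(patient_id = c(1, 1), reader_id = c("a", "b"),
                             score = c(1, 2))
  o2 <- coincidence_matrix(disagree)
  expect_equal(o2["1", "2"], 1)
  expect_equal(o2["2", "1"], 1)
  expect_equal(o2["1", "1"], 0)

  # 3 raters, one unit, ratings (1,1,2): 6 ordered pairs over m_u - 1 = 2
  trio <- tibble::tibble(patient_id = 1, reader_id = c("a", "b", "c"),
                         score = c(1, 1, 2))
  o3 <- coincidence_matrix(trio)
  expect_equal(o3["1", "1"], 1)
  expect_equal(o3["1", "2"], 1)
  expect_equal(o3["2", "1"], 1)
  expect_equal(o3["2", "2"], 0)
})

test_that("units with fewer than two ratings are excluded; none pairable errors", {
  df <- tibble::tibble(patient_id = c(1, 1, 2), reader_id = c("a", "b", "a"),
                       score = c(1, 2, 3))
  o <- coincidence_matrix(df)
  expect_equal(attr(o, "n_pairable"), 2)
  solo <- tibble::tibble(patient_id = 1:3, reader_id = "a", score = 1:3)
  expect_error(coincidence_matrix(solo), "pairable")
})

test_that("perfect agreement across distinct values yields alpha 1", {
  df <- tibble::tibble(patient_id = rep(1:3, each = 2),
                       reader_id = rep(c("a", "b"), 3),
                       score = rep(1:3, each = 2))
  expect_equal(krippendorff_alpha(df, metric = "nominal")$alpha, 1)
  expect_equal(krippendorff_alpha(df, metric = "ordinal")$alpha, 1)
})

test_that("degenerate all-identical ratings raise an explicit error", {
  df <- tibble::tibble(patient_id = rep(1:3, each = 2),
                       reader_id = rep(c("a", "b"), 3), score = 2)
  expect_error(krippendorff_alpha(df), "degenerate")
})

test_that("single disagreeing pair reproduces the hand-worked small-sample alpha", {
  # unit (1,2), nominal: D_o = 1, D_e = 2*1*1/(2*1) = 1, alpha = 0
  df <- tibble::tibble(patient_id = 1, reader_id = c("a", "b"), score = 1:2)
  expect_equal(krippendorff_alpha(df, metric = "nominal")$alpha, 0)
})

test_that("alpha equals the brute-force pairwise oracle on random matrices", {
  withr::local_seed(424242)
  for (i in 1:300) {
    df <- random_ratings(sample(2:4, 1), sample(2:6, 1), sample(2:3, 1))
    for (metric in c("nominal", "ordinal")) {
      got <- try(krippendorff_alpha(df, metric = metric)$alpha, silent = TRUE)
      want <- try(oracle_alpha(df, metric), silent = TRUE)
      if (inherits(want, "try-error")) {
        expect_s3_class(got, "try-error")
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("alpha is invariant to relabeling raters and units", {
  withr::local_seed(99)
  df <- random_ratings(4, 6, 3)
  base <- krippendorff_alpha(df, metric = "ordinal")$alpha
  shuf <- df
  shuf$reader_id <- match(df$reader_id, sample(unique(df$reader_id)))
  shuf$patient_id <- match(df$patient_id, sample(unique(df$patient_id)))
  expect_equal(krippendorff_alpha(shuf, metric = "ordinal")$alpha, base,
               tolerance = 1e-12)
})

test_that("nominal and ordinal alpha coincide on binary ratings", {
  withr::local_seed(7)
  for (i in 1:20) {
    df <- random_ratings(3, 6, 2)
    expect_equal(krippendorff_alpha(df, metric = "nominal")$alpha,
                 krippendorff_alpha(df, metric = "ordinal")$alpha,
                 tolerance = 1e-12)
  }
})

test_that("an all-missing rater never changes alpha", {
  withr::local_seed(15)
  df <- random_ratings(3, 6, 3)
  base <- krippendorff_alpha(df)$alpha
  extra <- rbind(df, tibble::tibble(patient_id = unique(df$patient_id),
                                    reader_id = 99, score = NA))
  expect_equal(krippendorff_alpha(extra)$alpha, base, tolerance = 1e-15)
})

test_that("bootstrap interval is seeded, reproducible, and tight under perfection", {
  perfect <- tibble::tibble(patient_id = rep(1:5, each = 2),
                            reader_id = rep(c("a", "b"), 5),
                            score = rep(c(1, 2, 3, 1, 2), each = 2))
  ci <- alpha_bootstrap_ci(perfect, metric = "nominal", n_boot = 200,
                           seed = 4)
  expect_equal(unname(ci[1:2]), c(1, 1))
  withr::local_seed(10)
  df <- random_ratings(3, 8, 3)
  ci1 <- alpha_bootstrap_ci(df, n_boot = 200, seed = 42)
  ci2 <- alpha_bootstrap_ci(df, n_boot = 200, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], krippendorff_alpha(df)$alpha)
  expect_error(alpha_bootstrap_ci(df, n_boot = 50), "at least 100")
})

test_that("agreement table mirrors the method-by-stratum layout", {
  study <- tiny_study(seed = 3)
  tab <- agreement_table(study$scores, study$panel,
                         assessments = study$assessments)
  expect_setequal(unique(tab$stratum), c("all", "expert", "nonexpert"))
  expect_setequal(
    unique(tab$item),
    c("five_point", "four_point", "two_point", "mrf_obvious", "t_high_risk",
      "nodal_obvious", "emvi_obvious"))
  expect_equal(nrow(tab), 7 * 3)
  expect_equal(unique(tab$metric[tab$item == "five_point"]), "ordinal")
  expect_equal(unique(tab$metric[tab$item == "two_point"]), "nominal")
  expect_true(all(tab$alpha <= 1))

  # noiseless channel: every cell is exactly 1
  noiseless <- tiny_study(seed = 3, feature_error = zero_error)
  tab0 <- agreement_table(noiseless$scores, noiseless$panel)
  expect_true(all(tab0$alpha == 1))

  # missing stratum: column omitted with a warning
  solo <- tiny_study(seed = 5, n_expert = 0, n_nonexpert = 3)
  expect_warning(tab1 <- agreement_table(solo$scores, solo$panel),
                 "no readers in stratum 'expert'")
  expect_setequal(unique(tab1$stratum), c("all", "nonexpert"))
})

test_that("experts dominate when non-experts rate pure noise", {
  withr::local_seed(31)
  n_pat <- 40
  expert_scores <- tidyr::expand_grid(patient_id = seq_len(n_pat),
                                      reader_id = c("E1", "E2"))
  expert_scores$score <- rep(sample(1:5, n_pat, replace = TRUE), each = 2)
  noise <- tidyr::expand_grid(patient_id = seq_len(n_pat),
                              reader_id = c("N1", "N2"))
  noise$score <- sample(1:5, nrow(noise), replace = TRUE)
  scores <- rbind(expert_scores, noise)
  scores$method <- "five_point"
  panel <- tibble::tibble(reader_id = c("E1", "E2", "N1", "N2"),
                          stratum = c("expert", "expert", "nonexpert",
                                      "nonexpert"))
  tab <- agreement_table(scores, panel)
  expect_equal(tab$alpha[tab$stratum == "expert"], 1)
  expect_lt(abs(tab$alpha[tab$stratum == "nonexpert"]), 0.35)
})
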