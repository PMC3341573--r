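test_that("generative models validate and renormalize their prevalence simplex", {
  dz <- toy_disease_table(c("a", "b"), c(30, 60), c("C", "notC"))
  probs <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("a", "b"), "f"))
  m <- generative_model(dz, probs)
  expect_equal(sum(m$diseases$prevalence), 1, tolerance = 1e-9)
  expect_equal(m$diseases$prevalence, c(1 / 3, 2 / 3), tolerance = 1e-12)

  expect_error(generative_model(dz, matrix(0.5, 1, 1,
                                           dimnames = list("a", "f"))),
               "missing disease")
  bad <- probs; bad[1] <- 1.2
  expect_error(generative_model(dz, bad), "\\[0, 1\\]")
})

test_that("generative models round trip through JSON", {
  m <- random_model(5, 3, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_generative_model(m, tmp)
  back <- read_generative_model(tmp)
  expect_equal(back$probs, m$probs, tolerance = 1e-12)
  expect_equal(back$diseases$prevalence, m$diseases$prevalence, tolerance = 1e-12)
  expect_equal(back$finding_ids, m$finding_ids)
})

test_that("cohort simulation is reproducible, seed-scoped and respects edge cases", {
  m <- homogeneous_model(p_in = c(0.9, 0.3), p_out = c(0.2, 0.7))
  expect_equal(nrow(simulate_cohort(m, 0, seed = 1)), 0)
  expect_error(simulate_cohort(m, -1, seed = 1), "non-negative")

  a <- simulate_cohort(m, 500, seed = 42)
  b <- simulate_cohort(m, 500, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_cohort(m, 500, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))

  # the caller's RNG stream is not consumed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(m, 100, seed = 1)); after <- runif(1)
  expect_identical(before, after)

  # degenerate prevalence: every patient carries the only disease
  dz <- toy_disease_table(c("only", "never"), c(100, 0), c("C", "notC"))
  probs <- matrix(0.5, 2, 1, dimnames = list(c("only", "never"), "f"))
  mono <- generative_model(dz, probs)
  co <- simulate_cohort(mono, 200, seed = 7)
  expect_true(all(co$disease_id == "only"))
})

test_that("simulated disease frequencies fall in their exact 99% binomial intervals", {
  m <- random_model(6, 1, seed = 5)
  n <- 10000
  co <- simulate_cohort(m, n, seed = 11)
  counts <- table(factor(co$disease_id, levels = m$diseases$disease_id))
  for (i in seq_len(nrow(m$diseases))) {
    p <- m$diseases$prevalence[i]
    expect_gte(counts[[i]], qbinom(0.005, n, p))
    expect_lte(counts[[i]], qbinom(0.995, n, p))
  }
})

test_that("cohorts round trip to CSV", {
  m <- homogeneous_model(p_in = 0.9, p_out = 0.2)
  co <- simulate_cohort(m, 50, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$disease_id, co$disease_id)
  expect_equal(back$f1, co$f1)
})

test_that("category accuracy estimates match a hand-tallied 2x2 table", {
  dz <- toy_disease_table(c("c1", "x1"), c(40, 60), c("C", "notC"))
  # ten listed patients: 4 members (3 finding-positive), 6 non-members (2 positive)
  cohort <- structure(
    data.frame(
      disease_id = c("c1", "c1", "c1", "c1", "x1", "x1", "x1", "x1", "x1", "x1"),
      f = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L),
      stringsAsFactors = FALSE),
    class = c("cohort", "data.frame"), diseases = dz)
  est <- estimate_category_accuracy(cohort, "f", "C")
  expect_equal(est$sensitivity$point, 3 / 4)
  expect_equal(est$sensitivity$n_pos, 3L)
  expect_equal(est$specificity$point, 4 / 6)
  expect_equal(est$specificity$n_neg, 2L)
  expect_lte(est$sensitivity$ci_low, est$sensitivity$point)
  expect_gte(est$sensitivity$ci_high, est$sensitivity$point)

  emp <- empirical_category_lr(cohort, "f", "C")
  expect_equal(emp$lr_pos, (3 / 4) / (2 / 6))
  expect_equal(emp$lr_neg, (1 / 4) / (4 / 6))

  mono <- structure(
    data.frame(disease_id = rep("c1", 3), f = c(1L, 1L, 0L),
               stringsAsFactors = FALSE),
    class = c("cohort", "data.frame"), diseases = dz)
  expect_error(estimate_category_accuracy(mono, "f", "C"),
               "both members and non-members")
})

test_that("a perfectly separating finding estimates (1, 1)", {
  m <- homogeneous_model(p_in = 1, p_out = 0)
  co <- simulate_cohort(m, 300, seed = 2)
  est <- estimate_category_accuracy(co, "f1", "C")
  expect_equal(est$sensitivity$point, 1)
  expect_equal(est$specificity$point, 1)
})

test_that("estimates are consistent under the generative model at n = 200,000", {
  m <- homogeneous_model(p_in = 0.9, p_out = 0.2)
  co <- simulate_cohort(m, 200000, seed = 8)
  est <- estimate_category_accuracy(co, "f1", "C")
  half <- function(e) (e$ci_high - e$ci_low) / 2
  expect_lte(abs(est$sensitivity$point - 0.9), 3 * half(est$sensitivity))
  expect_lte(abs(est$specificity$point - 0.8), 3 * half(est$specificity))
})

test_that("wilson intervals behave at the boundaries", {
  w <- wilson_ci(8, 10)
  expect_equal(w$point, 0.8)
  expect_true(w$ci_low < 0.8 && w$ci_high > 0.8)
  w0 <- wilson_ci(0, 20)
  expect_equal(w0$ci_low, 0)
  expect_gt(w0$ci_high, 0)
  w1 <- wilson_ci(20, 20)
  expect_equal(w1$ci_high, 1)
  expect_lt(w1$ci_low, 1)
})

test_that("the enumeration oracle matches an independent joint-table summation", {
  m <- random_model(5, 3, seed = 9)
  prof <- patient_profile(c(f1 = "present", f2 = "absent", f3 = "unknown"))
  got <- exact_posterior(m, prof)
  want <- joint_table_posterior(m, prof)
  expect_equal(got$disease, want, tolerance = 1e-12)
  expect_equal(sum(got$disease), 1, tolerance = 1e-9)
  # category posteriors are the sums of their members'
  for (path in names(got$categories)) {
    expect_equal(got$categories[[path]],
                 sum(got$disease[category_members(m$diseases, path)]),
                 tolerance = 1e-12)
  }
})

test_that("the oracle handles empty and uninformative evidence", {
  m <- random_model(5, 2, seed = 4)
  empty <- patient_profile(c(f1 = "unknown"))
  post <- exact_posterior(m, empty)
  expect_equal(unname(post$disease), m$diseases$prevalence, tolerance = 1e-12)

  # a finding with identical probability in every disease changes nothing
  dz <- toy_disease_table(c("a", "b", "c"), c(20, 30, 50), c("C", "C", "notC"))
  probs <- matrix(0.4, 3, 1, dimnames = list(c("a", "b", "c"), "f"))
  flat <- generative_model(dz, probs)
  post2 <- exact_posterior(flat, patient_profile(c(f = "present")))
  expect_equal(unname(post2$disease), flat$diseases$prevalence, tolerance = 1e-12)

  # impossible evidence errors
  sure <- generative_model(dz, matrix(c(1, 1, 1), 3, 1,
                                      dimnames = list(c("a", "b", "c"), "f")))
  expect_error(exact_posterior(sure, patient_profile(c(f = "absent"))),
               "probability zero")
  expect_error(exact_posterior(m, patient_profile(c(nope = "present"))),
               "not in model")
})

test_that("naive sequential updating agrees with the oracle where it must", {
  rm <- random_model(6, 3, seed = 12)
  single <- patient_profile(c(f2 = "present"))
  expect_lt(naive_vs_exact(rm, single, "C")$abs_diff, 1e-10)

  hom <- homogeneous_model(p_in = c(0.9, 0.3, 0.6), p_out = c(0.2, 0.7, 0.5))
  multi <- patient_profile(c(f1 = "present", f2 = "absent", f3 = "present"))
  expect_lt(naive_vs_exact(hom, multi, "C")$abs_diff, 1e-10)

  # heterogeneous member probabilities break exactness; the discrepancy is
  # reported, not hidden
  dz <- toy_disease_table(c("a", "b", "x"), c(10, 10, 80), c("C", "C", "notC"))
  probs <- matrix(c(0.9, 0.3, 0.5,
                    0.9, 0.3, 0.5), 3, 2,
                  dimnames = list(c("a", "b", "x"), c("f1", "f2")))
  het <- generative_model(dz, probs)
  rep_ <- naive_vs_exact(het, patient_profile(c(f1 = "present", f2 = "present")),
                         "C")
  expect_gt(rep_$abs_diff, 1e-6)
  expect_equal(rep_$exact_posterior,
               joint_table_category_posterior(
                 het, patient_profile(c(f1 = "present", f2 = "present")), "C"),
               tolerance = 1e-12)
})

test_that("the demonstration abdominal model reproduces its source category LRs", {
  m <- demo_abdominal_model()
  tab <- read_accuracy_table(catlr_example("accuracy_abdominal_organic.csv"),
                             target = "organic")
  for (i in seq_len(nrow(tab))) {
    pair <- category_lr(m, "organic", tab$finding_id[i])
    expect_equal(pair$lr_pos, tab$lr_pos[i], tolerance = 1e-6)
    expect_equal(pair$lr_neg, tab$lr_neg[i], tolerance = 1e-6)
  }
  het <- demo_abdominal_model(heterogeneity = 0.5)
  expect_gt(stats::sd(het$probs[m$diseases$category_path != "non-organic", 1]), 0)
})
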