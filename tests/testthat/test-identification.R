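hyp_sm <- build_system_matrix(adhd_depression_model("hypothesized"))

test_that("order condition reproduces the survey's exclusion counts", {
  oc <- order_condition(hyp_sm)
  expect_identical(oc$K[oc$equation == "adhd"], 12L)
  expect_identical(oc$K[oc$equation == "depression"], 3L)
  expect_true(all(oc$satisfied))
  expect_identical(unique(oc$M), 2L)

  # K = 1 against a 3-member loop fails the counting rule
  m3 <- matrix(1L, 3, 4, dimnames = list(paste0("y", 1:3),
                                         c("x1", paste0("y", 1:3))))
  m3[1, "x1"] <- 0L
  expect_false(order_condition(m3)$satisfied[1])
})

test_that("rank condition reproduces the printed reduction", {
  rk <- rank_condition(hyp_sm)
  expect_identical(rk$rank, c(1L, 1L))
  expect_true(all(rk$identified))
  expect_true(attr(rk, "model_identified"))
})

test_that("rank condition agrees with the rational-rank oracle on random systems", {
  set.seed(7)
  for (rep in 1:300) {
    sm <- random_system_matrix(sample(2:6, 1), sample(2:6, 1))
    rk <- rank_condition(sm)
    oc <- order_condition(sm)
    for (i in seq_len(nrow(sm))) {
      red <- sm[-i, sm[i, ] == 0, drop = FALSE]
      red <- red[rowSums(red != 0) > 0, , drop = FALSE]
      oracle <- if (nrow(red)) qr(red)$rank else 0L
      expect_identical(rk$rank[i], as.integer(oracle))
    }
    # rank identification implies the order condition (necessary vs sufficient)
    expect_true(all(oc$satisfied[rk$identified]))
  }
})

test_that("instrument designation matches the survey's assignment", {
  m <- adhd_depression_model("hypothesized")
  ins <- designate_instruments(m)
  expect_setequal(ins$instruments[[which(ins$member == "adhd")]],
                  c("mother_education", "father_education", "birth_order"))
  dep <- ins$instruments[[which(ins$member == "depression")]]
  expect_identical(length(dep), 12L)
  expect_true(all(c("worry_academic", "stressful_life_event", "social_support",
                    "piu", "insomnia") %in% dep))
  expect_false(any(ins$flagged))

  # every exogenous variable hitting both members leaves no instruments
  toy <- loop_toy_model()
  toy$paths <- dplyr::bind_rows(
    toy$paths,
    tibble::tibble(source = c("z1", "z2"), target = c("e2", "e1"),
                   kind = "structural", fixed = FALSE, value = NA_real_)
  )
  ins2 <- designate_instruments(toy)
  expect_true(all(ins2$flagged))
  expect_error(designate_instruments(two_factor_model()), "loop")
})

test_that("free-parameter count reproduces the survey's worked arithmetic", {
  m <- adhd_depression_model("hypothesized")
  pc <- count_free_parameters(m)
  expect_identical(pc$total, 147L)
  expect_identical(pc$loadings_free, 29L)
  expect_identical(pc$indicator_error_variances, 34L)
  expect_identical(pc$structural_paths, 45L)
  expect_identical(pc$exogenous_variances, 29L)
  expect_identical(pc$disturbance_variances, 2L)
  expect_identical(pc$covariances, 8L)

  pg <- parameter_groups(m)
  lookup <- stats::setNames(pg$count, pg$group)
  expect_identical(unname(lookup[c("measurement", "adhd_specific",
                                   "depression_specific", "common_predictors",
                                   "feedback_loop", "error_covariances")]),
                   c(63L, 6L, 24L, 42L, 5L, 7L))
  expect_identical(attr(pg, "total"), 147L)
})

test_that("parameter counting is additive and path-local", {
  m <- one_factor_model(3)
  expect_identical(count_free_parameters(m)$total, 6L)  # 2 loadings + 3 errors + 1 variance

  # removing one free path decrements the total by exactly one
  big <- adhd_depression_model("hypothesized")
  drop <- which(big$paths$kind == "structural" & big$paths$source == "age")[1]
  big2 <- big
  big2$paths <- big2$paths[-drop, ]
  expect_identical(count_free_parameters(big2)$total, 146L)

  # disjoint unions add their totals
  a <- one_factor_model(3, name = "fa", items = paste0("a", 1:3))
  b <- one_factor_model(4, name = "fb", items = paste0("b", 1:4))
  ab <- sem_model(dplyr::bind_rows(a$variables, b$variables),
                  dplyr::bind_rows(a$paths, b$paths))
  expect_identical(count_free_parameters(ab)$total,
                   count_free_parameters(a)$total + count_free_parameters(b)$total)
})

test_that("N:q sample-size planning matches the survey's arithmetic", {
  s <- required_sample_size(147, ratio = 10, nonresponse = 0.05)
  expect_identical(s$base_n, 1470)
  expect_identical(s$final_n, 1544)
  expect_true(is.na(s$warning))

  expect_identical(required_sample_size(100, 5, 0)$final_n, 500)
  expect_identical(required_sample_size(147, 20, 0.05)$final_n, 3087)
  expect_false(is.na(required_sample_size(147, 25, 0)$warning))
  expect_error(required_sample_size(147, 10, 0.6), "nonresponse")

  # the tibble from count_free_parameters slots straight in
  expect_identical(
    required_sample_size(count_free_parameters(adhd_depression_model("hypothesized")))$final_n,
    1544)
})
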