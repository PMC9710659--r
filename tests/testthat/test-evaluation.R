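test_that("macro metrics handle perfect, inverted and mixed predictions", {
  perfect <- macro_prf(c(0, 1, 2, 0), c(0, 1, 2, 0), scheme = "alpha-beta-other")
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
  expect_equal(perfect$macro_f1, 1)

  inverted <- macro_prf(c(0, 0, 1, 1), c(1, 1, 0, 0), scheme = "alpha-other")
  expect_equal(inverted$macro_f1, 0)

  # hand-computed confusion matrix: P = 13/18, R = 2/3
  mixed <- macro_prf(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 2, 2, 2), scheme = "alpha-beta-other")
  expect_equal(mixed$macro_precision, 13 / 18)
  expect_equal(mixed$macro_recall, 2 / 3)
  expect_equal(mixed$macro_f1, 2 * (13 / 18) * (2 / 3) / (13 / 18 + 2 / 3), tolerance = 1e-9)
  expect_equal(round(mixed$macro_f1, 4), 0.6933)

  expect_error(macro_prf(c(0, 1), c(0, 1, 2), scheme = "alpha-beta-other"),
    class = "geosec_validation_error"
  )
})

test_that("macro metrics include classes absent from the sample", {
  # class 1 never occurs: its P and R count as 0 in the macro average
  rep <- macro_prf(c(0, 0, 2, 2), c(0, 0, 2, 2), scheme = "alpha-beta-other")
  expect_equal(rep$macro_precision, 2 / 3)
  expect_equal(rep$macro_recall, 2 / 3)
})

test_that("macro metrics match a brute-force confusion-matrix computation", {
  set.seed(71)
  for (rep_i in 1:100) {
    d <- sample(c(2, 3, 8), 1)
    scheme <- switch(as.character(d), "2" = "alpha-other", "3" = "alpha-beta-other", "8" = "all8")
    n <- sample(5:40, 1)
    yt <- sample(0:(d - 1), n, replace = TRUE)
    yp <- sample(0:(d - 1), n, replace = TRUE)
    got <- macro_prf(yt, yp, scheme = scheme)
    # independent oracle: direct counting
    P <- R <- numeric(d)
    for (c_ in 0:(d - 1)) {
      tp <- sum(yt == c_ & yp == c_)
      P[c_ + 1] <- if (sum(yp == c_) > 0) tp / sum(yp == c_) else 0
      R[c_ + 1] <- if (sum(yt == c_) > 0) tp / sum(yt == c_) else 0
    }
    expect_equal(got$macro_precision, mean(P))
    expect_equal(got$macro_recall, mean(R))
  }
})

test_that("boundary errors are binned by distance to the element extremity", {
  # one 5-residue helix flanked by coil
  yt <- c(2, 0, 0, 0, 0, 0, 2)
  yp_ext <- c(2, 2, 0, 0, 0, 2, 2) # errors at both extremities
  prof <- boundary_error_profile(yt, yp_ext, w_max = 2, scheme = "alpha-beta-other")
  expect_equal(prof$errors[prof$bucket == "1"], 2)
  expect_equal(sum(prof$errors), 2)

  yp_mid <- c(2, 0, 0, 1, 0, 0, 2) # error dead centre: w = 3
  prof3 <- boundary_error_profile(yt, yp_mid, w_max = 3, scheme = "alpha-beta-other")
  expect_equal(prof3$errors[prof3$bucket == "3"], 1)
  prof2 <- boundary_error_profile(yt, yp_mid, w_max = 2, scheme = "alpha-beta-other")
  expect_equal(prof2$errors[prof2$bucket == "interior"], 1)

  none <- boundary_error_profile(yt, yt, scheme = "alpha-beta-other")
  expect_equal(sum(none$errors), 0)

  outside <- boundary_error_profile(yt, c(0, 0, 0, 0, 0, 0, 2), scheme = "alpha-beta-other")
  expect_equal(outside$errors[outside$bucket == "outside"], 1)
})

test_that("element statistics count maximal runs per class", {
  # H H H H - - - - E E E as class ids
  y <- c(0, 0, 0, 0, 2, 2, 2, 2, 1, 1, 1)
  st <- element_stats(y, scheme = "alpha-beta-other")
  expect_equal(st$n_elements[st$ss_class == "alpha"], 1)
  expect_equal(st$mean_length[st$ss_class == "alpha"], 4)
  expect_equal(st$n_elements[st$ss_class == "beta"], 1)
  expect_equal(st$mean_length[st$ss_class == "beta"], 3)

  allother <- element_stats(rep(2, 6), scheme = "alpha-beta-other")
  expect_true(all(allother$n_elements == 0))

  y2 <- c(0, 0, 1, 1, 0, 0) # HHEEHH
  st2 <- element_stats(y2, scheme = "alpha-beta-other")
  expect_equal(st2$n_elements[st2$ss_class == "alpha"], 2)
  expect_equal(st2$mean_length[st2$ss_class == "alpha"], 2)
  expect_equal(st2$n_elements[st2$ss_class == "beta"], 1)
})

test_that("element count times mean length recovers the labelled residue totals", {
  set.seed(72)
  for (i in 1:20) {
    y <- sample(0:2, 50, replace = TRUE)
    st <- element_stats(y, scheme = "alpha-beta-other")
    expect_equal(
      st$n_elements[st$ss_class == "alpha"] * st$mean_length[st$ss_class == "alpha"],
      sum(y == 0)
    )
    expect_equal(
      st$n_elements[st$ss_class == "beta"] * st$mean_length[st$ss_class == "beta"],
      sum(y == 1)
    )
  }
})

test_that("trimming element limits relabels extremities and dissolves short elements", {
  y <- c(0, 0, 0, 0, 0) # HHHHH
  expect_equal(trim_element_limits(y, w = 1, scheme = "alpha-beta-other"), c(2, 0, 0, 0, 2))
  expect_equal(trim_element_limits(c(0, 0), w = 1, scheme = "alpha-beta-other"), c(2, 2))
  expect_error(trim_element_limits(y, w = 0, scheme = "alpha-beta-other"),
    class = "geosec_validation_error"
  )
  # trimming matches the boundary-error analysis: a prediction that is
  # perfect in element interiors scores 1 on the trimmed reference
  yt <- c(2, 0, 0, 0, 0, 0, 2, 1, 1, 1, 1, 2)
  yp <- c(2, 2, 0, 0, 0, 2, 2, 2, 1, 1, 2, 2) # extremities called Other
  trimmed <- trim_element_limits(yt, w = 1, scheme = "alpha-beta-other")
  expect_gte(
    macro_prf(trimmed, yp, scheme = "alpha-beta-other")$macro_recall,
    macro_prf(yt, yp, scheme = "alpha-beta-other")$macro_recall
  )
})
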