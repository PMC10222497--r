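make_table <- function(keys, cw, frequency = 5L, rare = FALSE) {
  tab <- data.frame(key = keys, kind = sub("\\|.*", "", keys),
                    token = sub("^[^|]*\\|", "", keys),
                    frequency = frequency,
                    rare = rare, cw = cw, stringsAsFactors = FALSE)
  class(tab) <- c("cw_table", "data.frame")
  attr(tab, "T") <- 1L
  tab
}

test_that("DCW is the multiplicity-weighted sum of non-rare weights", {
  p <- attribute_profile(rep("C", 4))
  expect_identical(compute_dcw(p, make_table("S|C", 0)), 0)
  tab <- make_table(c("S|C", "SS|C|C"), c(1.5, 0))
  expect_equal(compute_dcw(p, tab), 6.0)
  # brute-force oracle: explicit loop over an attribute occurrence list
  set.seed(5)
  for (i in 1:10) {
    atoms <- sample(c("C", "N", "O", "=", "Cl"), 10, replace = TRUE)
    p <- attribute_profile(atoms)
    keys <- names(p)
    cw <- round(stats::rnorm(length(keys)), 3)
    tab <- make_table(keys, cw)
    brute <- 0
    for (k in seq_along(keys))
      for (rep in seq_len(p[[k]])) brute <- brute + cw[k]
    expect_equal(compute_dcw(p, tab), brute, tolerance = 1e-12)
  }
})

test_that("DCW is linear: profile union adds descriptors", {
  tab <- make_table(c("S|C", "S|N", "SS|C|N"), c(0.5, -1, 2))
  p1 <- attribute_profile(c("C", "N"))
  p2 <- attribute_profile(c("C", "C"))
  keys <- union(names(p1), names(p2))
  merged <- structure(
    as.integer(sapply(keys, function(k)
      sum(p1[names(p1) == k], p2[names(p2) == k]))),
    names = keys, class = "attribute_profile")
  expect_equal(compute_dcw(merged, tab),
               compute_dcw(p1, tab) + compute_dcw(p2, tab))
})

test_that("rare and unknown attributes never contribute", {
  tab <- make_table(c("S|C", "S|Zz"), c(1, 100), rare = c(FALSE, TRUE))
  p <- attribute_profile(c("C", "Zz", "Qq"))  # Qq unknown to the table
  expect_equal(compute_dcw(p, tab), 1)
  m <- semicor_model(tab, T = 1, N = 0, C0 = 0.1, C1 = 2)
  pr <- predict(m, list(attribute_profile("C"), p))
  expect_equal(pr$y[1], pr$y[2])           # rare/unknown leave y unchanged
  # 6 occurrences in all (3 S, 2 SS, 1 SSS); only S|C carries weight
  expect_identical(pr$unknown_attributes, c(0L, 5L))
})

test_that("fit_line matches ordinary least squares", {
  # perfect fit: descriptor equals the label
  expect_equal(fit_line(c(0, 1, 0, 1), c(0, 1, 0, 1)),
               c(C0 = 0, C1 = 1))
  # constant labels: slope 0, intercept the common label
  expect_equal(fit_line(c(1, 2, 3), c(1, 1, 1)), c(C0 = 1, C1 = 0))
  # 6-point hand dataset against lm() as the independent reference
  x <- c(0.2, 1.1, 2.4, 3.0, 4.4, 5.1)
  y <- c(0, 0, 1, 0, 1, 1)
  cf <- fit_line(x, y)
  ref <- unname(stats::coef(stats::lm(y ~ x)))
  expect_equal(unname(cf), ref, tolerance = 1e-12)
  # residuals on the fitted set sum to zero
  expect_lt(abs(sum(y - (cf[1] + cf[2] * x))), 1e-9)
  expect_error(fit_line(rep(2, 5), c(0, 1, 0, 1, 0)), "degenerate")
  expect_error(fit_line(1, 1), "at least 2")
})

test_that("classification threshold is boundary-inclusive at y = 0.5", {
  tab <- make_table("S|C", 0)
  m <- semicor_model(tab, T = 1, N = 0, C0 = 0.5, C1 = 1)
  p0 <- attribute_profile(character(0))      # y = C0 exactly
  expect_identical(predict(m, list(p0))$category, 1L)
  m2 <- semicor_model(tab, T = 1, N = 0, C0 = 0.4999, C1 = 1)
  expect_identical(predict(m2, list(p0))$category, 0L)
  # degenerate slope: every compound lands on the intercept
  m3 <- semicor_model(tab, T = 1, N = 0, C0 = 0.5, C1 = 0)
  pr <- predict(m3, c("CCN", "O", ""))
  expect_identical(pr$category, rep(1L, 3))
})

test_that("model serialization round-trips bit-exactly", {
  d <- simulate_compounds(n_compounds = 80, seed = 12)
  cfg <- optimizer_config(T = 2, n_epochs = 3, seed = 12)
  fit <- fit_on_split1(d, cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(fit$model, path)
  back <- read_model(path)
  expect_identical(back$C0, fit$model$C0)
  expect_identical(back$C1, fit$model$C1)
  expect_identical(back$cw_table$cw, fit$model$cw_table$cw)
  p1 <- predict(fit$model, d$smiles)
  p2 <- predict(back, d$smiles)
  expect_identical(p1$y, p2$y)
  expect_identical(p1$category, p2$category)
})
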