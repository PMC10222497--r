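test_that("four-way splits partition the compounds near-evenly", {
  sp <- make_splits(8, k = 1, seed = 1)[[1]]
  expect_identical(unname(lengths(sp[semicor:::split_sets])),
                   rep(2L, 4))
  splits <- make_splits(1274, k = 3, seed = 9)
  for (sp in splits) {
    sizes <- lengths(sp[semicor:::split_sets])
    expect_identical(sum(sizes), 1274L)
    expect_true(all(sizes >= 314 & sizes <= 322))
    all_idx <- unlist(sp[semicor:::split_sets], use.names = FALSE)
    expect_identical(sort(all_idx), seq_len(1274))  # partition, disjoint
  }
  expect_identical(make_splits(100, 2, seed = 5), make_splits(100, 2, seed = 5))
  expect_error(make_splits(7, 1, seed = 1), "at least 8")
})

test_that("identical models on identical splits give a constant matrix", {
  d <- data.frame(smiles = rep(c("CCN", "CO", "N", "CCCN", "OO", "CN",
                                 "NO", "CCO"), 3),
                  label = rep(c(1, 0, 0, 1, 0, 1, 0, 1), 3))
  cfg <- optimizer_config(T = 1, n_epochs = 2, seed = 3)
  sp <- make_splits(nrow(d), 1, seed = 3)[[1]]
  fit <- mc_optimize(d, sp, cfg)
  mat <- build_matrix(list(fit$model, fit$model), list(sp, sp), d)
  expect_equal(max(mat) - min(mat), 0)
  expect_error(build_matrix(list(fit$model), list(sp, sp), d),
               "as many models as splits")
})

test_that("matrix cells equal hand-enumerated per-set MCCs", {
  # two deterministic single-attribute models on a 10-compound toy table
  mk <- function(cw_n) {
    tab <- data.frame(key = "S|N", kind = "S", token = "N", frequency = 5L,
                      rare = FALSE, cw = cw_n, stringsAsFactors = FALSE)
    class(tab) <- c("cw_table", "data.frame")
    semicor_model(tab, T = 1, N = 1, C0 = 0, C1 = 1)
  }
  # y = cw_n * (#N in SMILES); model A: cw 0.5 -> active iff >= 1 N;
  # model B: cw 0.26 -> active iff >= 2 N
  d <- data.frame(
    smiles = c("N", "CC", "NN", "CNC", "C", "NNN", "CN", "O", "NNO", "OC"),
    label  = c(1,   0,    1,    1,     0,   1,     0,    0,   1,     0))
  spl <- list(
    structure(list(active_training = 1:2, passive_training = 3:4,
                   calibration = 5:6, validation = 7:8),
              class = "four_way_split"),
    structure(list(active_training = 9:10, passive_training = 1:2,
                   calibration = 3:4, validation = 5:6),
              class = "four_way_split"))
  models <- list(mk(0.5), mk(0.26))
  mat <- build_matrix(models, spl, d)
  n_count <- c(1, 0, 2, 1, 0, 3, 1, 0, 2, 0)
  for (i in 1:2) for (j in 1:2) {
    pred <- as.integer(c(0.5, 0.26)[i] * n_count >= 0.5)
    idx <- spl[[j]]$validation
    expect_equal(mat[i, j], mcc_score(d$label[idx], pred[idx]),
                 info = sprintf("cell %d,%d", i, j))
  }
  # diagonal equals the metrics module's independent validation MCC
  for (i in 1:2) {
    idx <- spl[[i]]$validation
    pred <- predict(models[[i]], d$smiles[idx])$category
    expect_identical(mat[i, i], mcc_score(d$label[idx], pred))
  }
})

test_that("summary reduces to off-diagonal mean and population sd", {
  cmat <- matrix(0.7, 3, 3)
  s <- summarize_consistency(cmat)
  expect_equal(s$mean_offdiag, 0.7)
  expect_identical(s$sd_offdiag, 0)
  s <- summarize_consistency(matrix(c(0.6, 0.5, 0.4, 0.7), 2, 2,
                                    byrow = TRUE))
  expect_equal(s$mean_offdiag, 0.45)
  expect_equal(s$sd_offdiag, 0.05)
  set.seed(10)
  m <- matrix(stats::runif(25), 5, 5)
  s <- summarize_consistency(m)
  off <- c()
  for (i in 1:5) for (j in 1:5) if (i != j) off <- c(off, m[i, j])
  expect_equal(s$mean_offdiag, mean(off), tolerance = 1e-12)
  expect_equal(s$sd_offdiag, sqrt(mean((off - mean(off))^2)),
               tolerance = 1e-12)
  expect_equal(s$mean_all, mean(m), tolerance = 1e-12)
  expect_error(summarize_consistency(matrix(1, 1, 1)), "k >= 2")
})

test_that("validation overlap is Jaccard with the expected null level", {
  sp <- make_splits(100, 1, seed = 2)[[1]]
  expect_equal(validation_overlap(list(sp, sp)),
               matrix(1, 2, 2, dimnames = list(c("V1", "V2"),
                                               c("V1", "V2"))))
  a <- structure(list(active_training = 1:2, passive_training = 3:4,
                      calibration = 5:6, validation = 7:8),
                 class = "four_way_split")
  b <- structure(list(active_training = 7:8, passive_training = 5:6,
                      calibration = 3:4, validation = 1:2),
                 class = "four_way_split")
  expect_equal(validation_overlap(list(a, b))[1, 2], 0)
  # independent 25% samples: E[Jaccard] = (1/16) / (7/16) = 1/7
  splits <- make_splits(1000, k = 6, seed = 8)
  ov <- validation_overlap(splits)
  offdiag <- ov[row(ov) != col(ov)]
  expect_lt(abs(mean(offdiag) - 1 / 7), 0.03)
  expect_true(isSymmetric(ov))
})
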