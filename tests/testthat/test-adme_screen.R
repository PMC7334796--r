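test_that("Tanimoto drug-likeness matches hand-evaluated cases", {
  expect_equal(tanimoto_dl(c(2, 3, 1), c(2, 3, 1)), 1.0)
  expect_equal(tanimoto_dl(c(1, 0), c(0, 5)), 0.0)
  expect_equal(tanimoto_dl(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_error(tanimoto_dl(c(1, 2), c(1, 2, 3)), "length")
  expect_error(tanimoto_dl(c(0, 0), c(0, 0)), "zero")
})

test_that("Tanimoto score is symmetric and in (0, 1] for non-negative input", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(8, 0, 10)
    b <- runif(8, 0, 10)
    expect_equal(tanimoto_dl(a, b), tanimoto_dl(b, a))
    expect_gt(tanimoto_dl(a, b), 0)
    expect_lte(tanimoto_dl(a, b), 1)
  }
})

test_that("screen reproduces the published threshold behavior", {
  ing <- load_table1_fixture()
  res <- screen(ing)
  expect_true("ATR93" %in% res$passed)        # kaempferol: 41.88 / 0.24
  expect_true("CR38" %in% res$rejected)       # syringin: OB 14.64 < 30
  expect_true("CR75" %in% res$rejected)       # HMF: DL 0.02 < 0.10

  wl <- default_whitelist(ing)
  expect_true(all(c("CR38", "CR75", "CR77") %in% wl))
  res_wl <- screen(ing, whitelist = wl)
  expect_true("CR38" %in% res_wl$supplemented)
  expect_length(res_wl$rejected, 0)
  expect_equal(length(res_wl$passed) + length(res_wl$supplemented), 68)
})

test_that("screen partitions its input and is order-independent", {
  ing <- load_table1_fixture()
  set.seed(7)
  for (i in 1:10) {
    ob_min <- runif(1, 0, 100)
    dl_min <- runif(1, 0, 1)
    wl <- sample(ing$id, sample.int(10, 1))
    res <- screen(ing, ob_min, dl_min, wl)
    expect_setequal(c(res$passed, res$supplemented, res$rejected), ing$id)
    expect_equal(length(res$passed) + length(res$supplemented) +
                   length(res$rejected), nrow(ing))
    shuffled <- screen(ing[sample.int(nrow(ing)), ], ob_min, dl_min, wl)
    expect_setequal(shuffled$passed, res$passed)
    expect_setequal(shuffled$supplemented, res$supplemented)
  }
  expect_warning(screen(ing, whitelist = "XX99"), "absent")
})

test_that("thresholds are inclusive at the boundary", {
  ing <- data.frame(id = c("ATR1", "ATR2", "CR1"), name = "x",
                    herb = c("ATR", "ATR", "CR"),
                    ob = c(30, 29.99, 50), dl = c(0.10, 0.5, 0.0999))
  res <- screen(ing)
  expect_equal(res$passed, "ATR1")
  expect_setequal(res$rejected, c("ATR2", "CR1"))
})

test_that("herb property comparison matches a closed-form Welch oracle", {
  set.seed(11)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    ing <- data.frame(id = c(sprintf("ATR%d", seq_along(x)),
                             sprintf("CR%d", seq_along(y))),
                      name = "x",
                      herb = rep(c("ATR", "CR"), c(length(x), length(y))),
                      ob = 50, dl = 0.5, mw = c(x, y))
    got <- compare_herb_properties(ing, "mw")
    want <- oracle_welch(x, y)
    expect_equal(got$t, unname(want["t"]), tolerance = 1e-10)
    expect_equal(got$p, unname(want["p"]), tolerance = 1e-10)
    expect_equal(got$mean_ATR, mean(x))
    expect_equal(got$mean_CR, mean(y))
  }
})

test_that("identical groups give t = 0, p = 1", {
  ing <- data.frame(id = c("ATR1", "ATR2", "ATR3", "CR1", "CR2", "CR3"),
                    name = "x", herb = rep(c("ATR", "CR"), each = 3),
                    ob = 50, dl = 0.5, mw = rep(c(100, 200, 300), 2))
  got <- compare_herb_properties(ing, "mw")
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
})

test_that("shared ingredients are counted in both herb groups", {
  ing <- data.frame(id = c("ATR1", "ATR2", "CR1", "CR2", "CR75"),
                    name = "x",
                    herb = c("ATR", "ATR", "CR", "CR", "SHARED"),
                    ob = 50, dl = 0.5, mw = c(10, 20, 30, 40, 100))
  got <- compare_herb_properties(ing, "mw")
  expect_equal(got$n_ATR, 3)
  expect_equal(got$n_CR, 3)
  expect_equal(got$mean_ATR, mean(c(10, 20, 100)))
  expect_equal(got$mean_CR, mean(c(30, 40, 100)))
})

test_that("properties without enough data are skipped with a message", {
  ing <- data.frame(id = c("ATR1", "ATR2", "CR1", "CR2"), name = "x",
                    herb = c("ATR", "ATR", "CR", "CR"),
                    ob = 50, dl = 0.5, mw = NA_real_)
  expect_message(got <- compare_herb_properties(ing, c("mw", "ob")),
                 "skipped")
  expect_equal(got$property, "ob")
})

test_that("herbs simulated at the published means separate at p < 0.01", {
  set.seed(1)
  mw <- c(rnorm(105, 227.44, 80), rnorm(134, 316.17, 80))
  ing <- data.frame(id = c(sprintf("ATR%d", 1:105), sprintf("CR%d", 1:134)),
                    name = "x", herb = rep(c("ATR", "CR"), c(105, 134)),
                    ob = 50, dl = 0.5, mw = mw)
  got <- compare_herb_properties(ing, "mw")
  expect_lt(got$p, 0.01)
})
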