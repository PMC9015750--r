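test_that("3PL closed forms hold at the anchor points", {
  it <- new_item("q", a = 2, b = -0.3, c = 0.2)
  expect_equal(prob_correct(it, -0.3), 0.6)           # (1 + c) / 2 at theta = b
  it2 <- new_item("q", a = 1, b = 0, c = 0.25)
  expect_equal(prob_correct(it2, -50), 0.25, tolerance = 1e-9)
  expect_equal(prob_correct(it2, 50), 1, tolerance = 1e-9)
  # frozen independent arithmetic: a=1.5, b=0.5, c=0.2, theta=1
  it3 <- new_item("q", 1.5, 0.5, 0.2)
  expect_equal(prob_correct(it3, 1), 0.7433429593403145, tolerance = 1e-10)
  expect_equal(item_information(it3, 1), 0.35835591877047546,
               tolerance = 1e-10)
  # 2PL reduction: I = a^2 / 4 at theta = b when c = 0
  it4 <- new_item("q", 1.7, 0.4, 0)
  expect_equal(item_information(it4, 0.4), 1.7^2 / 4)
  expect_error(new_item("q", 1, 0, 1.2), "\\[0, 1\\)")
})

test_that("prob_correct is increasing in theta and bounded in (c, 1)", {
  set.seed(11)
  for (rep in 1:25) {
    it <- new_item("q", a = runif(1, 0.3, 2.5), b = runif(1, -2, 2),
                   c = runif(1, 0, 0.4))
    th <- sort(runif(7, -5, 5))
    p <- prob_correct(it, th)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > it$c & p < 1))
    expect_true(all(item_information(it, th) >= 0))
  }
})

test_that("EAP matches a fine-grid oracle and behaves at the prior", {
  empty <- estimate_ability_eap(numeric(0), list())
  expect_equal(empty$theta, 0)
  expect_equal(empty$se, 1)

  its <- list(new_item("a", 1, 0, 0.2), new_item("b", 1, 0, 0.2))
  est <- estimate_ability_eap(c(1, 1), its)
  expect_equal(est$theta, oracle_eap(c(1, 1), its), tolerance = 1e-4)
  est0 <- estimate_ability_eap(c(0, 0), its)
  expect_gt(est$theta, est0$theta)

  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    its <- lapply(seq_len(k), function(i)
      new_item(paste0("i", i), runif(1, 0.5, 2), runif(1, -1.5, 1.5),
               runif(1, 0, 0.3)))
    resp <- rbinom(k, 1, 0.5)
    est <- estimate_ability_eap(resp, its)
    expect_equal(est$theta, oracle_eap(resp, its), tolerance = 1e-4)
    expect_gt(est$se, 0)
  }
  expect_error(estimate_ability_eap(c(1, 0), list(new_item("a", 1, 0))),
               "length")
})

test_that("flipping an incorrect response to correct raises the EAP", {
  set.seed(12)
  its <- lapply(1:5, function(i)
    new_item(paste0("i", i), runif(1, 0.5, 2), runif(1, -1, 1),
             runif(1, 0, 0.25)))
  resp <- c(0, 1, 0, 1, 0)
  base <- estimate_ability_eap(resp, its)$theta
  for (j in which(resp == 0)) {
    flipped <- resp
    flipped[j] <- 1
    expect_gt(estimate_ability_eap(flipped, its)$theta, base)
  }
})

test_that("literacy classification splits at the average score", {
  expect_identical(classify_literacy(1.2), "high")
  expect_identical(classify_literacy(-0.5), "low")
  expect_identical(classify_literacy(0), "high")    # documented tie-break
  est <- estimate_ability_eap(c(1, 1),
                              list(new_item("a", 1.5, 1), new_item("b", 1.5, 1.5)))
  expect_identical(classify_literacy(est), classify_literacy(est$theta))
})

test_that("EM calibration recovers simulated truth and ascends", {
  spec <- synth_spec(seed = 1L,
                     irt = list(n_items = 12L, n_persons = 600L,
                                a_range = c(0.8, 2), b_range = c(-2, 2),
                                c_range = c(0, 0.25)))
  items <- synth_items(spec)
  resp <- synth_responses(items, spec$irt$n_persons, seed = 101L)
  fit <- calibrate_3pl_em(resp$values, max_iter = 80L)
  expect_true(all(diff(fit$loglik) > -1e-6))
  b_true <- vapply(items, `[[`, numeric(1), "b")
  b_hat <- vapply(fit$items, `[[`, numeric(1), "b")
  expect_lt(sqrt(mean((b_hat - b_true)^2)), 0.45)
})

test_that("degenerate items are excluded and contracts enforced", {
  set.seed(5)
  m <- matrix(rbinom(200, 1, 0.6), 50, 4,
              dimnames = list(NULL, paste0("i", 1:4)))
  m[, 2] <- 1                       # answered correctly by everyone
  expect_warning(fit <- calibrate_3pl_em(m, max_iter = 5L), "i2")
  expect_identical(fit$excluded, "i2")
  expect_false("i2" %in% vapply(fit$items, `[[`, character(1), "id"))
  expect_error(calibrate_3pl_em(matrix(numeric(0), 0, 0)), "empty|matrix")
  expect_error(validate_response_matrix(matrix(c(0, 2), 1, 2)), "0, 1")
})

test_that("short-form selection matches brute force and drops a <= a_min", {
  grid <- quadrature_grid(21L, -4, 4)
  brute_best <- function(items, n) {
    ids <- vapply(items, `[[`, character(1), "id")
    keep <- vapply(items, function(it) it$a > 0.2, logical(1))
    pool <- which(keep)
    combos <- utils::combn(pool, n)
    obj <- apply(combos, 2L, function(ix)
      mean(Reduce(`+`, lapply(items[ix], item_information, theta = grid$nodes))))
    sort(ids[combos[, which.max(obj)]])
  }
  set.seed(77)
  for (rep in 1:6) {
    items <- lapply(1:5, function(i)
      new_item(paste0("q", i), runif(1, 0.3, 2.2), runif(1, -2, 2),
               runif(1, 0, 0.3)))
    expect_identical(sort(shorten_test(items, 2L, grid)),
                     brute_best(items, 2L))
  }
  items <- c(lapply(1:4, function(i)
    new_item(paste0("q", i), 0.5 + i / 4, 0, 0.1)),
    list(new_item("flat", 0, 0, 0.1)))
  sel <- shorten_test(items, 4L, grid)
  expect_false("flat" %in% sel)                 # a = 0: no information
  all_in <- lapply(1:3, function(i) new_item(paste0("k", i), 1 + i / 10, 0))
  expect_setequal(shorten_test(all_in, 3L, grid), c("k1", "k2", "k3"))
  expect_error(shorten_test(all_in, 0L, grid), ">= 1")
})

test_that("item banks and response matrices round-trip through files", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,a,b,c", "q1,1.5,0.5,0.2", "q2,0.9,-1,0"), path)
  bank <- read_item_bank(path)
  expect_length(bank, 2L)
  expect_equal(bank[[1]]$a, 1.5)

  rpath <- tempfile(fileext = ".csv")
  writeLines(c("person,q1,q2", "p1,1,0", "p2,NA,1"), rpath)
  m <- read_response_matrix(rpath)
  expect_identical(dim(m), c(2L, 2L))
  expect_true(is.na(m["p2", "q1"]))
})
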