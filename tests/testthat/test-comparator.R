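# Structural guarantees and training behaviour of the cross-wired comparator.

test_that("reflexivity and anti-symmetry hold structurally for random weights", {
  set.seed(42)
  for (rep in 1:5) {
    m <- comparator(6, hidden = c(8, 8), seed = rep)
    for (i in 1:10) {
      x <- rnorm(6)
      y <- rnorm(6)
      expect_lt(abs(compare(m, x, x) - 0.5), 1e-9)
      expect_lt(abs(compare(m, x, y) + compare(m, y, x) - 1), 1e-6)
    }
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  m <- comparator(4, hidden = c(5, 3), seed = 9)
  X <- matrix(rnorm(4 * 7), 4)
  Y <- matrix(rnorm(4 * 7), 4)
  g <- lbassign:::.comparator_grad(m, X, Y)
  loss_at <- function(mod) {
    -mean(log(lbassign:::.comparator_forward(mod, X, Y)$score))
  }
  eps <- 1e-6
  probes <- list(
    list(\(mod, v) { mod$layers[[1]]$W11[2, 3] <- v; mod },
         \(mod) mod$layers[[1]]$W11[2, 3], \() g$grads[[1]]$W11[2, 3]),
    list(\(mod, v) { mod$layers[[2]]$W12[1, 4] <- v; mod },
         \(mod) mod$layers[[2]]$W12[1, 4], \() g$grads[[2]]$W12[1, 4]),
    list(\(mod, v) { mod$layers[[1]]$b[5] <- v; mod },
         \(mod) mod$layers[[1]]$b[5], \() g$grads[[1]]$b[5]),
    list(\(mod, v) { mod$w_out[2] <- v; mod },
         \(mod) mod$w_out[2], \() g$dw_out[2])
  )
  for (p in probes) {
    v0 <- p[[2]](m)
    num <- (loss_at(p[[1]](m, v0 + eps)) - loss_at(p[[1]](m, v0 - eps))) / (2 * eps)
    expect_equal(p[[3]](), num, tolerance = 1e-5)
  }
})

test_that("training is reproducible, reduces loss, and separates a repeated pair", {
  set.seed(5)
  pr <- preference_pairs(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
  m1 <- train_comparator(pr, hidden = c(8), epochs = 20, seed = 31)
  m2 <- train_comparator(pr, hidden = c(8), epochs = 20, seed = 31)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$w_out, m2$w_out)

  one <- preference_pairs(matrix(rep(c(1, 0, 0, 0), 30), 30, byrow = TRUE),
                          matrix(rep(c(0, 1, 0, 0), 30), 30, byrow = TRUE))
  m3 <- train_comparator(one, hidden = c(8), epochs = 40, seed = 1)
  expect_gt(compare(m3, c(1, 0, 0, 0), c(0, 1, 0, 0)), 0.5)
  expect_lt(mean(utils::tail(m3$loss_history, 5)),
            mean(utils::head(m3$loss_history, 5)))
})

test_that("invalid inputs are rejected", {
  m <- comparator(4, hidden = 4, seed = 1)
  expect_error(compare(m, c(1, 2, 3), c(1, 2, 3, 4)), "schema")
  expect_error(compare(m, c(1, 2, 3, NA), c(1, 2, 3, 4)), "finite")
  empty <- preference_pairs(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, 4))
  expect_error(train_comparator(empty), "empty")
})

test_that("serialisation round-trips scores exactly enough to reuse the model", {
  set.seed(8)
  pr <- preference_pairs(matrix(rnorm(120), 30), matrix(rnorm(120), 30),
                         schema_id = "demo")
  m <- train_comparator(pr, hidden = c(6, 4), epochs = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_comparator(m, path)
  m2 <- read_comparator(path)
  expect_identical(m2$schema_id, "demo")
  x <- rnorm(4); y <- rnorm(4)
  expect_equal(compare(m2, x, y), compare(m, x, y), tolerance = 1e-12)
})
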