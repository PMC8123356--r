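# Majority-vote selection and ordered-pool insertion.

test_that("a single candidate is returned without any comparison", {
  m <- comparator(3, hidden = 4, seed = 1)
  expect_identical(majority_vote_select(m, matrix(rnorm(3), 1)), 1L)
  expect_error(majority_vote_select(m, matrix(numeric(0), 0, 3)), "empty")
})

test_that("the vote winner maximises an independently recomputed tournament", {
  set.seed(21)
  for (rep in 1:30) {
    m <- comparator(4, hidden = c(6), seed = rep)
    n <- sample(2:6, 1)
    cands <- matrix(rnorm(4 * n), n)
    # naive double-loop tournament, independent of tournament_points()
    pts <- numeric(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- compare(m, cands[i, ], cands[j, ])
        if (abs(s - 0.5) <= .Machine$double.eps) {
          pts[i] <- pts[i] + 0.5; pts[j] <- pts[j] + 0.5
        } else if (s > 0.5) pts[i] <- pts[i] + 1 else pts[j] <- pts[j] + 1
      }
    }
    win <- majority_vote_select(m, cands)
    expect_equal(pts[win], max(pts))
    expect_equal(tournament_points(m, cands), pts)
  }
})

test_that("exact-0.5 ties are broken uniformly at random", {
  m <- comparator(3, hidden = 4, seed = 2)
  x <- c(0.3, -1, 2)
  cands <- rbind(x, x) # identical vectors: C = 0.5 exactly
  set.seed(99)
  picks <- replicate(10000, majority_vote_select(m, cands))
  n1 <- sum(picks == 1L)
  # binomial(10000, 0.5): 3 s.e. ~ 150
  expect_gt(n1, 5000 - 150)
  expect_lt(n1, 5000 + 150)
})

test_that("partial-order insertion respects boundaries and incumbent order", {
  sch_dim <- 5
  m <- linear_feature_comparator(sch_dim, idx = 1)
  mk <- function(v) c(v, rnorm(sch_dim - 1))
  set.seed(4)
  empty <- insert_by_partial_order(m, NULL, mk(0))
  expect_equal(nrow(empty$pool), 1L)
  expect_equal(empty$position, 1L)

  pool <- rbind(mk(3), mk(2), mk(1)) # ranked best-first on feature 1
  top <- insert_by_partial_order(m, pool, mk(10))
  expect_equal(top$position, 1L)
  bottom <- insert_by_partial_order(m, pool, mk(-10))
  expect_equal(bottom$position, 4L)
  mid <- insert_by_partial_order(m, pool, mk(2.5))
  expect_equal(mid$position, 2L)
  # incumbents keep their relative order
  expect_equal(mid$pool[-mid$position, ], pool, ignore_attr = TRUE)
})
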