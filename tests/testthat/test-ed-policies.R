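# FCFSwU baseline contract and the comparator policy's candidate handling.

test_that("non-urgent patients never go to a mismatched specialist", {
  # orthopedic non-urgent patient; only an internal-medicine specialist idle
  st <- make_ed_state(
    waiting = data.frame(idx = 1L, severity = 4L, injury = "orthopedic"),
    physicians = data.frame(seniority = "attending", specialty = "internal"))
  dec <- fcfswu_decide(st)
  expect_equal(nrow(dec), 0L) # the patient waits

  # with a generalist available the patient is seated with the generalist
  st2 <- make_ed_state(
    waiting = data.frame(idx = 1L, severity = 4L, injury = "orthopedic"),
    physicians = data.frame(seniority = c("attending", "intern"),
                            specialty = c("internal", NA)))
  dec2 <- fcfswu_decide(st2)
  expect_equal(dec2$physician, 2L)
})

test_that("mismatch avoidance holds across random constructed states", {
  set.seed(33)
  injuries <- c("internal", "orthopedic", "trauma")
  for (rep in 1:40) {
    nw <- sample(1:4, 1)
    np <- sample(1:4, 1)
    st <- make_ed_state(
      waiting = data.frame(idx = seq_len(nw),
                           severity = sample(3:5, nw, replace = TRUE),
                           injury = sample(injuries, nw, replace = TRUE),
                           arr = sample(0:5, nw, replace = TRUE)),
      physicians = data.frame(
        seniority = sample(c("attending", "resident", "intern"), np, replace = TRUE),
        specialty = sample(c(injuries, NA), np, replace = TRUE),
        busy_patient = 0L))
    dec <- fcfswu_decide(st)
    for (r in seq_len(nrow(dec))) {
      spec <- st$physicians$specialty[dec$physician[r]]
      inj <- st$waiting$injury[st$waiting$idx == dec$patient[r]]
      expect_true(is.na(spec) || spec == inj)
    }
  }
})

test_that("urgent arrivals interrupt the most senior eligible physician", {
  # attending specialist busy with a non-urgent patient: preempted
  st <- make_ed_state(
    waiting = data.frame(idx = 9L, severity = 1L, injury = "internal"),
    physicians = data.frame(seniority = c("attending", "resident"),
                            specialty = c("internal", "internal"),
                            busy_patient = c(5L, 0L),
                            busy_severity = c(4L, 0L)))
  dec <- fcfswu_decide(st)
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$physician, 1L) # most senior specialist, interrupted

  # a physician already treating an urgent patient is not interrupted
  st2 <- st
  st2$physicians$busy_severity <- c(2L, 0L)
  dec2 <- fcfswu_decide(st2)
  expect_equal(dec2$physician, 2L)
})

test_that("non-urgent patients are seated first-come-first-served", {
  st <- make_ed_state(
    waiting = data.frame(idx = c(1L, 2L), severity = c(4L, 4L),
                         injury = "internal", arr = c(6L, 2L)),
    physicians = data.frame(seniority = "intern", specialty = NA))
  dec <- fcfswu_decide(st)
  expect_equal(dec$patient, 2L) # the earlier arrival
})

test_that("the comparator policy enumerates waiting x (physicians + wait room)", {
  sch <- ed_schema(c("internal", "orthopedic", "trauma"))
  st <- make_ed_state(
    waiting = data.frame(idx = 1:3, severity = c(3L, 4L, 2L),
                         injury = c("internal", "trauma", "orthopedic")),
    physicians = data.frame(seniority = c("attending", "intern"),
                            specialty = c("internal", NA)))
  cs <- ed_candidate_set(st, sch)
  expect_equal(nrow(cs$features), 3L * (2L + 1L))
  expect_equal(sum(cs$meta$physician == 0L), 3L)

  m <- comparator(sch$length, hidden = 4, schema_id = sch$id, seed = 1)
  set.seed(1)
  dec <- lba_decide(m, st, sch)
  expect_true(all(dec$physician %in% 1:2))
  expect_lte(nrow(dec), 2L) # at most one assignment per physician per round

  empty <- make_ed_state(waiting = data.frame(idx = 1L),
                         physicians = data.frame(seniority = "attending"))
  empty$waiting <- empty$waiting[0, , drop = FALSE]
  expect_equal(nrow(lba_decide(m, empty, sch)), 0L)
})
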