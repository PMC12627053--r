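test_that("score_match implements coverage minus off-template penalty", {
  tab <- default_prototypes()
  expect_equal(score_match(c("6" = 4, "12" = 3, "25" = 2), "happiness", tab), 1)
  expect_equal(score_match(setNames(numeric(0), character(0)), "happiness", tab), 0)
  expect_equal(score_match(c("6" = 2, "12" = 3), "happiness", tab), 2 / 3)
  # off-template activity is penalised by beta per active AU
  expect_equal(score_match(c("6" = 2, "12" = 3, "25" = 1, "4" = 2), "happiness", tab),
               1 - 0.5 * 1 / 4)
  expect_error(score_match(c("6" = 2), "boredom", tab), "unknown")
  expect_error(score_match(c("6" = 2), "neutral", tab), "unknown|non-scorable")
})

test_that("score_match is monotone in threshold crossings", {
  tab <- default_prototypes()
  base <- c("6" = 2, "12" = 3)
  # a prototype AU crossing tau_active cannot lower the score
  expect_gte(score_match(c(base, "25" = 1), "happiness", tab),
             score_match(c(base, "25" = 0), "happiness", tab))
  # a non-prototype AU crossing tau_active cannot raise it
  expect_lte(score_match(c(base, "9" = 1), "happiness", tab),
             score_match(c(base, "9" = 0), "happiness", tab))
})

test_that("classify_expression recovers prototypes and falls back to neutral", {
  tab <- default_prototypes()
  expect_equal(as.character(classify_expression(c("6" = 4, "12" = 3, "25" = 2), tab)),
               "happiness")
  expect_equal(as.character(classify_expression(au_vector(), tab)), "neutral")
  expect_equal(as.character(classify_expression(c("1" = 2, "4" = 3, "15" = 2), tab)),
               "sadness")
  # blink alone is not an expression
  expect_equal(as.character(classify_expression(c("45" = 3), tab)), "neutral")
  # sub-threshold best score goes neutral
  expect_equal(as.character(classify_expression(c("6" = 1), tab)), "neutral")
})

test_that("classifier matches brute-force prototype scoring on the sadness example", {
  tab <- default_prototypes()
  v <- c("1" = 2, "4" = 3, "15" = 2)
  scores <- vapply(
    c("happiness", "sadness", "fear", "anger", "surprise", "disgust"),
    function(e) score_match(v, e, tab), numeric(1)
  )
  expect_equal(names(which.max(scores)), "sadness")
  expect_gte(max(scores), tab$s_min)
})

test_that("every prototype classifies as itself at any active intensity", {
  tab <- default_prototypes()
  for (e in c("happiness", "sadness", "fear", "anger", "surprise", "disgust")) {
    for (lev in c(1, 3, 5)) {
      v <- setNames(rep(lev, length(tab$prototypes[[e]])),
                    as.character(tab$prototypes[[e]]))
      expect_equal(as.character(classify_expression(v, tab)), e,
                   label = sprintf("%s at level %d", e, lev))
    }
  }
})

test_that("vectorised classifier agrees with the single-vector classifier", {
  set.seed(42)
  tab <- default_prototypes()
  ids <- human_au_ids()
  M <- matrix(sample(0:5, 60 * length(ids), replace = TRUE, prob = c(.7, .1, .08, .06, .04, .02)),
              60, length(ids), dimnames = list(NULL, as.character(ids)))
  batch <- classify_expression_matrix(M, tab)
  single <- vapply(seq_len(nrow(M)),
                   function(i) as.character(classify_expression(M[i, ], tab)),
                   character(1))
  expect_equal(as.character(batch), single)
})

test_that("intensity indices follow their definitions and ordering", {
  tab <- default_prototypes()
  r <- intensity_indices(c("6" = 2, "12" = 4, "25" = 0), "happiness", tab)
  expect_equal(r$mean_all, 2)
  expect_equal(r$mean_active, 3)
  expect_equal(r$max_au, 4)
  r5 <- intensity_indices(c("6" = 5, "12" = 5, "25" = 5), "happiness", tab)
  expect_equal(unlist(r5), c(mean_all = 5, mean_active = 5, max_au = 5))
  r1 <- intensity_indices(c("6" = 1), "happiness", tab)
  expect_equal(r1$mean_all, 1 / 3)
  expect_equal(r1$mean_active, 1)
  expect_equal(r1$max_au, 1)
  # mean_all <= mean_active <= max whenever something is active
  set.seed(7)
  for (i in 1:50) {
    v <- setNames(sample(0:5, 3, replace = TRUE), c("6", "12", "25"))
    r <- intensity_indices(v, "happiness", tab)
    if (any(v > 0)) {
      expect_lte(r$mean_all, r$mean_active)
      expect_lte(r$mean_active, r$max_au)
    }
  }
})

test_that("retention filter keeps exactly the accurate trials, idempotently", {
  trials <- tibble::tibble(
    participant_id = sprintf("P%d", 1:7),
    accurate = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  expect_message(kept <- retain_accurate(trials), "2 trial")
  expect_equal(nrow(kept), 5)
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_true(all(kept$accurate))
  expect_equal(kept$participant_id, trials$participant_id[trials$accurate])
  again <- suppressMessages(retain_accurate(kept))
  expect_equal(again$participant_id, kept$participant_id)
  empty <- suppressMessages(retain_accurate(trials[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("group accuracy computes percentages per group and emotion", {
  groups <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20),
    bp_group = factor(rep(c("normotensive", "prehypertensive"), each = 10))
  )
  trials <- tibble::tibble(
    participant_id = groups$participant_id,
    intended = "sadness",
    accurate = c(rep(TRUE, 10), rep(TRUE, 2), rep(FALSE, 8))
  )
  out <- group_accuracy(trials, groups)
  norm <- out[out$bp_group == "normotensive" & out$emotion == "sadness", ]
  pre <- out[out$bp_group == "prehypertensive" & out$emotion == "sadness", ]
  expect_equal(norm$accuracy_pct, 100)
  expect_equal(pre$accuracy_pct, 20)
  # unobserved cells are undefined markers
  expect_true(is.na(out$accuracy_pct[out$emotion == "fear"][1]))
  dup <- dplyr::bind_rows(trials, trials[1, ])
  expect_error(group_accuracy(dup, groups), "at most one trial")
})

test_that("prototype table validates and reads from plain text", {
  expect_error(
    prototype_table(list(happiness = c(6, 12), sadness = 1, fear = 1,
                         anger = 1, surprise = 1, disgust = 1)),
    "AU6, AU12 and AU25"
  )
  expect_error(prototype_table(list(happiness = c(6, 12, 25))), "lacks entries")
  expect_error(
    prototype_table(list(happiness = c(6, 12, 25), sadness = 1, fear = 1,
                         anger = 1, surprise = 1, disgust = 1, neutral = 4)),
    "neutral"
  )
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# custom prototypes",
    "happiness: 6, 12, 25",
    "sadness: 1, 4, 15",
    "fear: 1, 2, 4, 5, 20, 26",
    "anger: 4, 5, 7, 23",
    "surprise: 1, 2, 5, 26",
    "disgust: 9, 15, 16",
    "neutral:"
  ), path)
  tab <- read_prototype_table(path)
  expect_equal(tab$prototypes$anger, c(4L, 5L, 7L, 23L))
  expect_equal(tab$prototypes$neutral, integer(0))
})
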