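test_that("contingency reproduces the hand-counted 5-voxel table", {
  gt <- array(c(1L, 1L, 1L, 2L, 2L, 0L), c(1, 1, 6))
  pred <- array(c(1L, 1L, 2L, 2L, 2L, 3L), c(1, 1, 6))
  tab <- contingency(gt, pred, "instance", foreground_restricted = TRUE)
  expect_equal(tab$n_eval, 5)
  expect_equal(tab$p["1", "1"], 2 / 5)
  expect_equal(tab$p["2", "1"], 1 / 5)
  expect_equal(tab$p["2", "2"], 2 / 5)
  expect_equal(sum(tab$p), 1)
  expect_equal(unname(tab$s), unname(rowSums(tab$p)))

  r <- rand_score(tab, 0.5)
  expect_equal(r$score, 9 / 13)
  # harmonic-mean identity between the score and its split/merge limits
  expect_equal(1 / r$score, 0.5 / r$split + 0.5 / r$merge)
})

test_that("identical volumes score exactly 1 and p is diagonal", {
  v <- random_label_volume(c(6, 8, 8), 4, seed = 3)
  tab <- contingency(v, v, "instance")
  offdiag <- tab$p
  diag(offdiag) <- 0
  expect_true(all(offdiag == 0))
  for (a in c(0, 0.5, 1)) {
    expect_equal(rand_score(tab, a)$score, 1)
  }
})

test_that("rand_score is invariant to relabeling either volume", {
  withr::local_seed(11)
  gt <- random_label_volume(c(5, 6, 6), 4, seed = 5)
  pred <- random_label_volume(c(5, 6, 6), 4, seed = 6)
  base <- rand_score(contingency(gt, pred, "instance"), 0.5)$score
  for (i in 1:10) {
    perm <- c(0L, sample(1:4) * 10L)
    gt2 <- array(perm[gt + 1L], dim(gt))
    perm2 <- c(0L, sample(1:4) + 7L)
    pred2 <- array(perm2[pred + 1L], dim(pred))
    expect_equal(rand_score(contingency(gt2, pred2, "instance"), 0.5)$score,
                 base)
  }
})

test_that("the score at alpha 0.5 lies between the split and merge limits", {
  for (s in 1:20) {
    gt <- random_label_volume(c(5, 5, 5), 3, seed = 100 + s)
    pred <- random_label_volume(c(5, 5, 5), 3, seed = 200 + s)
    r <- rand_score(contingency(gt, pred, "instance"), 0.5)
    expect_gte(r$score, min(r$split, r$merge) - 1e-12)
    expect_lte(r$score, max(r$split, r$merge) + 1e-12)
  }
})

test_that("merge errors lower the merge limit; split errors the split limit", {
  for (s in 1:10) {
    gt <- random_label_volume(c(5, 5, 5), 3, seed = 300 + s)
    if (length(setdiff(unique(as.vector(gt)), 0L)) < 2) next
    pred <- gt  # perfect prediction, then corrupt it
    # collapsing every predicted object into one is a pure merge error:
    # pairs predicted-same (sum s^2) inflate, so the alpha -> 1 limit drops
    merged <- array(as.integer(pred > 0), dim(pred))
    merge_before <- rand_score(contingency(gt, pred, "instance"), 0.5)$merge
    merge_after <- rand_score(contingency(gt, merged, "instance"), 0.5)$merge
    expect_lt(merge_after, merge_before)
    # shattering each object in half is a pure split error: pairs that are
    # same in the ground truth separate, so the alpha -> 0 limit drops
    shattered <- pred
    odd <- slice.index(pred, 3) %% 2 == 1
    shattered[odd & pred > 0] <- shattered[odd & pred > 0] + 100L
    split_before <- rand_score(contingency(gt, pred, "instance"), 0.5)$split
    split_after <- rand_score(contingency(gt, shattered, "instance"), 0.5)$split
    expect_lt(split_after, split_before)
  }
})

test_that("semantic mode collapses both volumes to binary before counting", {
  gt <- array(c(0L, 5L, 9L, 5L), c(1, 2, 2))
  pred <- array(c(0L, 2L, 2L, 0L), c(1, 2, 2))
  tab <- contingency(gt, pred, "semantic")
  expect_equal(dim(tab$p), c(2L, 1L))  # pred {0,1} x gt {1} after restriction
  expect_equal(tab$n_eval, 3)
  expect_error(contingency(array(0L, c(1, 2, 2)), pred, "semantic"),
               "all background")
})

test_that("semantic overlap trio matches direct formula evaluation", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(1, 1, 4))
  expect_equal(unname(semantic_overlap(a, a)), c(1, 1, 1))
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(1, 1, 4))
  expect_equal(unname(semantic_overlap(a, b)), c(1 / 3, 1 / 2, -1))
  disj <- array(c(FALSE, FALSE, TRUE, TRUE), c(1, 1, 4))
  ov <- semantic_overlap(a, disj)
  expect_equal(unname(ov[1:2]), c(0, 0))
  expect_equal(unname(ov[3]), -Inf)
  expect_error(semantic_overlap(a & FALSE, b & FALSE), "undefined")
})
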