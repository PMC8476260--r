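mk_stack <- function(vote_rows, d = c(4, 4, 2)) {
  # vote_rows: R x n matrix of 0/1 votes laid out over a small grid
  stopifnot(ncol(vote_rows) == prod(d))
  decision_stack(lapply(seq_len(nrow(vote_rows)), function(j)
    labelmap(array(vote_rows[j, ], d))))
}

test_that("majority vote follows the strict-majority and tie rules", {
  n <- prod(c(4, 4, 2))
  v <- rbind(rep(1, n), rep(1, n), rep(0, n))  # votes (1,1,0) everywhere
  expect_true(all(majority_vote(mk_stack(v))$fused$voxels == 1))
  v2 <- rbind(rep(1, n), rep(0, n), rep(0, n))
  expect_true(all(majority_vote(mk_stack(v2))$fused$voxels == 0))
  # even R ties go to background
  v3 <- rbind(rep(1, n), rep(0, n))
  expect_true(all(majority_vote(mk_stack(v3))$fused$voxels == 0))
  v10 <- rbind(matrix(1, 5, n), matrix(0, 5, n))
  expect_true(all(majority_vote(mk_stack(v10))$fused$voxels == 0))
  # R = 1 returns the single input map
  set.seed(2)
  single <- labelmap(random_mask(c(5, 5, 5)))
  expect_identical(majority_vote(decision_stack(list(single)))$fused$voxels,
                   single$voxels)
})

test_that("majority vote equals exhaustive per-voxel enumeration", {
  for (R in c(3, 5)) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), R)))  # all 2^R rows
    d <- c(nrow(patterns), 1, 1)
    stack <- decision_stack(lapply(seq_len(R), function(j)
      labelmap(array(patterns[, j], d))))
    fused <- majority_vote(stack)$fused$voxels
    want <- apply(patterns, 1, function(v) as.integer(sum(v) > R / 2))
    expect_identical(as.vector(fused), want)
  }
})

test_that("fusers are invariant to the atlas order", {
  set.seed(4)
  truth <- labelmap(array(0L, c(12, 12, 8)))
  truth$voxels[4:9, 4:9, 3:6] <- 1L
  stack <- simulate_raters(truth, 0.85, 0.9, R = 6, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  stack_p <- decision_stack(stack$decisions[perm], stack$atlas_ids[perm])
  expect_identical(majority_vote(stack)$fused$voxels,
                   majority_vote(stack_p)$fused$voxels)
  s1 <- staple(stack); s2 <- staple(stack_p)
  expect_lt(max(abs(s1$posterior - s2$posterior)), 1e-10)
  f1 <- simple_fuse(stack); f2 <- simple_fuse(stack_p)
  expect_identical(f1$fused$voxels, f2$fused$voxels)
})

test_that("staple posteriors respect unanimity and perfect raters", {
  set.seed(6)
  truth <- labelmap(array(0L, c(10, 10, 10)))
  truth$voxels[3:7, 3:7, 3:7] <- 1L
  noisy <- simulate_raters(truth, 0.9, 0.9, R = 5, seed = 2)
  res <- staple(noisy, roi_dilate = Inf)
  expect_true(all(res$posterior >= 0 & res$posterior <= 1))
  unanimous <- Reduce(`&`, lapply(noisy$decisions, function(l) l$voxels == 1))
  expect_true(all(res$posterior[unanimous] > 0.99))
  # raters identical to a reference mask drive p, q to the boundary
  perfect <- decision_stack(list(truth, truth, truth))
  res2 <- staple(perfect, roi_dilate = Inf)
  expect_true(all(res2$performance$p >= 0.999))
  expect_true(all(res2$performance$q >= 0.999))
  expect_identical(res2$fused$voxels, truth$voxels)
})

test_that("staple EM log-likelihood is non-decreasing", {
  truth <- labelmap(array(0L, c(15, 15, 10)))
  truth$voxels[4:11, 4:11, 3:8] <- 1L
  stack <- simulate_raters(truth, 0.8, 0.85, R = 8, seed = 14)
  res <- staple(stack, roi_dilate = Inf)
  expect_true(all(diff(res$audit$loglik) > -1e-9))
})

test_that("staple requires a valid stack", {
  one <- decision_stack(list(labelmap(array(0:1, c(4, 4, 2)))))
  expect_error(staple(one), "at least 2")
  empties <- decision_stack(list(labelmap(array(0L, c(4, 4, 2))),
                                 labelmap(array(0L, c(4, 4, 2)))))
  expect_error(staple(empties), "foreground")
})

test_that("simple fusion discards an inverted atlas in round one", {
  set.seed(5)
  truth <- labelmap(array(0L, c(12, 12, 8)))
  truth$voxels[4:9, 4:9, 3:6] <- 1L
  good <- simulate_raters(truth, 0.95, 0.97, R = 9, seed = 3)
  inverted <- labelmap(1L - truth$voxels)
  stack <- decision_stack(c(good$decisions, list(inverted)),
                          c(good$atlas_ids, "inverted"))
  res <- simple_fuse(stack)
  r1 <- res$audit$trail[res$audit$trail$round == 1, ]
  expect_true(r1$discarded[r1$atlas_id == "inverted"])
  expect_false(any(r1$discarded[r1$atlas_id != "inverted"]))
  expect_false("inverted" %in% res$audit$kept)
})

test_that("simple with alpha = Inf never discards and equals majority vote", {
  truth <- labelmap(array(0L, c(10, 10, 6)))
  truth$voxels[3:7, 3:7, 2:5] <- 1L
  stack <- simulate_raters(truth, 0.8, 0.9, R = 7, seed = 8)
  res <- simple_fuse(stack, alpha = Inf)
  expect_identical(res$fused$voxels, majority_vote(stack)$fused$voxels)
  expect_false(any(res$audit$trail$discarded))
  # all-identical stacks are a fixed point with zero discards
  same <- decision_stack(lapply(1:5, function(i) truth))
  res2 <- simple_fuse(same)
  expect_identical(res2$fused$voxels, truth$voxels)
  expect_false(any(res2$audit$trail$discarded))
})

test_that("degenerate stacks are rejected", {
  empt <- lapply(1:4, function(i) labelmap(array(0L, c(4, 4, 2))))
  expect_error(simple_fuse(decision_stack(empt)), "empty")
  a <- labelmap(array(0L, c(4, 4, 2)))
  b <- labelmap(array(0L, c(4, 4, 3)))
  expect_error(decision_stack(list(a, b)), "identical")
})
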