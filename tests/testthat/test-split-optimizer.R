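test_that("phase 1 finds the certified maximum coverage", {
  # saturation: every image contains all classes
  pool <- make_pool(list(i1 = c(A = 1, B = 1), i2 = c(A = 1, B = 2),
                         i3 = c(A = 2, B = 1)))
  p1 <- phase1_max_coverage(pool, n_support = 2)
  expect_equal(p1$cov_star, 2L * 2L)

  # hand-enumerable singleton case: only i2/i4 cover both classes
  pool <- make_pool(list(i1 = c(A = 1), i2 = c(A = 1, B = 1),
                         i3 = c(B = 1), i4 = c(A = 1, B = 1)))
  p1 <- phase1_max_coverage(pool, n_support = 1)
  expect_equal(p1$cov_star, 2L)
  expect_true(p1$support_ids %in% c("i2", "i4"))

  # brute-force over all pairs of a random 6-image pool
  for (seed in 1:10) {
    pool <- random_pool(6, seed = seed)
    prob_counts <- lapply(pool$images$image_id, function(id) {
      length(unique(pool$boxes$class[pool$boxes$image_id == id]))
    })
    pairs <- utils::combn(6, 2, simplify = FALSE)
    best <- max(vapply(pairs, function(p) {
      sum(unlist(prob_counts)[p])
    }, numeric(1)))
    expect_equal(phase1_max_coverage(pool, 2)$cov_star, best)
  }

  expect_error(phase1_max_coverage(pool, 99), "exceeds pool size")
})

test_that("phase 2 maximizes the scalarized objective at locked coverage", {
  # worked singleton example: totals A=4, B=6, w_A=1/4, w_B=1/6, lambda=1.
  # Cov* = 2 restricts to {i2, i4}; obj(i2) = w_A*3 + w_B*5 - 1*2 = -5/12,
  # obj(i4) = w_A*2 + w_B*4 - 1*4 = -17/6, so i2 wins.
  pool <- make_pool(list(i1 = c(A = 1), i2 = c(A = 1, B = 1),
                         i3 = c(B = 3), i4 = c(A = 2, B = 2)))
  p2 <- phase2_refine(pool, n_support = 1, cov_star = 2, lambda = 1)
  expect_equal(p2$support_ids, "i2")
  expect_equal(p2$objective, 1 / 4 * 3 + 1 / 6 * 5 - 2, tolerance = 1e-12)
  expect_equal(p2$cov_star, 2L)

  # lambda = 0, single-class pool: reduces to keeping box-rich images in the
  # reference side, i.e. selecting the n_support images with fewest boxes
  pool <- make_pool(list(i1 = c(A = 5), i2 = c(A = 1), i3 = c(A = 3),
                         i4 = c(A = 2)))
  p2 <- phase2_refine(pool, n_support = 2, cov_star = 2, lambda = 0)
  expect_setequal(p2$support_ids, c("i2", "i4"))
})

test_that("phase 2 equals exhaustive enumeration on small pools", {
  for (seed in 1:15) {
    pool <- random_pool(7, n_classes = 3, seed = seed + 100)
    n_sup <- 3
    cov_star <- phase1_max_coverage(pool, n_sup)$cov_star
    p2 <- phase2_refine(pool, n_sup, cov_star, lambda = 1)
    # independent subset oracle
    ids <- pool$images$image_id
    d <- vapply(ids, function(id) {
      length(unique(pool$boxes$class[pool$boxes$image_id == id]))
    }, numeric(1))
    totals <- table(factor(pool$boxes$class, levels = pool$classes))
    w <- 1 / as.numeric(totals)
    names(w) <- pool$classes
    objs <- vapply(utils::combn(length(ids), n_sup, simplify = FALSE),
                   function(sel) {
      if (sum(d[sel]) != cov_star) return(-Inf)
      sup_boxes <- pool$boxes[pool$boxes$image_id %in% ids[sel], ]
      s <- table(factor(sup_boxes$class, levels = pool$classes))
      r <- as.numeric(totals) - as.numeric(s)
      sum(w * r) - 1 * sum(s)
    }, numeric(1))
    expect_equal(p2$objective, max(objs), tolerance = 1e-9)
  }
})

test_that("optimizer equals the brute-force oracle on small pools", {
  for (seed in 1:30) {
    pool <- random_pool(6, n_classes = 3, sources = c("s1", "s2"),
                        seed = seed)
    cfg <- split_config(n_support = 2, n_test = 4, trials = 5,
                        base_seed = seed)
    opt <- optimize_split(pool, cfg)
    bf <- brute_force_split(pool, cfg)
    expect_equal(opt$per_source$cov_star, bf$per_source$cov_star)
    expect_equal(opt$per_source$phase2_objective,
                 bf$per_source$phase2_objective, tolerance = 1e-9)
  }
})

test_that("splits are exact disjoint partitions with requested sizes", {
  for (seed in 1:5) {
    pool <- random_pool(8, sources = c("a", "b"), seed = seed + 50)
    cfg <- split_config(n_support = 3, n_test = 5, trials = 3,
                        base_seed = seed)
    sp <- optimize_split(pool, cfg)
    a <- sp$assignment
    for (src in c("a", "b")) {
      sup <- a$image_id[a$source == src & a$split == "support"]
      tst <- a$image_id[a$source == src & a$split == "test"]
      expect_length(sup, 3)
      expect_length(tst, 5)
      expect_length(intersect(sup, tst), 0)
      expect_setequal(c(sup, tst),
                      pool$images$image_id[pool$images$source == src])
    }
    # phase 2 never degrades coverage: recompute on the final assignment
    for (src in c("a", "b")) {
      sup <- a$image_id[a$source == src & a$split == "support"]
      cov <- sum(vapply(sup, function(id) {
        length(unique(pool$boxes$class[pool$boxes$image_id == id]))
      }, numeric(1)))
      expect_equal(cov, sp$per_source$cov_star[sp$per_source$source == src])
    }
  }
})

test_that("optimization is deterministic given the base seed", {
  pool <- random_pool(8, sources = c("a", "b"), seed = 7)
  cfg <- split_config(n_support = 3, n_test = 5, trials = 10, base_seed = 99)
  s1 <- optimize_split(pool, cfg)
  s2 <- optimize_split(pool, cfg)
  expect_identical(s1$assignment, s2$assignment)
  expect_identical(s1$winning_trial, s2$winning_trial)
  expect_equal(glance(s1), glance(s2))
})

test_that("coverage never decreases with a larger support budget", {
  for (seed in 1:8) {
    pool <- random_pool(6, seed = seed + 200)
    covs <- vapply(1:5, function(k) {
      phase1_max_coverage(pool, k)$cov_star
    }, integer(1))
    expect_true(all(diff(covs) >= 0))
  }
})

test_that("degenerate repetition and ties resolve to the earliest trial", {
  # T = 1 equals the single two-phase solve
  pool <- random_pool(6, seed = 31)
  cfg1 <- split_config(n_support = 2, n_test = 4, trials = 1, base_seed = 5)
  sp <- optimize_split(pool, cfg1)
  ordering <- withr::with_seed(5, sample.int(6))
  p1 <- phase1_max_coverage(pool, 2, ordering)
  p2 <- phase2_refine(pool, 2, p1$cov_star, lambda = 1, ordering = ordering)
  expect_setequal(support_ids(sp), p2$support_ids)

  # identical images: every trial yields the same score, earliest trial wins
  pool <- make_pool(list(i1 = c(A = 1, B = 2), i2 = c(A = 1, B = 2),
                         i3 = c(A = 1, B = 2), i4 = c(A = 1, B = 2)))
  sp <- optimize_split(pool, split_config(n_support = 1, n_test = 3,
                                          trials = 20, base_seed = 0))
  expect_equal(sp$winning_trial, 0L)
})

test_that("per-class support floors are honoured or rejected", {
  # unconstrained optimum takes the cheap single-class image; the floor on B
  # forces a B box into the support
  pool <- make_pool(list(i1 = c(A = 1), i2 = c(A = 1), i3 = c(A = 3, B = 2),
                         i4 = c(A = 4, B = 1)))
  cfg0 <- split_config(n_support = 2, n_test = 2, trials = 3, base_seed = 1)
  cfg1 <- split_config(n_support = 2, n_test = 2, trials = 3, base_seed = 1,
                       min_support_boxes_per_class = 1)
  sp0 <- optimize_split(pool, cfg0)
  sp1 <- optimize_split(pool, cfg1)
  counts1 <- class_box_counts(pool, support_ids(sp1))
  expect_true(all(counts1$n_boxes >= 1))
  bf1 <- brute_force_split(pool, cfg1)
  expect_equal(sp1$per_source$phase2_objective,
               bf1$per_source$phase2_objective, tolerance = 1e-9)
  expect_gte(sp0$per_source$phase2_objective,
             sp1$per_source$phase2_objective - 1e-12)

  # infeasible floor names the class (A: best single image holds 4 < 5)
  expect_error(
    optimize_split(pool, split_config(n_support = 1, n_test = 3, trials = 2,
                                      min_support_boxes_per_class = 5)),
    "infeasible.*'A'")
})

test_that("pool size mismatches are configuration errors", {
  pool <- random_pool(6, seed = 1)
  expect_error(optimize_split(pool, split_config(n_support = 2, n_test = 2,
                                                 trials = 1)),
               "expected")
  expect_error(brute_force_split(pool, split_config(n_support = 2,
                                                    n_test = 2)),
               "expected")
})

test_that("brute force refuses combinatorially large instances", {
  pool <- random_pool(30, seed = 2)
  expect_error(brute_force_split(pool, split_config(n_support = 15,
                                                    n_test = 15)),
               "combinatorial bound")
})
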