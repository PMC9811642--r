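# Coordination-shell cluster detection and size-distribution tracking.

test_that("contact clusters match trivially constructed frames", {
  cut <- cutoff_table("Ca-Oc" = 0.34)
  # two ions at 0.30 nm form one cluster of two
  fr <- traj_frame(rbind(c(1, 1, 1), c(1.3, 1, 1)), c("Ca", "Oc"), c(4, 4, 4))
  ca <- find_clusters(fr, cut)
  expect_equal(unname(sort(ca$sizes)), 2L)
  # everything beyond the cutoff stays a singleton
  fr2 <- traj_frame(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)),
                    c("Ca", "Oc", "Ca"), c(6, 6, 6))
  expect_equal(unname(find_clusters(fr2, cut)$sizes), c(1L, 1L, 1L))
  # species pair without a cutoff entry never bonds
  fr3 <- traj_frame(rbind(c(1, 1, 1), c(1.2, 1, 1)), c("Ca", "Ca"), c(4, 4, 4))
  expect_equal(unname(find_clusters(fr3, cut)$sizes), c(1L, 1L))
  # minimum-image contact across the boundary is honoured
  fr4 <- traj_frame(rbind(c(0.05, 1, 1), c(3.95, 1, 1)), c("Ca", "Oc"),
                    c(4, 4, 4))
  expect_equal(unname(find_clusters(fr4, cut)$sizes), 2L)
  # empty frame
  fr5 <- traj_frame(matrix(numeric(0), 0, 3), character(0), c(4, 4, 4))
  expect_equal(find_clusters(fr5, cut)$n_ions, 0L)
})

test_that("a carbonate counts as one ion however many atoms touch", {
  # carbonate with two oxygens near the same Ca: still a cluster of 2 ions
  co3 <- rbind(c(1.30, 1, 1), c(1.429, 1, 1), c(1.2355, 1.1117, 1),
               c(1.2355, 0.8883, 1))
  fr <- traj_frame(rbind(c(1, 1, 1), co3), c("Ca", "Cc", "Oc", "Oc", "Oc"),
                   c(5, 5, 5), mol = c(1, 2, 2, 2, 2))
  ca <- find_clusters(fr, cutoff_table("Ca-Oc" = 0.45))
  expect_equal(ca$n_ions, 2L)
  expect_equal(unname(ca$sizes), 2L)
  expect_setequal(ca$unit_species, c("Ca", "CO3"))
})

test_that("planted clusters are recovered exactly and match a BFS oracle", {
  pl <- gen_planted_clusters(sizes = c(5, 17, 40), n_singletons = 30,
                             seed = 3)
  ca <- find_clusters(pl$frame, pl$cutoffs)
  expect_equal(sort(unname(ca$sizes)), pl$truth)
  expect_equal(sum(ca$sizes), ca$n_ions)   # partition property
  # property check: random frames against brute-force BFS on the same graph
  for (seed in 1:100) {
    n <- sample(5:200, 1)
    fr <- random_ion_frame(n, box_edge = 3, seed = seed)
    cut <- cutoff_table("Ca-Oc" = 0.4, "Ca-Ca" = 0.3, "Oc-Oc" = 0.35)
    got <- find_clusters(fr, cut)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cc <- pair_cutoff(cut, fr$species[i], fr$species[j])
        if (!is.na(cc) &&
            mic_dist_oracle(fr$positions[i, ], fr$positions[j, ],
                            fr$box) < cc) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
    comp <- bfs_cluster_oracle(adj)
    # same partition: identical co-membership relations
    expect_identical(outer(got$cluster, got$cluster, "=="),
                     outer(comp, comp, "=="))
    expect_equal(sum(got$sizes), n)
  }
})

test_that("enlarging a cutoff never increases the number of clusters", {
  fr <- random_ion_frame(120, box_edge = 2.5, seed = 42)
  n_prev <- Inf
  for (cc in c(0.2, 0.3, 0.4, 0.5)) {
    cut <- cutoff_table("Ca-Oc" = cc, "Ca-Ca" = cc, "Oc-Oc" = cc)
    n_now <- length(find_clusters(fr, cut)$sizes)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("size distributions count ions and clusters consistently", {
  pl <- gen_planted_clusters(sizes = c(10, 40), seed = 5)
  ca <- find_clusters(pl$frame, pl$cutoffs)
  s_ion <- size_distribution(list(ca), weighting = "ion")
  expect_equal(s_ion$P[1, 10], 0.2)
  expect_equal(s_ion$P[1, 40], 0.8)
  expect_equal(rowSums(s_ion$P), 1)
  # cluster-count weighting interconverts with ion weighting via s
  s_cl <- size_distribution(list(ca), weighting = "cluster")
  s_vec <- s_cl$sizes
  conv <- s_cl$P[1, ] * s_vec
  conv <- conv / sum(conv)
  expect_equal(conv, s_ion$P[1, ])
  # degenerate cases
  singl <- gen_planted_clusters(n_singletons = 12, seed = 2)
  P1 <- size_distribution(list(find_clusters(singl$frame,
                                             singl$cutoffs)))$P
  expect_equal(P1[1, 1], 1)
  one <- gen_planted_clusters(sizes = 20, seed = 9)
  Pn <- size_distribution(list(find_clusters(one$frame, one$cutoffs)))$P
  expect_equal(Pn[1, 20], 1)
})

test_that("largest-cluster tracking reports sizes and first passage", {
  # synthetic growth: sizes 2,4,...,14 out of 20 ions, crossing 50% at t=7
  frames <- lapply(1:7, function(t) {
    pl <- gen_planted_clusters(sizes = 2 * t, n_singletons = 20 - 2 * t,
                               seed = t)
    a <- find_clusters(pl$frame, pl$cutoffs)
    a$time <- t
    a
  })
  ser <- size_distribution(frames)
  tr <- largest_cluster_track(ser, threshold = 0.5)
  expect_equal(tr$largest, seq(2L, 14L, by = 2L))
  expect_true(tr$crossed)
  expect_equal(tr$first_passage, 6)   # 12/20 = 60% first exceeds 50%
  # never crossing is flagged absent
  tr2 <- largest_cluster_track(ser, threshold = 0.9)
  expect_false(tr2$crossed)
  expect_true(is.na(tr2$first_passage))
  expect_error(largest_cluster_track(ser, threshold = 0), "0, 1")
  # constant singleton series stays at 1
  singl <- lapply(1:3, function(t) {
    pl <- gen_planted_clusters(n_singletons = 8, seed = t)
    a <- find_clusters(pl$frame, pl$cutoffs); a$time <- t; a
  })
  expect_equal(largest_cluster_track(size_distribution(singl))$largest,
               rep(1L, 3))
})

test_that("replicate averaging demands matching grids and averages pointwise", {
  mk <- function(seed) {
    frames <- lapply(1:3, function(t) {
      pl <- gen_planted_clusters(sizes = c(4, 6), n_singletons = 10,
                                 seed = seed * 10 + t)
      a <- find_clusters(pl$frame, pl$cutoffs); a$time <- t; a
    })
    size_distribution(frames)
  }
  s1 <- mk(1); s2 <- mk(2)
  avg <- average_size_distributions(list(s1, s2))
  expect_equal(avg$P, (s1$P + s2$P) / 2)
  expect_equal(avg$replicates, 2L)
  s3 <- mk(3); s3$times <- s3$times + 0.5
  expect_error(average_size_distributions(list(s1, s3)), "mismatch")
})
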