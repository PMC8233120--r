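two_control_cohort <- function(atlas, v1, v2, modality = "FC") {
  n <- nrow(atlas)
  ids <- c("c1", "c2")
  Y <- rbind(v1, v2)
  rownames(Y) <- ids
  subjects <- data.frame(subject_id = ids, group = "control",
                         age = c(30, 50), stringsAsFactors = FALSE)
  edges <- list(); edges[[modality]] <- Y
  cohort(atlas, subjects, edges)
}

test_that("topology averaging uses present edges only", {
  atlas <- mini_atlas()
  ne <- nrow(atlas) * (nrow(atlas) - 1) / 2
  v1 <- rep(0.2, ne); v2 <- rep(0.4, ne)
  coh <- two_control_cohort(atlas, v1, v2)
  topo <- build_topology(coh, "FC")
  expect_equal(unname(topo$left[1, 2]), 0.3)

  # SC: edge absent in one control -> mean of the present one; absent in
  # all -> absent in T
  s1 <- exp(v1); s2 <- exp(v2)
  s1[1] <- NA
  s1[2] <- NA; s2[2] <- NA
  cohs <- two_control_cohort(atlas, s1, s2, "SC")
  ts <- build_topology(cohs, "SC")
  expect_equal(unname(ts$left[1, 2]), exp(0.4))
  expect_true(is.na(ts$left[1, 3]))
})

test_that("model vectors read the seed row and RSN ignores the seed", {
  atlas <- mini_atlas()
  ne <- nrow(atlas) * (nrow(atlas) - 1) / 2
  set.seed(2)
  v <- stats::rnorm(ne)
  coh <- two_control_cohort(atlas, v, v)
  topo <- build_topology(coh, "FC")
  seed <- anterior_hippocampus(atlas, "left")
  mv <- model_vector(topo, seed)
  expect_equal(nrow(mv), nrow(topo$left) - 1)
  expect_false(seed %in% mv$region_id)
  full <- edges_to_matrix(v, nrow(atlas))
  expect_equal(mv$value, full[seed + 1, mv$region_id + 1])

  rsn <- build_topology(coh, "RSN")
  mv1 <- model_vector(rsn, anterior_hippocampus(atlas, "left"))
  mv2 <- model_vector(rsn, anterior_hippocampus(atlas, "right"))
  expect_equal(mv1$value[mv1$region_id %in% mv2$region_id],
               mv2$value[mv2$region_id %in% mv1$region_id])
})

test_that("binning follows each topology's ranking convention", {
  # FC: descending absolute value
  mv <- structure(data.frame(region_id = 0:3,
                             value = c(-0.9, 0.5, -0.1, 0.05)),
                  kind = "FC", seed = 99L,
                  class = c("model_vector", "data.frame"))
  b <- bin_edges(mv, 2)
  expect_equal(sort(b[[1]]), c(0, 1))
  expect_equal(sort(b[[2]]), c(2, 3))

  # LEN: ascending
  mvl <- structure(data.frame(region_id = 0:3, value = c(4, 1, 3, 2)),
                   kind = "LEN", seed = 99L,
                   class = c("model_vector", "data.frame"))
  bl <- bin_edges(mvl, 2)
  expect_equal(sort(bl[[1]]), c(1, 3))

  # SC: descending, missing edges excluded before chunking
  mvs <- structure(data.frame(region_id = 0:4,
                              value = c(5, NA, 3, 8, 1)),
                   kind = "SC", seed = 99L,
                   class = c("model_vector", "data.frame"))
  bs <- bin_edges(mvs, 2)
  expect_equal(sort(unlist(bs)), c(0, 2, 3, 4))
  expect_equal(sort(bs[[1]]), c(0, 3))
})

test_that("bin sizes are as equal as possible with earlier bins larger", {
  expect_equal(netprog:::chunk_sizes(54, 5), c(11, 11, 11, 11, 10))
  expect_equal(netprog:::chunk_sizes(54, 4), c(14, 14, 13, 13))
  expect_equal(netprog:::chunk_sizes(10, 2), c(5, 5))
  expect_error(netprog:::chunk_sizes(3, 5), "more bins")
})

test_that("default-atlas hippocampal binnings partition the seed edges", {
  coh <- shared_cohort()$norm
  atlas <- coh$atlas
  topo <- build_topology(coh, "LEN")
  b <- hippocampal_binnings(topo, atlas, 5)
  for (side in c("left", "right")) {
    expect_equal(lengths(b[[side]]), c(11, 11, 11, 11, 10))
    seed <- anterior_hippocampus(atlas, side)
    expect_equal(sort(unlist(b[[side]])),
                 sort(setdiff(hemisphere_regions(atlas, side), seed)))
  }
  # RSN bins: 10 bilateral edges per network
  rsn <- build_topology(coh, "RSN")
  br <- hippocampal_binnings(rsn, atlas)
  expect_equal(lengths(br$left), c(10, 10, 10, 10))
  expect_equal(atlas$rsn_label[br$left[[3]] + 1], rep(3L, 10))
})

test_that("binning is invariant to monotone transforms of the model vector", {
  set.seed(4)
  mv <- structure(data.frame(region_id = 0:20,
                             value = stats::runif(21, 10, 200)),
                  kind = "LEN", seed = 99L,
                  class = c("model_vector", "data.frame"))
  b1 <- bin_edges(mv, 4)
  mv2 <- mv; mv2$value <- log(mv2$value)
  expect_identical(unclass(bin_edges(mv2, 4))[1:4], unclass(b1)[1:4])
  # FC |.| ranking unaffected by sign flips
  mvf <- mv; attr(mvf, "kind") <- "FC"
  flip <- mvf; flip$value <- -flip$value
  expect_identical(unclass(bin_edges(flip, 4))[1:4],
                   unclass(bin_edges(mvf, 4))[1:4])
})

test_that("hemisphere topologies agree for mirrored synthetic controls", {
  coh <- shared_cohort()$norm
  for (kind in c("LEN", "FC")) {
    topo <- build_topology(coh, kind)
    l <- topo$left[upper.tri(topo$left)]
    r <- topo$right[upper.tri(topo$right)]
    ok <- !is.na(l) & !is.na(r)
    expect_gt(stats::cor(l[ok], r[ok]), 0.9)
  }
  # and the control-average LEN topology tracks the latent lengths
  truth <- shared_cohort()$sim$truth
  topo <- build_topology(coh, "LEN")
  D <- edges_to_matrix(truth$len_base, 109)
  ids <- topo$regions_left + 1
  est <- topo$left[upper.tri(topo$left)]
  lat <- D[ids, ids][upper.tri(topo$left)]
  ok <- !is.na(est)
  expect_gt(stats::cor(est[ok], lat[ok]), 0.9)
})
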