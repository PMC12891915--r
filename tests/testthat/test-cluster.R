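blob_fm <- function(centers, nPer = 20, sdv = 0.1, seed = 1,
                    group = NULL) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(nPer * ncol(centers), sd = sdv), nPer), 2,
          centers[i, ], `+`)))
  ids <- sprintf("s%03d", seq_len(nrow(X)))
  descs <- setNames(lapply(seq_len(nrow(X)), function(i) X[i, ]), ids)
  assembleFeatures(descs, scaling = "none",
                   group = if (!is.null(group)) setNames(group, ids))
}

test_that("k-means recovers well-separated blobs across seeds", {
  centers <- rbind(c(0, 0), c(5, 0))
  truth <- rep(1:2, each = 20)
  for (s in 1:10) {
    fm <- blob_fm(centers, seed = s)
    rep <- kmeansCluster(fm, 2, seed = s)
    lab <- clusterLabels(rep)
    agree <- max(mean(lab == truth), mean(lab == 3 - truth))
    expect_equal(agree, 1)
  }
})

test_that("inertia falls with k and vanishes on duplicated points", {
  fm <- blob_fm(rbind(c(0, 0), c(3, 3), c(0, 4)), seed = 2)
  i2 <- kmeansCluster(fm, 2, seed = 1)@inertia
  i5 <- kmeansCluster(fm, 5, seed = 1)@inertia
  i20 <- kmeansCluster(fm, 20, seed = 1)@inertia
  expect_gt(i2, i5)
  expect_gt(i5, i20)
  # duplicated points: inertia 0 at k = number of distinct points
  X <- rbind(c(0, 0), c(1, 1), c(2, 0))
  descs <- setNames(lapply(rep(1:3, each = 3), function(i) X[i, ]),
                    sprintf("d%d", 1:9))
  fmd <- assembleFeatures(descs, scaling = "none")
  expect_lt(kmeansCluster(fmd, 3, seed = 1)@inertia, 1e-12)
  expect_error(kmeansCluster(fm, 1, seed = 1), "2 <= k")
})

test_that("silhouette and elbow diagnostics find planted structure", {
  fm <- blob_fm(rbind(c(0, 0), c(6, 0), c(3, 6)), nPer = 15, seed = 3)
  ck <- chooseK(fm, 2:8, seed = 4)
  expect_equal(ck$recommendedK, 3L)
  expect_true(all(diff(ck$table$inertia) < 0))
  # a single blob has no structure: silhouette stays low
  fm1 <- blob_fm(matrix(0, 1, 5), nPer = 50, sdv = 1, seed = 5)
  ck1 <- chooseK(fm1, 2:6, seed = 5)
  expect_lt(max(ck1$table$silhouette), 0.4)
})

test_that("the group report tests each cluster one-vs-rest and in aggregate", {
  # planted frequency shift: treated spines over-populate blob 2
  set.seed(7)
  n <- 120
  grp <- rep(c("control", "treated"), each = n / 2)
  blob <- ifelse(grp == "control", rbinom(n / 2, 1, 0.2) + 1,
                 rbinom(n / 2, 1, 0.6) + 1)
  centers <- rbind(c(0, 0), c(8, 0))
  X <- centers[blob, ] + matrix(rnorm(2 * n, sd = 0.3), n)
  ids <- sprintf("s%03d", 1:n)
  fm <- assembleFeatures(setNames(lapply(1:n, function(i) X[i, ]), ids),
                         scaling = "none", group = setNames(grp, ids))
  rep <- clusterGroupReport(fm, 2, seed = 1)
  expect_equal(sum(rep@perCluster$nControl), n / 2)
  expect_equal(sum(rep@perCluster$pctControl), 100, tolerance = 0.01)
  expect_equal(sum(rep@perCluster$pctTreated), 100, tolerance = 0.01)
  expect_true(all(rep@perCluster$acP < 0.05))
  expect_lt(rep@chi2P, 0.001)
  expect_true(all(rep@perCluster$acPHolm >= rep@perCluster$acP))
  # determinism
  rep2 <- clusterGroupReport(fm, 2, seed = 1)
  expect_identical(clusterLabels(rep), clusterLabels(rep2))
  expect_identical(rep@perCluster, rep2@perCluster)
  row <- table1Row(rep, "blobs")
  expect_equal(row$n_clusters, 2)
  expect_equal(row$n_significant, 2)
})

test_that("group report preconditions are enforced", {
  fm <- blob_fm(rbind(c(0, 0), c(5, 5)), seed = 9)
  expect_error(clusterGroupReport(fm, 2), "no group")
  fm2 <- blob_fm(rbind(c(0, 0), c(5, 5)), seed = 9,
                 group = rep("control", 40))
  expect_error(clusterGroupReport(fm2, 2), "both groups")
})

test_that("representative spines are the nearest-to-centroid members", {
  fm <- blob_fm(rbind(c(0, 0), c(6, 6)), nPer = 12, seed = 11)
  rep <- kmeansCluster(fm, 2, seed = 2)
  reps <- representativeSpines(rep, fm, top = 3)
  expect_equal(lengths(reps), c(cluster_1 = 3L, cluster_2 = 3L))
  # brute-force oracle
  X <- featureMatrix(fm)
  for (cl in 1:2) {
    rows <- which(clusterLabels(rep) == cl)
    ctr <- colMeans(X[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(X[rows, , drop = FALSE], 2, ctr)^2))
    expect_equal(reps[[cl]], fm@spineIds[rows[order(d)][1:3]])
  }
  # top larger than the cluster returns the whole cluster
  repsAll <- representativeSpines(rep, fm, top = 99)
  expect_equal(sort(unlist(repsAll)), sort(fm@spineIds),
               ignore_attr = TRUE)
})

test_that("cluster reports serialize to JSON and back", {
  fm <- blob_fm(rbind(c(0, 0), c(5, 0)), seed = 13,
                group = rep(c("control", "treated"), 20))
  rep <- clusterGroupReport(fm, 2, seed = 3)
  p <- file.path(tempdir(), "report.json")
  writeClusterReport(rep, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$k, 2)
  expect_equal(back$chi2_p, rep@chi2P, tolerance = 1e-12)
  expect_equal(nrow(back$labels), 40)
})
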