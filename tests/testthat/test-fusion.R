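snv_toy_block <- function(n, p, name = "qepas") {
  m <- t(apply(matrix(stats::rnorm(n * p), n, p), 1, snv))
  feature_block(name, m, provenance = "snv()")
}

autoscaled_toy_block <- function(n, p, name = "ims") {
  b <- feature_block(name, matrix(stats::rnorm(n * p, 5), n, p))
  autoscale_apply(b, autoscale_fit(b))
}

test_that("low-level assembly concatenates blocks in a fixed order with provenance", {
  set.seed(8)
  ims <- autoscaled_toy_block(6, 500)
  qepas <- snv_toy_block(6, 300)
  rt <- stats::runif(6, 50, 60)
  out <- lldf_assemble(ims, qepas, rt)
  expect_equal(ncol(out$matrix), 801L)   # 500 + 300 + 1
  expect_equal(unname(out$matrix[, 801]), rt)  # RT is the documented last column
  expect_equal(out$matrix[, 1:500], ims$matrix, ignore_attr = TRUE)

  raw <- feature_block("ims", matrix(stats::rnorm(6 * 500), 6, 500))
  expect_error(lldf_assemble(raw, qepas, rt), "autoscale")
  expect_error(lldf_assemble(ims, feature_block("q", qepas$matrix), rt), "snv")
  expect_error(lldf_assemble(ims, snv_toy_block(5, 300), rt), "row counts")
})

test_that("per-block PCA retains the smallest count reaching the EV criterion", {
  set.seed(10)
  # variance along exactly one direction -> one component
  one_dir <- outer(stats::rnorm(20), c(1, 2, 3, 4))
  pca1 <- pca_blocks_fit(list(ims = feature_block("ims", one_dir)))
  expect_equal(pca1$fits$ims$n_components, 1L)

  # known eigenvalues via independent columns with chosen variances
  vars <- c(100, 10, 1, 0.5)  # cumEV: 0.897, 0.987, 0.9955 -> 3 components
  x <- sapply(seq_along(vars), function(j) stats::rnorm(2000, sd = sqrt(vars[j])))
  pca2 <- pca_blocks_fit(list(ims = feature_block("ims", x)), ev = 0.99)
  expect_equal(pca2$fits$ims$n_components, 3L)
  m <- pca2$fits$ims$n_components
  expect_gte(sum(pca2$fits$ims$explained_variance[1:m]), 0.99)
  expect_lt(sum(pca2$fits$ims$explained_variance[seq_len(m - 1)]), 0.99)

  # retained scores reconstruct >= 99% of the training variance
  f <- pca2$fits$ims
  xc <- sweep(x, 2, f$center)
  recon <- xc %*% f$loadings %*% t(f$loadings)
  expect_lte(sum((xc - recon)^2) / sum(xc^2), 0.01)
})

test_that("mid-level assembly concatenates per-block scores with raw RT", {
  set.seed(11)
  ims <- autoscaled_toy_block(8, 40)
  qepas <- snv_toy_block(8, 30)
  rt <- stats::runif(8, 50, 60)
  pca <- pca_blocks_fit(list(ims = ims, qepas = qepas), ev = 0.99)
  out <- mldf_assemble(ims, qepas, rt, pca)
  expect_equal(ncol(out$matrix),
               pca$fits$ims$n_components + pca$fits$qepas$n_components + 1L)
  expect_equal(unname(out$matrix[, ncol(out$matrix)]), rt)
  wrong <- snv_toy_block(8, 29)
  expect_error(mldf_assemble(ims, wrong, rt, pca), "does not match")
})

test_that("the one-class SVM wrapper is deterministic and honours tau semantics", {
  set.seed(12)
  x <- matrix(stats::rnorm(40 * 6, mean = 10, sd = 0.5), 40, 6)
  m1 <- ocsvm_fit(x, nu = 0.05)
  m2 <- ocsvm_fit(x, nu = 0.05)
  expect_identical(m1$train_decision, m2$train_decision)  # deterministic solver
  expect_gt(mean(m1$train_decision >= 0), 0.9)            # nu bounds training outliers

  centroid <- matrix(colMeans(x), 1)
  expect_true(ocsvm_classify(m1, centroid)$inlier)
  # the linear one-class boundary is a halfspace between the cloud and the
  # origin; the outlier probe sits far on the origin side
  far <- matrix(colMeans(x) - 100 * apply(x, 2, stats::sd), 1)
  res_far <- ocsvm_classify(m1, far)
  expect_lt(res_far$f, 0)
  expect_false(res_far$inlier)
  expect_true(ocsvm_classify(m1, far, threshold = -Inf)$inlier)  # tau = -Inf

  expect_error(ocsvm_fit(x[1, , drop = FALSE]), "at least 2")
  expect_error(ocsvm_fit(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(ocsvm_classify(m1, matrix(0, 1, 5)), "does not match")
})

test_that("inlier/outlier verdicts agree with an independent one-class implementation", {
  skip_if_not_installed("kernlab")
  set.seed(13)
  x <- matrix(stats::rnorm(60 * 4, mean = 5, sd = 0.3), 60, 4)
  test_pts <- rbind(colMeans(x), colMeans(x) + 50)
  ours <- ocsvm_classify(ocsvm_fit(x, kernel = "rbf", nu = 0.1), test_pts)
  ref <- kernlab::ksvm(x, type = "one-svc", kernel = "rbfdot", nu = 0.1)
  theirs <- kernlab::predict(ref, test_pts)
  expect_equal(ours$inlier, as.logical(theirs))  # clear-cut points agree
})

test_that("lowering tau never converts a one-class positive into a negative", {
  set.seed(14)
  x <- matrix(stats::rnorm(30 * 5, 3), 30, 5)
  m <- ocsvm_fit(x)
  y <- matrix(stats::rnorm(50 * 5, 3, 2), 50, 5)
  base <- ocsvm_classify(m, y, threshold = 0)
  lower <- ocsvm_classify(m, y, threshold = -0.5)
  expect_true(all(lower$inlier[base$inlier]))
})

test_that("decision-level combination follows the any/all rules", {
  inl <- data.frame(f = 0.3, inlier = TRUE)
  outl <- data.frame(f = -0.4, inlier = FALSE)
  pos <- data.frame(dE = 1, dM = 1, positive = TRUE)
  neg <- data.frame(dE = 9, dM = 9, positive = FALSE)
  expect_true(hldf_combine(inl, pos, "any")$positive)
  expect_true(hldf_combine(inl, pos, "all")$positive)
  expect_true(hldf_combine(outl, pos, "any")$positive)
  expect_false(hldf_combine(outl, pos, "all")$positive)
  expect_false(hldf_combine(outl, neg, "any")$positive)
  expect_error(hldf_combine(NULL, pos), "missing IMS")
  expect_error(hldf_combine(inl, list(dE = 1)), "missing GC")
})

test_that("a fold's model reproduces its stored training decision values exactly", {
  ds <- small_corpus("dmmp", n = 3, seed = 31, concentrations = c(2.8, 50, 500))
  pipe <- train_pipeline(ds, "lldf", "dmmp")
  again <- predict_pipeline(pipe, ds)
  expect_equal(again$f, pipe$ocsvm$train_decision, tolerance = 1e-12)
})

test_that("fuse classifies a co-located pair and refuses a distant one", {
  ds <- study_corpus("dmmp")
  pipe <- train_pipeline(ds, "lldf", "dmmp")
  near <- generate_scene(
    list(list(template = templates()$dmmp, concentration = 50)),
    sensor_position(0, 0, 0), sensor_position(0.3, 0.3, 0.3), seed = 77)[[1]]
  verdict <- fuse(near$readings[[1]], near$readings[[2]], pipe)
  expect_s3_class(verdict, "fusion_verdict")
  expect_true(verdict$positive)
  expect_true(verdict$gate$fused)

  far <- generate_scene(
    list(list(template = templates()$dmmp, concentration = 50)),
    sensor_position(0, 0, 0), sensor_position(3, 0, 0), seed = 77)[[1]]
  err <- tryCatch(fuse(far$readings[[1]], far$readings[[2]], pipe),
                  chemfuse_gate_error = function(e) e)
  expect_s3_class(err, "chemfuse_gate_error")
  expect_false(err$decision$fused)

  # a non-target analyte pair is classified, and negative
  conf <- generate_scene(
    list(list(template = templates()$toluene, concentration = 50)),
    sensor_position(0, 0, 0), sensor_position(0.3, 0.3, 0.3), seed = 78)[[1]]
  v2 <- fuse(conf$readings[[1]], conf$readings[[2]], pipe)
  expect_false(v2$positive)
})
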