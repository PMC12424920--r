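fit_small <- function(seed = 91, k1 = 3L) {
  sim <- simulate_case_control(simulation_config(
    m = 300, n1 = 40, n0 = 40, k0 = 2, k1 = 2, seed = seed))
  list(sim = sim, fit = fit_paca(sim$pair, r = 2, k1 = k1))
}

test_that("export/project round-trip reproduces (z-scaled) training scores", {
  fs <- fit_small()
  for (idx in 1:3) {
    model <- export_score(fs$fit, idx)
    expect_identical(unname(model$weights),
                     unname(fs$fit$feature_loadings[, idx]))
    got <- project_score(model, fs$sim$pair$X)
    want <- as.vector(scale(fs$fit$case_scores[, idx]))
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
  expect_error(export_score(fs$fit, 4), "out of range")
})

test_that("projection aligns features by id and is affine-equivariant pre-z-scaling", {
  fs <- fit_small()
  model <- export_score(fs$fit, 1)
  X <- unclass(fs$sim$pair$X)
  shuffled <- X[sample(nrow(X)), ]
  expect_equal(project_score(model, shuffled), project_score(model, X))

  # all-zero cohort: identical score for every sample
  zero <- matrix(0, nrow(X), 4, dimnames = list(rownames(X), paste0("z", 1:4)))
  sz <- project_score(model, zero)
  expect_equal(unname(sz), rep(sz[[1]], 4))

  # adding a constant vector shifts all raw scores equally
  c_vec <- rnorm(nrow(X))
  s1 <- project_score(model, X) * model$normalization$sd + model$normalization$mean
  s2 <- project_score(model, X + c_vec) * model$normalization$sd + model$normalization$mean
  expect_equal(unname(s2 - s1), rep(sum(model$weights * c_vec), ncol(X)),
               tolerance = 1e-8)

  expect_error(project_score(model, X[-(1:5), ]), "missing 5 model feature")
})

test_that("scores transfer across cohorts sharing the latent structure", {
  recs <- numeric(10)
  for (i in 1:10) {
    cf <- simulation_config(m = 1000, n1 = 100, n0 = 100, k0 = 3, k1 = 1,
                            shared_scales = 5, case_scales = 2, seed = 400 + i)
    disc <- simulate_case_control(cf)
    repl <- simulate_case_control(
      simulation_config(m = 1000, n1 = 100, n0 = 100, k0 = 3, k1 = 1,
                        shared_scales = 5, case_scales = 2, seed = 500 + i),
      basis = disc$truth)
    fit <- fit_paca(disc$pair, r = 3, k1 = 1)
    scores <- project_score(export_score(fit, 1), repl$pair$X)
    recs[i] <- abs(cor(scores, repl$truth$Z_X1[1, ]))
  }
  expect_gte(median(recs), 0.8)
})

test_that("rank_features orders by |weight| with lexicographic tie-breaks", {
  model <- structure(list(
    feature_ids = c("f1", "f2", "f3"),
    weights = c(f1 = 0.1, f2 = -0.5, f3 = 0.3),
    centering = c(f1 = 0, f2 = 0, f3 = 0), scaling = NULL,
    component_index = 1L, normalization = list(mean = 0, sd = 1)
  ), class = "stratification_model")
  expect_equal(rank_features(model, 2)$feature_id, c("f2", "f3"))
  expect_setequal(rank_features(model, 3)$feature_id, model$feature_ids)

  # brute-force sort oracle on a random 100-feature model with ties
  set.seed(93)
  w <- round(rnorm(100), 1)
  ids <- sprintf("cg%03d", sample(100))
  model$feature_ids <- ids
  model$weights <- setNames(w, ids)
  model$centering <- setNames(numeric(100), ids)
  got <- rank_features(model, 100)
  oracle <- ids[order(-abs(w), ids, method = "radix")]
  expect_identical(got$feature_id, oracle)
})

test_that("phenotype consistency summarizes cross-cohort correlation agreement", {
  set.seed(95)
  sa <- setNames(rnorm(30), paste0("a", 1:30))
  sb <- setNames(rnorm(25), paste0("b", 1:25))
  pa <- cbind(self = sa, anti = -sa + rnorm(30, sd = 1e-8))
  pb <- cbind(self = sb, anti = sb)
  out <- phenotype_consistency(sa, sb, pa, pb)
  self_row <- out$per_phenotype[out$per_phenotype$phenotype == "self", ]
  anti_row <- out$per_phenotype[out$per_phenotype$phenotype == "anti", ]
  expect_equal(self_row$cor_a, 1, tolerance = 1e-8)
  expect_equal(self_row$cor_b, 1, tolerance = 1e-8)
  expect_equal(anti_row$cor_a, -1, tolerance = 1e-6)
  expect_equal(anti_row$cor_b, 1, tolerance = 1e-8)
  expect_equal(out$sign_agreement, 0.5)

  # sparse phenotype with < 3 paired observations is skipped with a warning
  pa2 <- cbind(pa, sparse = c(1, 2, rep(NA, 28)))
  pb2 <- cbind(pb, sparse = rnorm(25))
  expect_warning(out2 <- phenotype_consistency(sa, sb, pa2, pb2), "skipped")
  expect_false("sparse" %in% out2$per_phenotype$phenotype)

  expect_error(phenotype_consistency(sa, sb, pa[, 0, drop = FALSE], pb),
               "no phenotype shared")
})

test_that("a replicating phenotype shows same-sign correlations in both cohorts", {
  hits <- logical(20)
  for (i in 1:20) {
    cf1 <- simulation_config(m = 800, n1 = 80, n0 = 80, k0 = 3, k1 = 1,
                             seed = 600 + i)
    disc <- simulate_case_control(cf1)
    repl <- simulate_case_control(
      simulation_config(m = 800, n1 = 80, n0 = 80, k0 = 3, k1 = 1,
                        seed = 700 + i), basis = disc$truth)
    fit <- fit_paca(disc$pair, r = 3, k1 = 1)
    model <- export_score(fit, 1)
    sa <- project_score(model, disc$pair$X)
    sb <- project_score(model, repl$pair$X)
    set.seed(800 + i)
    pa <- cbind(ph = disc$truth$Z_X1[1, ] + rnorm(80, sd = sd(disc$truth$Z_X1)))
    rownames(pa) <- names(sa)
    pb <- cbind(ph = repl$truth$Z_X1[1, ] + rnorm(80, sd = sd(repl$truth$Z_X1)))
    rownames(pb) <- names(sb)
    out <- phenotype_consistency(sa, sb, pa, pb)
    hits[i] <- out$sign_agreement == 1
  }
  expect_gte(mean(hits), 0.9)
})

test_that("association filter keeps shifted features and calibrates under the null", {
  set.seed(97)
  n1 <- 20; n0 <- 20
  X <- matrix(rnorm(100 * n1), 100, n1)
  Y <- matrix(rnorm(100 * n0), 100, n0)
  X[1, ] <- X[1, ] + 10
  rownames(X) <- rownames(Y) <- sprintf("f%03d", 1:100)
  colnames(X) <- paste0("c", 1:n1); colnames(Y) <- paste0("k", 1:n0)
  pair <- case_control_pair(X, Y)
  out <- filter_features_by_association(pair, 0.01)
  expect_true("f001" %in% rownames(out$pair$X))
  expect_identical(rownames(out$pair$X), rownames(out$pair$Y))

  # threshold 1 retains everything
  all_kept <- filter_features_by_association(pair, 1)
  expect_identical(dim(all_kept$pair$X), dim(X))

  # type-I calibration: ~1% of pure-noise features survive p <= 0.01
  kept <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(1000 * 15), 1000, 15)
    Yn <- matrix(rnorm(1000 * 15), 1000, 15)
    rownames(Xn) <- rownames(Yn) <- sprintf("f%04d", 1:1000)
    colnames(Xn) <- paste0("c", 1:15); colnames(Yn) <- paste0("k", 1:15)
    sum(filter_features_by_association(case_control_pair(Xn, Yn),
                                       0.01)$p_values <= 0.01)
  }, numeric(1))
  expect_lt(abs(mean(kept) - 10), 3 * sqrt(1000 * 0.01 * 0.99 / 10))

  expect_error(filter_features_by_association(pair, 0), "\\(0, 1\\]")
  expect_error(filter_features_by_association(pair, 1.5), "\\(0, 1\\]")
})
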