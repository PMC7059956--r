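test_that("edge scores reproduce the tier weighting rules", {
  es1 <- compute_edge_scores(evidence_table("T", "g", "encode"))
  expect_equal(es1$scores["T", "g"], 0.5)
  es2 <- compute_edge_scores(evidence_table("T", "g", "tfacts"))
  expect_equal(es2$scores["T", "g"], 0.25)
  es3 <- compute_edge_scores(evidence_table("T", "g", "metacore_direct"))
  expect_equal(es3$scores["T", "g"], 2)
  # two of the three medium-confidence sources count 1 each...
  es4 <- compute_edge_scores(
    evidence_table(c("T", "T"), c("g", "g"), c("chea", "ecrbase")))
  expect_equal(es4$scores["T", "g"], 2)
  es5 <- compute_edge_scores(evidence_table(
    c("T", "T", "T"), c("g", "g", "g"),
    c("chea", "ecrbase", "metacore_unspecified")))
  expect_equal(es5$scores["T", "g"], 3)
  # ...but a single one contributes nothing from that tier
  es6 <- compute_edge_scores(evidence_table("T", "g", "chea"))
  expect_equal(es6$scores["T", "g"], 0)
  # tiers are additive across groups
  es7 <- compute_edge_scores(evidence_table(
    c("T", "T", "T", "T"), rep("g", 4),
    c("metacore_direct", "encode", "tfacts", "chea")))
  expect_equal(es7$scores["T", "g"], 2.75)
  # unrelated pairs do not interact
  es8 <- compute_edge_scores(evidence_table(
    c("T1", "T2"), c("g1", "g1"), c("chea", "ecrbase")))
  expect_equal(unname(es8$scores[, "g1"]), c(0, 0))
})

test_that("TF eligibility uses the known-target count boundary", {
  tfs <- c("T15", "T14")
  ev <- rbind(
    data.frame(tf = "T15", target = sprintf("g%02d", 1:15),
               tier = "metacore_direct"),
    data.frame(tf = "T14", target = sprintf("g%02d", 1:14),
               tier = "metacore_direct"))
  es <- compute_edge_scores(evidence_table(ev$tf, ev$target, ev$tier))
  sig <- sprintf("g%02d", 1:20)
  expect_equal(filter_eligible_tfs(es, sig), "T15")
  expect_setequal(filter_eligible_tfs(es, sig, min_targets = 14),
                  c("T14", "T15"))
  expect_error(filter_eligible_tfs(es, sig, min_targets = 16),
               "min_targets")
  # count matches a direct oracle on random fixtures
  sim <- generate_expression(n_genes = 60, n_true_tf = 2, n_decoy_tf = 6,
                             seed = 4)
  es2 <- sim$truth$edge_scores
  sig2 <- rownames(sim$expression$values)
  got <- filter_eligible_tfs(es2, sig2, min_targets = 20)
  want <- rownames(es2$scores)[rowSums(es2$scores[, sig2] > 0) >= 20]
  expect_setequal(got, want)
})

test_that("activities are target-mean z-scores", {
  vals <- matrix(c(1, 2, 3, 3, 2, 1, 5, 5, 8), 3, 3, byrow = TRUE,
                 dimnames = list(c("ga", "gb", "gc"), c("s1", "s2", "s3")))
  z <- z_transform(make_expr(vals))
  ev <- evidence_table(c("Tsolo", "Tpair", "Tpair", "Ttrio", "Ttrio", "Ttrio"),
                       c("ga", "ga", "gb", "ga", "gb", "gc"),
                       "metacore_direct")
  es <- compute_edge_scores(ev)
  act <- compute_activities(es, z)
  expect_equal(act$act["Tsolo", ], z$values["ga", ])
  # opposite z-profiles average to zero
  expect_equal(unname(act$act["Tpair", ]), rep(0, 3), tolerance = 1e-12)
  expect_equal(act$act["Ttrio", ], colMeans(z$values))
  expect_equal(unname(act$n_targets[c("Tsolo", "Tpair", "Ttrio")]),
               c(1L, 2L, 3L))
  # a TF with no measured target is dropped with a warning
  ev2 <- evidence_table(c("Tsolo", "Tghost"), c("ga", "nowhere"),
                        "metacore_direct")
  expect_warning(act2 <- compute_activities(compute_edge_scores(ev2), z),
                 "Tghost")
  expect_equal(rownames(act2$act), "Tsolo")
})

test_that("noiseless single-regulator data is recovered exactly", {
  sim <- generate_expression(n_genes = 45, n_true_tf = 3, n_decoy_tf = 5,
                             noise_sd = 0, seed = 6)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z,
                            tfs = filter_eligible_tfs(es, rownames(z$values),
                                                      min_targets = 10))
  fit <- fit_regnet(rownames(z$values), z, es, act, regulator_cap = 3,
                    seed = 3)
  expect_setequal(fit$selected, sim$truth$true_tfs)
  expect_equal(fit$objective, 0, tolerance = 1e-5)
  for (f in fit$cv) expect_lt(f$heldout_mae, 1e-6)
  # fitted values equal observations
  expect_equal(fitted(fit), z$values[fit$targets, ], tolerance = 1e-6)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-6)
})

test_that("the enumeration backend matches the generic MIP backend", {
  sim <- generate_expression(n_genes = 30, n_true_tf = 2, n_decoy_tf = 3,
                             noise_sd = 0.3, seed = 9)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z, tfs = rownames(es$scores))
  genes <- rownames(z$values)[1:6]
  samples <- colnames(z$values)
  esm <- matrix(0, nrow(act$act), length(genes),
                dimnames = list(rownames(act$act), genes))
  common <- intersect(genes, colnames(es$scores))
  esm[, common] <- es$scores[rownames(act$act), common]
  a <- macrep:::solve_regnet(z$values, act$act, esm, genes, samples, 2,
                             backend = "enumeration")
  b <- macrep:::solve_regnet(z$values, act$act, esm, genes, samples, 2,
                             backend = "mip")
  expect_equal(a$objective, b$objective, tolerance = 1e-5)
})

test_that("the magnitude-matching objective is optimized exactly", {
  set.seed(5)
  n <- 6
  act <- matrix(rnorm(n), 1, n, dimnames = list("T1", paste0("s", 1:n)))
  z <- rbind(G1 = 1.5 + 0.8 * act["T1", ] + rnorm(n, sd = 0.05))
  colnames(z) <- paste0("s", 1:n)
  esm <- matrix(1, 1, 1, dimnames = list("T1", "G1"))
  s_sig <- macrep:::solve_regnet(z, act, esm, "G1", colnames(z), 1,
                                 objective = "signed")
  s_mag <- macrep:::solve_regnet(z, act, esm, "G1", colnames(z), 1,
                                 objective = "magnitude")
  # the magnitude optimum can never exceed the magnitude metric of the
  # signed fit, and coincides with it when predictions stay positive
  pred <- s_sig$beta0[["G1"]] + s_sig$beta["T1", "G1"] * act["T1", ]
  mag_of_signed <- sum(abs(abs(z["G1", ]) - abs(pred)))
  expect_lte(s_mag$objective, mag_of_signed + 1e-7)
  expect_equal(s_mag$objective, mag_of_signed, tolerance = 1e-6)
})

test_that("with all-zero activities the model reduces to L1-optimal intercepts", {
  set.seed(2)
  vals <- matrix(rnorm(5 * 9), 5, 9,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:9)))
  z <- make_expr(vals, phenotype = rep(c("M0", "M1", "M2"), each = 3))
  ev <- evidence_table(rep(c("TA", "TB"), each = 5),
                       rep(paste0("g", 1:5), 2), "metacore_direct")
  es <- compute_edge_scores(ev)
  act <- structure(list(
    act = matrix(0, 2, 9, dimnames = list(c("TA", "TB"), colnames(vals))),
    n_targets = c(TA = 5L, TB = 5L)), class = "activity_matrix")
  fit <- fit_regnet(paste0("g", 1:5), z, es, act, regulator_cap = 2,
                    seed = 1)
  med_obj <- sum(abs(sweep(vals, 1, apply(vals, 1, median))))
  expect_equal(fit$objective, med_obj, tolerance = 1e-9)
  for (g in paste0("g", 1:5)) {
    o <- sort(vals[g, ])
    expect_gte(fit$beta0[[g]], o[5] - 1e-9)  # n = 9: the median order stat
    expect_lte(fit$beta0[[g]], o[5] + 1e-9)
  }
})

test_that("the regulator cap binds", {
  sim <- generate_expression(n_genes = 60, n_true_tf = 5, n_decoy_tf = 2,
                             noise_sd = 0.1, seed = 10)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z, tfs = rownames(es$scores))
  fit <- fit_regnet(rownames(z$values)[1:25], z, es, act,
                    regulator_cap = 3, seed = 1)
  expect_lte(length(fit$selected), 3)
  # coefficients only on selected TFs with known interactions
  nz <- which(fit$beta != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    expect_true(all(rownames(fit$beta)[nz[, 1]] %in% fit$selected))
    for (k in seq_len(nrow(nz)))
      expect_gt(fit$es[rownames(fit$beta)[nz[k, 1]],
                       colnames(fit$beta)[nz[k, 2]]], 0)
  }
})

test_that("bootstrap selection is deterministic and its Fisher tests match the hypergeometric oracle", {
  sim <- generate_expression(n_genes = 40, n_true_tf = 2, n_decoy_tf = 6,
                             noise_sd = 0.2, seed = 14)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z,
                            tfs = filter_eligible_tfs(es, rownames(z$values),
                                                      min_targets = 10))
  b1 <- bootstrap_selection(rownames(z$values), z, es, act, reps = 25,
                            genes_per_rep = 8, regulator_cap = 3, seed = 8)
  b2 <- bootstrap_selection(rownames(z$values), z, es, act, reps = 25,
                            genes_per_rep = 8, regulator_cap = 3, seed = 8)
  expect_identical(b1$count, b2$count)
  expect_identical(b1$pvalue, b2$pvalue)
  expect_true(all(b1$count <= b1$n_draws))
  expect_true(all(b1$pvalue >= 0 & b1$pvalue <= 1))
  # independent exact hypergeometric tail for each 2x2 table
  for (k in seq_len(nrow(b1))) {
    s <- b1$count[k]; N <- b1$n_draws[k]; e <- b1$expected[k]
    oracle <- phyper(s - 1, s + e, (N - s) + (N - e), N,
                     lower.tail = FALSE)
    expect_equal(b1$pvalue[k], oracle, tolerance = 1e-10)
  }
  # a TF never selected shows no enrichment
  never <- b1[b1$count == 0, ]
  if (nrow(never)) expect_true(all(never$pvalue >= 0.99))
  # BH adjustment is monotone in the raw p-values
  expect_true(all(diff(b1$padj[order(b1$pvalue)]) >= -1e-12))
})

test_that("parsimony fitting keeps the generating regulators and respects candidates", {
  sim <- generate_expression(n_genes = 40, n_true_tf = 3, n_decoy_tf = 5,
                             noise_sd = 0, seed = 17)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z,
                            tfs = filter_eligible_tfs(es, rownames(z$values),
                                                      min_targets = 10))
  fit <- fit_parsimony_model(sim$truth$true_tfs, rownames(z$values),
                             z, es, act, seed = 2)
  expect_setequal(fit$selected, sim$truth$true_tfs)
  expect_equal(fit$objective, 0, tolerance = 1e-5)
  # single candidate: at most one regulator
  fit1 <- fit_parsimony_model(sim$truth$true_tfs[1], rownames(z$values),
                              z, es, act, seed = 2)
  expect_lte(length(fit1$selected), 1)
  # cap honored with many candidates
  cand <- rownames(act$act)[1:8]
  fit8 <- fit_parsimony_model(cand, rownames(z$values), z, es, act,
                              regulator_cap = 5, seed = 2)
  expect_lte(length(fit8$selected), 5)
  expect_true(all(fit8$selected %in% cand))
})

test_that("reprogramming is the identity without replacement and linear in activity differences", {
  sim <- generate_expression(n_genes = 40, n_true_tf = 3, n_decoy_tf = 5,
                             noise_sd = 0.2, seed = 19)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z,
                            tfs = filter_eligible_tfs(es, rownames(z$values),
                                                      min_targets = 10))
  fit <- fit_parsimony_model(sim$truth$true_tfs, rownames(z$values),
                             z, es, act, seed = 4)
  # empty replacement set or target == source: the fitted source-state model
  meta <- z$meta
  m2cols <- meta$sample[meta$phenotype == "M2"]
  base_pred <- drop(predict(fit,
                            cbind(rowMeans(act$act[rownames(fit$beta),
                                                   m2cols, drop = FALSE]))))
  rp0 <- reprogram(fit, from = "M2", to = "M1", tfs = character(0))
  expect_equal(rp0$genes$prediction, unname(base_pred), tolerance = 1e-9)
  rp_same <- reprogram(fit, from = "M2", to = "M2")
  expect_equal(rp_same$genes$prediction, unname(base_pred),
               tolerance = 1e-9)

  # per-gene prediction equals a direct evaluation of the substitution model
  tfs <- fit$selected[1:2]
  rp <- reprogram(fit, from = "M2", to = "M1", tfs = tfs)
  a_m2 <- rowMeans(act$act[, meta$sample[meta$phenotype == "M2"]])
  a_m1 <- rowMeans(act$act[, meta$sample[meta$phenotype == "M1"]])
  for (g in rownames(z$values)[c(1, 7, 20)]) {
    manual <- fit$beta0[[g]]
    for (t in rownames(fit$beta)) {
      a <- if (t %in% tfs) a_m1[[t]] else a_m2[[t]]
      manual <- manual + fit$beta[t, g] * fit$es[t, g] * a
    }
    expect_equal(rp$genes$prediction[rp$genes$gene == g], manual,
                 tolerance = 1e-9)
  }
  # the prediction shift depends only on the replaced TFs' activity change
  shift <- rp$genes$prediction - rp0$genes$prediction
  manual_shift <- colSums((fit$beta[tfs, , drop = FALSE] *
                             fit$es[tfs, rownames(z$values)]) *
                            (a_m1[tfs] - a_m2[tfs]))
  expect_equal(shift, unname(manual_shift), tolerance = 1e-9)
  expect_error(reprogram(fit, from = "M2", to = "M1", tfs = "NOPE"),
               "NOPE")
  expect_equal(rp$switched_fraction, mean(rp$genes$switched))
})

test_that("subset evaluation covers every non-empty subset consistently", {
  sim <- generate_expression(n_genes = 40, n_true_tf = 3, n_decoy_tf = 4,
                             noise_sd = 0.2, seed = 23)
  z <- z_transform(sim$expression, collapse_technical = TRUE)
  es <- sim$truth$edge_scores
  act <- compute_activities(es, z,
                            tfs = filter_eligible_tfs(es, rownames(z$values),
                                                      min_targets = 10))
  fit <- fit_parsimony_model(sim$truth$true_tfs, rownames(z$values),
                             z, es, act, seed = 5)
  k <- length(fit$selected)
  tab <- evaluate_subsets(fit, from = "M2", to = "M1")
  expect_equal(nrow(tab), 2^k - 1)
  expect_false(any(tab$subset == ""))
  for (r in c(1, nrow(tab))) {
    sub <- strsplit(tab$subset[r], ",")[[1]]
    expect_equal(tab$switched_fraction[r],
                 reprogram(fit, "M2", "M1", tfs = sub)$switched_fraction)
  }
  expect_true(all(diff(tab$switched_fraction) <= 1e-12))
})
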