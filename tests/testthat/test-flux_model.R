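test_that("FVA pins a fixed-input chain, blocks disconnected reactions, and matches a per-reaction LP oracle", {
  # chain with the input exchange fixed to 1: every reaction carries 1
  m <- chain_model()
  b <- run_fva(m, biomass_min = 0.028)
  for (r in m$reactions$id) {
    expect_equal(b$fva_min[b$id == r], 1, tolerance = 1e-7)
    expect_equal(b$fva_max[b$id == r], 1, tolerance = 1e-7)
  }

  # reaction disconnected from all exchanges is blocked
  m2 <- add_reaction(chain_model(), "orphan", c(X = -1, Y = 1), 0, 10)
  b2 <- run_fva(m2)
  expect_equal(b2$fva_min[b2$id == "orphan"], 0)
  expect_equal(b2$fva_max[b2$id == "orphan"], 0)
  expect_equal(b2$min_v[b2$id == "orphan"], 0)

  # diamond network: bounds match independently solved per-reaction LPs
  dm <- diamond_model()
  bd <- run_fva(dm, biomass_min = 0.1)
  oracle <- function(r, sense) {
    p <- lmp(sense)
    lbv <- dm$reactions$lb; lbv[dm$reactions$id == "biomass"] <- 0.1
    p <- lmp_add_variables(p, dm$reactions$id, lb = lbv,
                           ub = dm$reactions$ub)
    S <- as.matrix(dm$S)
    for (met in rownames(S))
      p <- lmp_add_constraints(p, S[met, S[met, ] != 0], "==", 0)
    p <- lmp_set_objective(p, setNames(1, r))
    solve_lmp(p)$objective
  }
  for (r in dm$reactions$id) {
    expect_equal(bd$fva_min[bd$id == r], oracle(r, "min"), tolerance = 1e-6)
    expect_equal(bd$fva_max[bd$id == r], oracle(r, "max"), tolerance = 1e-6)
  }
  # branch reactions can be off while the other branch carries everything
  expect_equal(bd$min_v[bd$id == "R_ab"], 0)

  # unreachable biomass floor is reported
  m3 <- chain_model()
  m3$reactions$ub[m3$reactions$id == "EX_in"] <- 0
  m3$reactions$lb[m3$reactions$id == "EX_in"] <- 0
  expect_error(run_fva(m3, biomass_min = 0.028), "0.028")
})

test_that("expression-to-flux interpolation hits its endpoints and stays monotone", {
  expect_equal(expression_to_flux_magnitude(2, -1, 2, 0.5, 4), 4)
  expect_equal(expression_to_flux_magnitude(-1, -1, 2, 0.5, 4), 0.5)
  expect_equal(expression_to_flux_magnitude(0.5, -1, 2, 0.5, 4),
               (0.5 + 4) / 2)
  g <- sort(runif(20, -2, 2))
  out <- expression_to_flux_magnitude(g, -2, 2, 0.3, 5)
  expect_true(all(diff(out) >= 0))
  expect_error(expression_to_flux_magnitude(0, 1, 1, 0, 1), "max_g")
})

test_that("targets carry per-gene averaging weights and the 100x core emphasis", {
  m <- diamond_model()
  m$genes$R_ab <- c("gx", "gy")       # two genes on one core reaction
  b <- run_fva(m, biomass_min = 0.1)
  vals <- matrix(c(1, 3, 2, 5, 4, 1, 0, 2), 4, 2,
                 dimnames = list(c("gx", "gy", "g_ac", "g_bd"),
                                 c("s1", "s2")))
  z <- z_transform(make_expr(vals, phenotype = c("M1", "M2")))
  tg <- build_targets(m, z, b, core = "R_ab",
                      currency = character())
  two <- tg[tg$id == "R_ab" & tg$phenotype == "M1", ]
  expect_equal(nrow(two), 2)          # one entry per associated gene
  maxv_ab <- b$max_v[b$id == "R_ab"]
  expect_equal(unique(two$weight), 100 / (maxv_ab * 2))
  # neighbor weight is 1/(max_v * n); core/neighbor ratio is 100 at equal
  # max_v and gene count
  nb <- tg[tg$id == "R_ac", ]
  expect_gt(nrow(nb), 0)
  expect_equal(unique(nb$weight),
               1 / (b$max_v[b$id == "R_ac"] * 1))
  expect_equal(unique(two$weight) / unique(nb$weight) *
                 (maxv_ab / b$max_v[b$id == "R_ac"]) * 2, 100)
  # magnitudes stay within the attainable range
  expect_true(all(tg$target >= 0 - 1e-12))
  for (k in seq_len(nrow(tg)))
    expect_lte(tg$target[k], b$max_v[b$id == tg$id[k]] + 1e-9)

  # a gene missing from the expression matrix drops the reaction with warning
  m$genes$R_bd <- "ghost_gene"
  expect_warning(tg2 <- build_targets(m, z, b, core = "R_ab",
                                      currency = character()),
                 "ghost_gene")
  expect_false("R_bd" %in% tg2$id)
  expect_error(build_targets(m, z, b, core = character()), "non-empty")
})

test_that("cycle detection finds minimal cycles and proves chains loop-free", {
  tn <- generate_toy_network(2, seed = 8)
  # a simple chain support has no cycle
  v_chain <- tn$truth$v
  v_chain[tn$truth$cycle] <- 0
  expect_null(detect_min_cycle(tn$model, v_chain))
  # the planted 2-cycle is detected from the generating flux
  cut <- detect_min_cycle(tn$model, tn$truth$v)
  expect_s3_class(cut, "cycle_cut")
  expect_setequal(cut$reactions, tn$truth$cycle)
  expect_equal(cut$k, 2)

  # nested 2-cycle and 4-cycle: the smaller cycle is returned
  tn4 <- generate_toy_network(4, seed = 9)
  m <- add_reaction(tn4$model, "CYB1", c(B = -1, Q = 1), 0, 10,
                    genes = "gq1")
  m <- add_reaction(m, "CYB2", c(Q = -1, B = 1), 0, 10, genes = "gq2")
  v <- tn4$truth$v
  v <- c(v, CYB1 = 0.9, CYB2 = 0.9)
  expect_equal(max(abs(as.matrix(m$S) %*% v[m$reactions$id])), 0,
               tolerance = 1e-9)
  cut2 <- detect_min_cycle(m, v[m$reactions$id])
  expect_setequal(cut2$reactions, c("CYB1", "CYB2"))
})

test_that("flux fitting reproduces consistent targets and removes planted loops", {
  tn <- generate_toy_network(3, seed = 21)
  b <- run_fva(tn$model)
  # targets built from the loop-free part of the generating flux:
  # perfectly attainable, so the deviation objective vanishes
  v_ref <- tn$truth$v
  v_ref[tn$truth$cycle] <- 0
  tg0 <- targets_from_flux(tn$model, b, v_ref, "M1",
                           setdiff(tn$model$reactions$id[
                             !tn$model$reactions$exchange],
                             c(tn$truth$cycle, "biomass")))
  f0 <- fit_fluxes(tn$model, tg0, b, "M1")
  expect_equal(f0$objective, 0, tolerance = 1e-6)
  for (r in unique(tg0$id))
    expect_equal(abs(f0$fluxes[[r]]), tg0$target[tg0$id == r][1],
                 tolerance = 1e-6)
  expect_equal(max(abs(as.matrix(tn$model$S) %*% f0$fluxes)), 0,
               tolerance = 1e-6)

  # targets that reward the planted cycle: carried before loop removal,
  # eliminated at convergence with throughput preserved
  tg <- targets_from_flux(tn$model, b, tn$truth$v, "M1")
  pre <- fit_fluxes(tn$model, tg, b, "M1", max_iter = 0)
  expect_gte(min(abs(pre$fluxes[tn$truth$cycle])), 0.01)
  post <- fit_fluxes(tn$model, tg, b, "M1")
  expect_gte(post$iterations, 1)
  expect_null(detect_min_cycle(tn$model, post$fluxes))
  expect_length(find_balanced_subcycles(tn$model, post$fluxes), 0)
  expect_equal(post$biomass_flux, pre$biomass_flux, tolerance = 1e-6)
  expect_equal(post$fluxes[["EX_in"]], pre$fluxes[["EX_in"]],
               tolerance = 1e-6)
  # objective cannot beat the cut-free relaxation
  expect_gte(post$objective, pre$objective - 1e-9)

  # identical targets for two phenotypes give identical flux vectors
  tg2 <- tg
  tg2$phenotype <- "M2"
  both <- rbind(tg, tg2)
  class(both) <- class(tg)
  fA <- fit_fluxes(tn$model, both, b, "M1")
  fB <- fit_fluxes(tn$model, both, b, "M2")
  expect_equal(fA$fluxes, fB$fluxes, tolerance = 1e-9)
})

test_that("differential flux percentages follow the 0-100 normalization", {
  expect_equal(differential_flux_percent(3, 3), 0)
  expect_equal(differential_flux_percent(2, 0), 100)
  expect_equal(differential_flux_percent(0, -1.5), 100)
  expect_equal(differential_flux_percent(2, 1), 50)
  expect_equal(differential_flux_percent(-2, 1), 50) # absolute fluxes
  expect_equal(differential_flux_percent(0, 0), 0)
  v <- differential_flux_percent(c(1, 0, 2), c(1, 1, 8))
  expect_equal(v, c(0, 100, 75))
})
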