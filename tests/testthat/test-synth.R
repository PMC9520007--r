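test_that("generators are deterministic under a fixed seed", {
  a <- synth_ontology(seed = 9)
  b <- synth_ontology(seed = 9)
  expect_identical(a$ontology$annotations, b$ontology$annotations)
  expect_identical(a$ontology$interactions, b$ontology$interactions)

  ea <- synth_expression(a$ontology, expression_spec(), seed = 4)
  eb <- synth_expression(b$ontology, expression_spec(), seed = 4)
  expect_identical(ea$table, eb$table)

  pa <- synth_proteomics(seed = 4)
  pb <- synth_proteomics(seed = 4)
  expect_identical(pa$table, pb$table)

  fa <- synth_profiles(profile_spec(genes = c(G1 = 1), n_experiments = 1),
                       seed = 4)
  fb <- synth_profiles(profile_spec(genes = c(G1 = 1), n_experiments = 1),
                       seed = 4)
  expect_identical(fa$experiments[[1]]$controls[[1]]$intensity,
                   fb$experiments[[1]]$controls[[1]]$intensity)

  # and the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(synth_ontology(seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated ontologies satisfy the structural invariants", {
  so <- synth_ontology(seed = 17)
  expect_s3_class(validate_ontology(so$ontology), "scp_ontology")
  # designated strong pair really is in the top-20% level-2 set
  ti <- top_interactions(so$ontology, 2, 0.20)
  key <- paste(pmin(ti$scp_a, ti$scp_b), pmax(ti$scp_a, ti$scp_b))
  sp <- sort(so$truth$strong_pair)
  expect_true(paste(sp[1], sp[2]) %in% key)
  # infeasible spec caught
  expect_error(synth_ontology(ontology_spec(genes_per_scp = c(0, 9, 9, 9),
                                            background_size = 5)),
               "genes_per_scp")
})

test_that("planted expression signal is recoverable from the manifest", {
  so <- synth_ontology(seed = 23)
  se <- synth_expression(
    so$ontology,
    expression_spec(planted = planted_pair_spec(so$truth, n_genes = 10)),
    seed = 23
  )
  degs <- call_degs(se$table, min_abs_log2fc = log2(1.5))
  hits <- degs$feature[degs$time_h == 6 & degs$direction == "up"]
  expect_gte(mean(toupper(se$truth$gene) %in% hits), 0.9)

  # the mid-fraction plants land between the two fold-change cutoffs
  se2 <- synth_expression(
    so$ontology,
    expression_spec(planted = planted_pair_spec(so$truth, n_genes = 10),
                    mid_fraction = 1),
    seed = 24
  )
  expect_true(all(abs(se2$truth$effect) >= log2(1.3) &
                    abs(se2$truth$effect) <= log2(1.5)))
  relaxed <- call_degs(se2$table, min_abs_log2fc = log2(1.3))
  strict <- call_degs(se2$table, min_abs_log2fc = log2(1.5))
  expect_gte(mean(toupper(se2$truth$gene) %in% relaxed$feature), 0.9)
  expect_false(any(toupper(se2$truth$gene) %in% strict$feature))
})

test_that("run batch factors cancel under within-run normalization", {
  sp <- synth_proteomics(proteomics_spec(noise_sd = 0, n_planted = 5),
                         seed = 6)
  norm <- normalize_proteomics_run(sp$table)
  # noise-free: every planted treated value normalizes to exactly 2^shift,
  # every null treated/vehicle value to exactly 1 -- batch factor gone
  tr <- norm[norm$role == "treated", ]
  planted <- sp$truth$protein[sp$truth$planted]
  expect_equal(unique(round(tr$normalized[tr$protein %in% planted], 12)),
               2^log2(1.2))
  expect_equal(unique(round(tr$normalized[!tr$protein %in% planted], 12)), 1)

  # single-peptide planted hits are excluded by the filter
  sp2 <- synth_proteomics(proteomics_spec(peptide_one_fraction = 1), seed = 6)
  expect_equal(nrow(suppressWarnings(call_deps(sp2$table))), 0)
})

test_that("profile damage flags produce failing cell bodies, both modes", {
  for (mode in c("displaced", "attenuated")) {
    pr <- synth_profiles(profile_spec(
      genes = c(G1 = 1), n_experiments = 2, controls_per_experiment = 1,
      damaged = "G1", damage_type = mode
    ), seed = 41)
    for (e in pr$experiments) {
      expect_equal(qc_cell_body(e$cell_body[[paste0(e$id, "_G1")]]),
                   "damaged")
      expect_equal(qc_cell_body(e$cell_body[[paste0(e$id, "_control1")]]),
                   "pass")
    }
  }
})

test_that("a planted knockdown effect is detected as inhibition", {
  pr <- synth_profiles(profile_spec(genes = c(KD = 0.5)), seed = 55)
  scr <- nog_screen(pr$experiments)
  expect_equal(scr$results$classification, "significant")
  expect_equal(scr$results$direction, "inhibit")
})

test_that("model regimes construct verified parameter sets", {
  for (s in 1:3) {
    f <- default_model_params("feasible", seed = s)
    expect_true(analytic_parameter_solution(f$target_velocity,
                                            f$back_transport_rate,
                                            f)$feasible)
    st <- default_model_params("stalled", seed = s)
    expect_false(analytic_parameter_solution(st$target_velocity,
                                             st$back_transport_rate,
                                             st)$feasible)
  }
})
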