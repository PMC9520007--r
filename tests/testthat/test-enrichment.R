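test_that("over-representation p equals the hypergeometric upper tail", {
  bg <- sprintf("G%03d", 1:100)
  gene_list <- bg[1:10]
  unit <- bg[c(1:5, 51:65)]                # overlap 5, unit 20
  res <- fisher_scp_test(gene_list, unit, bg)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_value, brute_force_overrep(5, 20, 10, 100),
               tolerance = 1e-12)

  # no overlap -> p = 1 for the one-sided test
  expect_equal(fisher_scp_test(bg[1:10], bg[90:100], bg)$p_value, 1)
  # saturated table -> p = 1
  expect_equal(fisher_scp_test(bg, bg, bg)$p_value, 1)
  expect_error(fisher_scp_test("A", "A", character(0)), "non-empty")
})

test_that("standard enrichment flags planted SCP signal and skips empty strata", {
  ont <- toy_ontology(background_extra = 960)   # background 1000
  calls <- tibble::tibble(
    feature = c(ont$annotations$A[1:8], sprintf("GX%03d", 1:42)),
    time_h = 4, direction = "up"
  )
  res <- standard_enrichment(calls, ont, levels = 2)
  a_row <- res[res$scp_id == "A", ]
  expect_true(a_row$significant)
  expect_equal(a_row$overlap, 8)
  expect_equal(a_row$p_value,
               brute_force_overrep(8, 10, 50, 1000), tolerance = 1e-12)

  # disjoint list: nothing significant
  res2 <- standard_enrichment(
    tibble::tibble(feature = sprintf("GX%03d", 101:150),
                   time_h = 4, direction = "down"),
    ont, levels = 2
  )
  expect_false(any(res2$significant))

  # a stratum whose genes are outside the background is skipped, warning
  expect_warning(
    standard_enrichment(
      tibble::tibble(feature = "NOT_THERE", time_h = 2, direction = "up"),
      ont, levels = 2
    ),
    "skipped"
  )
})

test_that("combinations require above-cutoff connectivity", {
  ont <- toy_ontology()
  # cutoff 0.5 keeps A-B (0.9) and B-C (0.8)
  combos <- generate_combinations(c("A", "B", "C"), ont, top_fraction = 0.5)
  expect_setequal(combos$unit_id, c("A+B", "B+C", "A+B+C"))
  expect_equal(combos$n_members[combos$unit_id == "A+B+C"], 3L)

  # seeds without any above-cutoff edge give nothing
  expect_equal(nrow(generate_combinations(c("C", "D"), ont, 0.5)), 0)
  expect_equal(nrow(generate_combinations(c("A", "D"), ont, 0.5)), 0)

  # clique mode drops the chain-connected triple (A-C edge missing)
  strict <- generate_combinations(c("A", "B", "C"), ont, 0.5,
                                  require_clique = TRUE)
  expect_setequal(strict$unit_id, c("A+B", "B+C"))

  expect_error(generate_combinations(c("A", "P1"), ont, 0.5), "share one level")
})

test_that("dynamic enrichment ranks a strong pair above its weak members", {
  ont <- toy_ontology(background_extra = 4000)
  gene_list <- c(ont$annotations$A[1:3], ont$annotations$B[1:3])
  pred <- dynamic_enrichment(gene_list, ont, level = 2, top_fraction = 0.5,
                             top_k = 5)
  expect_equal(pred$unit_id[1], "A+B")
  expect_lt(pred$p_value[1], min(pred$p_value[pred$unit_id %in% c("A", "B")]))
  # exhaustive check: the pair's p beats every single seed's p
  singles <- pred[pred$n_members == 1, ]
  expect_true(all(pred$p_value[1] < singles$p_value))

  # list inside one SCP, no interactions used: that SCP ranks first
  pred2 <- dynamic_enrichment(ont$annotations$D[1:5], ont, level = 2,
                              top_fraction = 0.5)
  expect_equal(pred2$unit_id[1], "D")

  # no seed contains a list gene: empty prediction set
  expect_equal(nrow(dynamic_enrichment(sprintf("GX%03d", 1:5), ont, 2)), 0)
})

test_that("rank ties break toward fewer member SCPs", {
  scps <- tibble::tibble(scp_id = c("S1", "A", "B"),
                         name = c("whole", "half a", "half b"), level = 2L)
  ann <- list(S1 = sprintf("x%02d", 1:10), A = sprintf("x%02d", 1:5),
              B = sprintf("x%02d", 6:10))
  ia <- tibble::tibble(scp_a = "A", scp_b = "B", level = 2L, strength = 1)
  ont <- scp_ontology(scps, tibble::tibble(scp_id = character(),
                                           parent_id = character()),
                      ann, ia, c(sprintf("x%02d", 1:10),
                                 sprintf("y%02d", 1:40)))
  # S1 and the pair A+B have identical gene sets -> identical p; the
  # single must come first
  pred <- dynamic_enrichment(c("x01", "x06"), ont, level = 2,
                             top_fraction = 1, top_k = 3)
  expect_equal(pred$p_value[pred$unit_id == "S1"],
               pred$p_value[pred$unit_id == "A+B"])
  expect_lt(pred$rank[pred$unit_id == "S1"], pred$rank[pred$unit_id == "A+B"])

  # determinism: same inputs, same ranking
  pred_again <- dynamic_enrichment(c("x01", "x06"), ont, level = 2,
                                   top_fraction = 1, top_k = 3)
  expect_identical(pred, pred_again)
})

test_that("SCP networks connect exactly the co-predicted members", {
  preds <- tibble::tibble(
    unit_id = c("A+B", "C"),
    members = list(c("A", "B"), "C"),
    n_members = c(2L, 1L),
    time_h = 6, direction = "up"
  )
  net <- build_scp_network(preds)
  expect_setequal(net$nodes$scp_id, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$unit_id, "A+B")

  # a predicted triple renders as its clique
  triple <- tibble::tibble(unit_id = "A+B+C", members = list(c("A", "B", "C")),
                           n_members = 3L)
  net3 <- build_scp_network(triple)
  expect_equal(nrow(net3$edges), 3)

  # disjoint singles: edgeless
  loose <- tibble::tibble(unit_id = c("A", "B"), members = list("A", "B"),
                          n_members = 1L)
  expect_equal(nrow(build_scp_network(loose)$edges), 0)
  expect_equal(nrow(build_scp_network(loose[0, ])$nodes), 0)
})

test_that("timelines carry -log10 p with absent tests as NA", {
  res <- tibble::tibble(
    scp_id = c("A", "A", "B"), level = 2L,
    time_h = c(2, 4, 2), direction = "up",
    overlap = 1L, unit_size = 10L, list_size = 5L, background_size = 100L,
    p_value = c(0.05, 0.001, 0.5), significant = c(TRUE, TRUE, FALSE)
  )
  tl <- assemble_timelines(res)
  expect_equal(tl$neg_log10_p[tl$scp_id == "A" & tl$time_h == 2],
               -log10(0.05))
  # B was tested at one of two time points: one value, one NA
  b <- tl[tl$scp_id == "B", ]
  expect_equal(sum(is.na(b$neg_log10_p)), 1)
  expect_equal(nrow(b), 2)
  expect_equal(attr(tl, "signif_line"), -log10(0.05))
})
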