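test_that("ontology files round-trip through load_ontology", {
  ont <- toy_ontology()
  dir <- withr::local_tempdir()
  write_ontology_files(ont, dir)
  back <- suppressMessages(load_ontology(
    file.path(dir, "hierarchy.tsv"), file.path(dir, "annotations.gmt"),
    file.path(dir, "interactions.tsv"), file.path(dir, "background.txt")
  ))
  expect_setequal(back$scps$scp_id, ont$scps$scp_id)
  expect_equal(sort(back$background), sort(ont$background))
  expect_equal(nrow(back$interactions), 4)
  expect_setequal(back$annotations$A, ont$annotations$A)
})

test_that("GMT duplicates collapse and unknown interaction SCPs error", {
  dir <- withr::local_tempdir()
  writeLines("scp_id\tparent_id\tlevel\tname\nS1\t\t1\tone",
             file.path(dir, "h.tsv"))
  writeLines("S1\tdesc\tg1\tg2\tg2", file.path(dir, "a.gmt"))
  writeLines("scp_a\tscp_b\tstrength", file.path(dir, "i.tsv"))
  writeLines(c("G1", "G2", "G3"), file.path(dir, "b.txt"))
  ont <- suppressMessages(load_ontology(
    file.path(dir, "h.tsv"), file.path(dir, "a.gmt"),
    file.path(dir, "i.tsv"), file.path(dir, "b.txt")
  ))
  expect_equal(sort(ont$annotations$S1), c("G1", "G2"))

  writeLines("scp_a\tscp_b\tstrength\nS1\tNOPE\t0.5", file.path(dir, "i.tsv"))
  expect_error(
    suppressMessages(load_ontology(
      file.path(dir, "h.tsv"), file.path(dir, "a.gmt"),
      file.path(dir, "i.tsv"), file.path(dir, "b.txt")
    )),
    "unknown SCP"
  )
})

test_that("background restriction intersects annotations and never drops SCPs", {
  ont <- toy_ontology()
  measurable <- c(ont$annotations$A[1:4], ont$annotations$B, "GX001")
  res <- restrict_to_background(ont, measurable)
  expect_setequal(res$annotations$A, ont$annotations$A[1:4])
  expect_setequal(res$annotations$B, ont$annotations$B)
  expect_equal(res$annotations$C, character(0))
  expect_setequal(res$scps$scp_id, ont$scps$scp_id)
  # every annotated gene ends up inside the background
  expect_true(all(unlist(res$annotations) %in% res$background))

  # full background is the identity
  same <- restrict_to_background(ont, ont$background)
  expect_equal(same$annotations, ont$annotations)

  expect_error(restrict_to_background(ont, "NOT_A_GENE"),
               "no measurable gene")
  expect_error(restrict_to_background(ont, character(0)), "non-empty")
})

test_that("composite SCPs take the member union and re-parent one level down", {
  ont <- toy_ontology()
  before <- length(unique(unlist(ont$annotations)))
  comp <- create_composite_scp(ont, "MITO", "organelle umbrella", 1,
                               c("A", "B"))
  expect_setequal(comp$annotations$MITO,
                  union(ont$annotations$A, ont$annotations$B))
  expect_true(all(c("A", "B") %in%
                    comp$parents$scp_id[comp$parents$parent_id == "MITO"]))
  # no genes created or lost
  expect_equal(length(unique(unlist(comp$annotations))), before)
  expect_error(create_composite_scp(comp, "MITO", "dup", 1, "C"),
               "already exists")
  expect_error(create_composite_scp(ont, "EMPTY", "none", 1, character(0)),
               "at least one member")
})

test_that("interaction strength cutoff keeps the top fraction, ties inclusive", {
  scps <- tibble::tibble(scp_id = sprintf("S%d", 1:6),
                         name = sprintf("S%d", 1:6), level = 2L)
  mk <- function(strengths) {
    ia <- tibble::tibble(scp_a = sprintf("S%d", seq_along(strengths)),
                         scp_b = sprintf("S%d", seq_along(strengths) + 1),
                         level = 2L, strength = strengths)
    scp_ontology(scps, tibble::tibble(scp_id = character(),
                                      parent_id = character()),
                 stats::setNames(rep(list(character(0)), 6), scps$scp_id),
                 ia, sprintf("G%d", 1:10))
  }
  ont <- mk(c(1, 2, 3, 4, 5))
  expect_equal(interaction_strength_cutoff(ont, 2, 0.2), 5)
  expect_equal(interaction_strength_cutoff(ont, 2, 1.0), 1)

  tied <- mk(c(3, 3, 3, 1))
  expect_equal(interaction_strength_cutoff(tied, 2, 0.25), 3)
  expect_equal(nrow(top_interactions(tied, 2, 0.25)), 3)

  expect_error(interaction_strength_cutoff(ont, 3, 0.2), "no horizontal")

  # monotone: larger fraction never raises the threshold
  set.seed(7)
  for (i in 1:20) {
    ont_r <- mk(round(runif(5), 3))
    fr <- sort(runif(2, 0.05, 1))
    expect_lte(interaction_strength_cutoff(ont_r, 2, fr[2]),
               interaction_strength_cutoff(ont_r, 2, fr[1]))
  }
})

test_that("structural validation rejects malformed ontologies", {
  ont <- toy_ontology()
  bad <- ont
  bad$interactions$scp_b[1] <- "P1"   # cross-level interaction
  expect_error(validate_ontology(bad), "same level")
  bad2 <- ont
  bad2$parents <- tibble::tibble(scp_id = "A", parent_id = "MISSING")
  expect_error(validate_ontology(bad2), "unknown SCP")
})

test_that("ortholog mapping rewrites annotations and background", {
  ont <- toy_ontology()
  map <- data.frame(from = "GA01", to = "ZZ99")
  out <- map_orthologs(ont, map)
  expect_true("ZZ99" %in% out$annotations$A)
  expect_false("GA01" %in% out$annotations$A)
  expect_true("ZZ99" %in% out$background)
})
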