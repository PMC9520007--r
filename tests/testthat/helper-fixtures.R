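# Hand-built toy ontology used across the enrichment and ontology tests.
#
# Level 1: P1 (container).  Level 2: A, B, C, D (ten genes each, A and B
# overlapping in none; background padded with unannotated genes so Fisher
# tables are not saturated).  Horizontal level-2 interactions:
#   A-B 0.9, B-C 0.8, C-D 0.2, A-D 0.1
# so the top-50% cutoff keeps exactly {A-B, B-C}.
toy_ontology <- function(background_extra = 60) {
  scps <- tibble::tibble(
    scp_id = c("P1", "A", "B", "C", "D"),
    name = c("container", "proc A", "proc B", "proc C", "proc D"),
    level = c(1L, 2L, 2L, 2L, 2L)
  )
  parents <- tibble::tibble(scp_id = c("A", "B", "C", "D"), parent_id = "P1")
  annotations <- list(
    P1 = character(0),
    A = sprintf("GA%02d", 1:10),
    B = sprintf("GB%02d", 1:10),
    C = sprintf("GC%02d", 1:10),
    D = sprintf("GD%02d", 1:10)
  )
  interactions <- tibble::tibble(
    scp_a = c("A", "B", "C", "A"),
    scp_b = c("B", "C", "D", "D"),
    level = 2L,
    strength = c(0.9, 0.8, 0.2, 0.1)
  )
  background <- c(unlist(annotations, use.names = FALSE),
                  sprintf("GX%03d", seq_len(background_extra)))
  scp_ontology(scps, parents, annotations, interactions, background)
}

# independent brute-force hypergeometric upper tail, exact binomials
brute_force_overrep <- function(overlap, unit_size, list_size, bg_size) {
  j <- seq(overlap, min(unit_size, list_size))
  sum(exp(lchoose(unit_size, j) + lchoose(bg_size - unit_size, list_size - j) -
            lchoose(bg_size, list_size)))
}

# closed-form two-sided one-sample t p-value (oracle for knockdown_test)
one_sample_t_p <- function(x, mu) {
  tt <- (mean(x) - mu) / (stats::sd(x) / sqrt(length(x)))
  2 * stats::pt(-abs(tt), length(x) - 1)
}
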