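# one-sided over-representation p from the 2x2 counts, vectorised:
# P(X >= overlap) for X ~ Hypergeometric(unit_size, N - unit_size, list_size)
fisher_overrep_p <- function(overlap, unit_size, list_size, background_size) {
  stats::phyper(overlap - 1, unit_size, background_size - unit_size,
                list_size, lower.tail = FALSE)
}

#' One-sided Fisher over-representation test for one gene-set unit
#'
#' Builds the 2x2 table (overlap; list-only; unit-only; neither) of a
#' query gene list against the gene set of a single SCP or SCP
#' combination, over the ontology background, and returns the one-sided
#' (over-representation) Fisher exact p-value, i.e. the hypergeometric
#' upper-tail probability of an overlap at least as large as observed.
#'
#' @param gene_list character vector of query genes (subset of the
#'   background; symbols outside it are dropped from the table).
#' @param unit_genes character vector of genes annotated to the unit.
#' @param background character vector, the test universe (non-empty).
#' @return One-row tibble: `overlap`, `unit_size`, `list_size`,
#'   `background_size`, `p_value`.
#' @export
fisher_scp_test <- function(gene_list, unit_genes, background) {
  if (length(background) == 0) {
    stop("background must be non-empty", call. = FALSE)
  }
  background <- unique(toupper(background))
  gene_list <- intersect(unique(toupper(gene_list)), background)
  unit_genes <- intersect(unique(toupper(unit_genes)), background)
  k <- length(intersect(gene_list, unit_genes))
  tibble::tibble(
    overlap = k,
    unit_size = length(unit_genes),
    list_size = length(gene_list),
    background_size = length(background),
    p_value = fisher_overrep_p(k, length(unit_genes), length(gene_list),
                               length(background))
  )
}

#' Standard SCP enrichment over all time points and directions
#'
#' Runs the one-sided Fisher test of every SCP against the up- and
#' down-regulated gene lists of every time point.  All results are
#' retained (for timelines); those with nominal p at most `alpha` carry
#' `significant = TRUE`.  Time-point strata with empty gene lists are
#' skipped with a warning.
#'
#' @param calls differential calls as produced by [call_degs()] /
#'   [call_deps()] (columns `feature`, `time_h`, `direction`).
#' @param ontology an `scp_ontology`, already restricted to the assay
#'   background.
#' @param alpha nominal significance level, default 0.05.
#' @param levels which SCP levels to test, default all (1:4).
#' @return Tibble: `scp_id`, `level`, `time_h`, `direction`, `overlap`,
#'   `unit_size`, `list_size`, `background_size`, `p_value`,
#'   `significant`.
#' @export
standard_enrichment <- function(calls, ontology, alpha = 0.05, levels = 1:4) {
  N <- length(ontology$background)
  scps <- ontology$scps[ontology$scps$level %in% levels, ]
  unit_sizes <- vapply(
    scps$scp_id,
    function(id) length(intersect(ontology$annotations[[id]],
                                  ontology$background)),
    integer(1), USE.NAMES = FALSE
  )
  strata <- unique(calls[, c("time_h", "direction")])
  strata <- strata[order(strata$time_h, strata$direction), ]
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    genes <- calls$feature[calls$time_h == strata$time_h[i] &
                             calls$direction == strata$direction[i]]
    genes <- intersect(unique(toupper(genes)), ontology$background)
    if (length(genes) == 0) {
      warning("empty gene list at ", strata$time_h[i], " h (",
              strata$direction[i], "); stratum skipped", call. = FALSE)
      next
    }
    overlap <- vapply(
      scps$scp_id,
      function(id) length(intersect(ontology$annotations[[id]], genes)),
      integer(1), USE.NAMES = FALSE
    )
    p <- fisher_overrep_p(overlap, unit_sizes, length(genes), N)
    out[[i]] <- tibble::tibble(
      scp_id = scps$scp_id,
      level = scps$level,
      time_h = strata$time_h[i],
      direction = strata$direction[i],
      overlap = overlap,
      unit_size = unit_sizes,
      list_size = length(genes),
      background_size = N,
      p_value = p,
      significant = p <= alpha
    )
  }
  dplyr::bind_rows(out)
}

#' Generate function-specific SCP combinations from seed SCPs
#'
#' Combines seed SCPs of one level into candidate higher-order units:
#' every unordered pair whose horizontal interaction strength reaches the
#' level's top-fraction cutoff, and every unordered triple whose three
#' members form a connected subgraph under the above-cutoff interactions
#' (at least two of the three pairwise edges; `require_clique = TRUE`
#' demands all three).  Each combination's gene set is the union of its
#' members' annotations.
#'
#' @param seed_scps character vector of SCP ids, all of the same level.
#' @param ontology an `scp_ontology`.
#' @param top_fraction interaction strength percentile (0.20 is the
#'   working default for level-2 networks, 0.25 for level-3).
#' @param require_clique if `TRUE`, triples need all three edges.
#' @return Tibble: `unit_id`, `members` (list column), `n_members`.
#' @export
generate_combinations <- function(seed_scps, ontology, top_fraction,
                                  require_clique = FALSE) {
  seed_scps <- unique(seed_scps)
  empty <- tibble::tibble(unit_id = character(), members = list(),
                          n_members = integer())
  if (length(seed_scps) < 2) return(empty)
  lev <- stats::setNames(ontology$scps$level, ontology$scps$scp_id)
  seed_lev <- unique(lev[seed_scps])
  if (length(seed_lev) != 1 || anyNA(seed_lev)) {
    stop("seed SCPs must all exist and share one level", call. = FALSE)
  }
  ia <- top_interactions(ontology, seed_lev, top_fraction)
  ia <- ia[ia$scp_a %in% seed_scps & ia$scp_b %in% seed_scps, ]
  if (nrow(ia) == 0) return(empty)
  edge_key <- paste(ia$scp_a, ia$scp_b)
  has_edge <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% edge_key

  pairs <- tibble::tibble(
    unit_id = paste(ia$scp_a, ia$scp_b, sep = "+"),
    members = unname(Map(c, ia$scp_a, ia$scp_b)),
    n_members = 2L
  )

  triples <- empty
  seeds_in_graph <- sort(unique(c(ia$scp_a, ia$scp_b)))
  if (length(seeds_in_graph) >= 3) {
    combs <- utils::combn(seeds_in_graph, 3, simplify = FALSE)
    keep <- vapply(combs, function(m) {
      e <- c(has_edge(m[1], m[2]), has_edge(m[1], m[3]), has_edge(m[2], m[3]))
      if (require_clique) all(e) else sum(e) >= 2
    }, logical(1))
    combs <- combs[keep]
    if (length(combs) > 0) {
      triples <- tibble::tibble(
        unit_id = vapply(combs, paste, character(1), collapse = "+"),
        members = combs,
        n_members = 3L
      )
    }
  }
  dplyr::bind_rows(pairs, triples)
}

#' Dynamic enrichment analysis
#'
#' The combination-aware enrichment step: level SCPs containing at least
#' one query gene become seeds; seeds are combined into function-specific
#' pairs and triples via [generate_combinations()]; every candidate unit
#' (single seeds plus combinations, unless `include_singles = FALSE`) is
#' Fisher-tested against the query list; results are ranked by p-value
#' with a deterministic tie-break (smaller p, then fewer member SCPs,
#' then larger overlap, then lexicographic unit id) and the top `top_k`
#' predictions are returned.
#'
#' @param gene_list character vector of query genes.
#' @param ontology an `scp_ontology` restricted to the assay background.
#' @param level SCP level to analyse (2 or 3 in routine use).
#' @param top_fraction interaction percentile; defaults to 0.20 for
#'   level 2 and 0.25 for level 3.
#' @param top_k number of predictions kept; defaults to 3 for level 2 and
#'   5 for level 3.
#' @param include_singles test single seed SCPs alongside combinations
#'   (default `TRUE`).
#' @param require_clique passed to [generate_combinations()].
#' @return Tibble of ranked predictions: `rank`, `unit_id`, `members`
#'   (list column), `n_members`, `overlap`, `unit_size`, `list_size`,
#'   `background_size`, `p_value`.  Zero rows when no seed contains a
#'   query gene.
#' @export
dynamic_enrichment <- function(gene_list, ontology, level,
                               top_fraction = if (level == 3) 0.25 else 0.20,
                               top_k = if (level == 3) 5L else 3L,
                               include_singles = TRUE,
                               require_clique = FALSE) {
  genes <- intersect(unique(toupper(gene_list)), ontology$background)
  empty <- tibble::tibble(
    rank = integer(), unit_id = character(), members = list(),
    n_members = integer(), overlap = integer(), unit_size = integer(),
    list_size = integer(), background_size = integer(), p_value = numeric()
  )
  if (length(genes) == 0) return(empty)

  level_ids <- ontology$scps$scp_id[ontology$scps$level == level]
  seeds <- level_ids[vapply(
    level_ids,
    function(id) length(intersect(ontology$annotations[[id]], genes)) > 0,
    logical(1)
  )]
  if (length(seeds) == 0) return(empty)

  units <- tibble::tibble(unit_id = seeds, members = as.list(seeds),
                          n_members = 1L)
  combos <- generate_combinations(seeds, ontology, top_fraction,
                                  require_clique = require_clique)
  units <- if (include_singles) dplyr::bind_rows(units, combos) else combos
  if (nrow(units) == 0) return(empty)

  N <- length(ontology$background)
  unit_genes <- lapply(units$members, function(m) {
    intersect(scp_genes(ontology, m), ontology$background)
  })
  unit_size <- lengths(unit_genes)
  overlap <- vapply(unit_genes, function(g) length(intersect(g, genes)),
                    integer(1))
  p <- fisher_overrep_p(overlap, unit_size, length(genes), N)

  res <- tibble::tibble(
    unit_id = units$unit_id, members = units$members,
    n_members = units$n_members, overlap = overlap, unit_size = unit_size,
    list_size = length(genes), background_size = N, p_value = p
  )
  ord <- order(res$p_value, res$n_members, -res$overlap, res$unit_id)
  res <- res[ord, ]
  res <- utils::head(res, top_k)
  res$rank <- seq_len(nrow(res))
  dplyr::relocate(res, "rank")
}

#' Build an SCP network from ranked dynamic-enrichment predictions
#'
#' Nodes are all member SCPs of the retained top predictions; two SCPs
#' are joined by an edge when they were predicted as part of the same
#' function-specific combination (a triple contributes its full clique of
#' three edges).  Node and edge tables carry the time point, direction
#' and the prediction that certifies them.
#'
#' @param predictions tibble as returned by [dynamic_enrichment()],
#'   optionally with `time_h` and `direction` columns attached (several
#'   strata may be concatenated).
#' @return List with tibbles `nodes` (`scp_id`, `time_h`, `direction`)
#'   and `edges` (`scp_a`, `scp_b`, `time_h`, `direction`, `unit_id`).
#' @export
build_scp_network <- function(predictions) {
  if (nrow(predictions) == 0) {
    return(list(
      nodes = tibble::tibble(scp_id = character(), time_h = numeric(),
                             direction = character()),
      edges = tibble::tibble(scp_a = character(), scp_b = character(),
                             time_h = numeric(), direction = character(),
                             unit_id = character())
    ))
  }
  if (!"time_h" %in% names(predictions)) predictions$time_h <- NA_real_
  if (!"direction" %in% names(predictions)) {
    predictions$direction <- NA_character_
  }
  nodes <- list()
  edges <- list()
  for (i in seq_len(nrow(predictions))) {
    m <- sort(predictions$members[[i]])
    nodes[[i]] <- tibble::tibble(
      scp_id = m,
      time_h = predictions$time_h[i],
      direction = predictions$direction[i]
    )
    if (length(m) >= 2) {
      pr <- utils::combn(m, 2)
      edges[[length(edges) + 1]] <- tibble::tibble(
        scp_a = pr[1, ], scp_b = pr[2, ],
        time_h = predictions$time_h[i],
        direction = predictions$direction[i],
        unit_id = predictions$unit_id[i]
      )
    }
  }
  list(
    nodes = dplyr::distinct(dplyr::bind_rows(nodes)),
    edges = dplyr::distinct(dplyr::bind_rows(edges))
  )
}

#' Assemble per-SCP enrichment timelines
#'
#' Reshapes standard-enrichment results into one -log10(p) series per SCP
#' and direction across all time points.  Time points at which an SCP was
#' not tested stay `NA` (absent, not zero).  The -log10 of the
#' significance level is attached as the `signif_line` attribute, for
#' plotting the usual dotted cutoff line.
#'
#' @param results tibble from [standard_enrichment()].
#' @param alpha significance level carried as metadata, default 0.05.
#' @return Long tibble: `scp_id`, `direction`, `time_h`, `neg_log10_p`,
#'   with attribute `signif_line = -log10(alpha)`.
#' @export
assemble_timelines <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) > 0)
  grid <- tidyr::expand_grid(
    scp_id = unique(results$scp_id),
    direction = unique(results$direction),
    time_h = sort(unique(results$time_h))
  )
  tl <- grid |>
    dplyr::left_join(
      dplyr::transmute(results, .data$scp_id, .data$direction, .data$time_h,
                       neg_log10_p = -log10(.data$p_value)),
      by = c("scp_id", "direction", "time_h")
    )
  attr(tl, "signif_line") <- -log10(alpha)
  tl
}
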