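#' Leveled subcellular-process (SCP) ontology
#'
#' An `scp_ontology` bundles everything the enrichment machinery needs:
#' a leveled hierarchy of subcellular processes (levels 1--4, level 1 most
#' general), per-SCP gene annotations, horizontal interaction strengths
#' between SCPs of the same level, and a background gene universe against
#' which all Fisher tables are built.
#'
#' @param scps tibble with columns `scp_id`, `name`, `level`.
#' @param parents tibble with columns `scp_id`, `parent_id` (one row per
#'   vertical parent-child link; level-1 SCPs have no rows).
#' @param annotations named list mapping `scp_id` to a character vector of
#'   gene symbols (upper-cased, unique).
#' @param interactions tibble with columns `scp_a`, `scp_b`, `level`,
#'   `strength` (unordered pairs stored with `scp_a < scp_b`).
#' @param background character vector of gene symbols forming the test
#'   universe.
#'
#' @return A validated object of class `scp_ontology`.
#' @export
scp_ontology <- function(scps, parents, annotations, interactions, background) {
  scps <- tibble::as_tibble(scps)
  parents <- tibble::as_tibble(parents)
  interactions <- tibble::as_tibble(interactions)
  obj <- structure(
    list(
      scps = scps,
      parents = parents,
      annotations = lapply(annotations, function(g) unique(toupper(g))),
      interactions = interactions,
      background = unique(toupper(background))
    ),
    class = "scp_ontology"
  )
  validate_ontology(obj)
}

#' Validate an SCP ontology
#'
#' Checks the structural invariants: levels in 1--4, parent links resolve
#' and point one level up, interaction endpoints exist and share a level,
#' unordered interaction pairs are unique, annotated genes (after
#' restriction) live in the background, and the parent graph is acyclic.
#'
#' @param ontology an `scp_ontology`.
#' @return The ontology, invisibly unchanged, or an error.
#' @export
validate_ontology <- function(ontology) {
  stopifnot(inherits(ontology, "scp_ontology"))
  scps <- ontology$scps
  if (anyDuplicated(scps$scp_id) > 0) {
    stop("duplicate scp_id in ontology", call. = FALSE)
  }
  if (!all(scps$level %in% 1:4)) {
    stop("SCP levels must be integers in 1..4", call. = FALSE)
  }
  lev <- stats::setNames(scps$level, scps$scp_id)

  par <- ontology$parents
  if (nrow(par) > 0) {
    missing <- setdiff(c(par$scp_id, par$parent_id), scps$scp_id)
    if (length(missing) > 0) {
      stop("parent link references unknown SCP: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bad <- lev[par$parent_id] != lev[par$scp_id] - 1L
    if (any(bad)) {
      stop("parent links must point exactly one level up", call. = FALSE)
    }
    if (any(lev[par$scp_id] == 1L)) {
      stop("level-1 SCPs cannot have parents", call. = FALSE)
    }
  }

  ia <- ontology$interactions
  if (nrow(ia) > 0) {
    missing <- setdiff(c(ia$scp_a, ia$scp_b), scps$scp_id)
    if (length(missing) > 0) {
      stop("interaction references unknown SCP: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(ia$scp_a == ia$scp_b)) {
      stop("self-interactions are not allowed", call. = FALSE)
    }
    if (any(lev[ia$scp_a] != lev[ia$scp_b])) {
      stop("interactions must connect SCPs of the same level", call. = FALSE)
    }
    if (any(lev[ia$scp_a] != ia$level)) {
      stop("interaction level column disagrees with endpoint levels",
           call. = FALSE)
    }
    key <- paste(pmin(ia$scp_a, ia$scp_b), pmax(ia$scp_a, ia$scp_b))
    if (anyDuplicated(key) > 0) {
      stop("duplicate unordered interaction pair", call. = FALSE)
    }
    if (any(!is.finite(ia$strength)) || any(ia$strength < 0)) {
      stop("interaction strengths must be finite and non-negative",
           call. = FALSE)
    }
  }

  ann <- ontology$annotations
  unknown <- setdiff(names(ann), scps$scp_id)
  if (length(unknown) > 0) {
    stop("annotations for unknown SCP: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(ann, function(g) any(!nzchar(g)), logical(1)))) {
    stop("empty gene symbol in annotations", call. = FALSE)
  }
  invisible(ontology)
}

#' @export
print.scp_ontology <- function(x, ...) {
  n_lev <- table(factor(x$scps$level, levels = 1:4))
  cat("<scp_ontology>\n")
  cat("  SCPs per level:", paste(sprintf("L%d=%d", 1:4, n_lev), collapse = " "),
      "\n")
  cat("  annotated genes:", length(unique(unlist(x$annotations))), "\n")
  cat("  horizontal interactions:", nrow(x$interactions), "\n")
  cat("  background size:", length(x$background), "\n")
  invisible(x)
}

#' Genes annotated to an SCP
#'
#' @param ontology an `scp_ontology`.
#' @param scp_id one or more SCP identifiers; the union of their gene sets
#'   is returned.
#' @return Character vector of gene symbols.
#' @export
scp_genes <- function(ontology, scp_id) {
  unique(unlist(ontology$annotations[scp_id], use.names = FALSE))
}

# read a GMT file (set_id <tab> description <tab> members...) into a named
# list of unique upper-cased gene vectors; parsing itself is delegated to
# fgsea's GMT reader
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(g) unique(toupper(g)))
}

#' Load an SCP ontology from its standard text files
#'
#' Reads the four text inputs that describe a leveled SCP ontology:
#' a hierarchy TSV (`scp_id`, `parent_id`, `level`, `name`; empty or `NA`
#' parent for level-1 SCPs), a GMT annotation file (one SCP gene set per
#' line: id, description, members), an interaction TSV (`scp_a`, `scp_b`,
#' `strength`), and a background gene list (one symbol per line).  Gene
#' symbols are upper-cased throughout; duplicate annotations within an SCP
#' are collapsed.  A short load report (SCP counts per level) is emitted
#' with `message()`.
#'
#' @param hierarchy_file,annotation_file,interaction_file,background_file
#'   paths to the four inputs.
#' @return An `scp_ontology`.
#' @export
load_ontology <- function(hierarchy_file, annotation_file, interaction_file,
                          background_file) {
  hier <- utils::read.delim(hierarchy_file, stringsAsFactors = FALSE)
  need <- c("scp_id", "parent_id", "level", "name")
  if (!all(need %in% names(hier))) {
    stop("hierarchy file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scps <- tibble::tibble(
    scp_id = as.character(hier$scp_id),
    name = as.character(hier$name),
    level = as.integer(hier$level)
  )
  has_parent <- !is.na(hier$parent_id) & nzchar(hier$parent_id)
  parents <- tibble::tibble(
    scp_id = as.character(hier$scp_id[has_parent]),
    parent_id = as.character(hier$parent_id[has_parent])
  )

  ann <- read_gmt(annotation_file)

  ia <- utils::read.delim(interaction_file, stringsAsFactors = FALSE)
  if (!all(c("scp_a", "scp_b", "strength") %in% names(ia))) {
    stop("interaction file must have columns scp_a, scp_b, strength",
         call. = FALSE)
  }
  missing <- setdiff(c(ia$scp_a, ia$scp_b), scps$scp_id)
  if (length(missing) > 0) {
    stop("interaction references unknown SCP: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  lev <- stats::setNames(scps$level, scps$scp_id)
  interactions <- tibble::tibble(
    scp_a = pmin(as.character(ia$scp_a), as.character(ia$scp_b)),
    scp_b = pmax(as.character(ia$scp_a), as.character(ia$scp_b)),
    level = as.integer(lev[as.character(ia$scp_a)]),
    strength = as.numeric(ia$strength)
  )

  background <- toupper(readLines(background_file, warn = FALSE))
  background <- background[nzchar(background)]

  ont <- scp_ontology(scps, parents, ann, interactions, background)
  counts <- table(factor(ont$scps$level, levels = 1:4))
  message("loaded ontology: ",
          paste(sprintf("%d level-%d", counts, 1:4), collapse = ", "),
          " SCPs; ", nrow(ont$interactions), " interactions; background ",
          length(ont$background), " genes")
  ont
}

#' Replace gene symbols via an ortholog table
#'
#' Applies a two-column mapping (e.g. human-to-mouse orthologs) to every
#' annotation and to the background.  Symbols absent from the table are
#' kept unchanged; mapping is case-insensitive.
#'
#' @param ontology an `scp_ontology`.
#' @param map data frame with columns `from`, `to`.
#' @return The remapped `scp_ontology`.
#' @export
map_orthologs <- function(ontology, map) {
  stopifnot(all(c("from", "to") %in% names(map)))
  lut <- stats::setNames(toupper(map$to), toupper(map$from))
  remap <- function(g) {
    hit <- g %in% names(lut)
    g[hit] <- lut[g[hit]]
    unique(g)
  }
  ontology$annotations <- lapply(ontology$annotations, remap)
  ontology$background <- remap(ontology$background)
  validate_ontology(ontology)
  ontology
}

#' Restrict an ontology to measurable genes
#'
#' Keeps in each SCP, and in the background, only genes that had a chance
#' of being observed by the assay at hand (e.g. genes on the reference
#' genome for RNA-seq, or proteins in the search database for proteomics).
#' SCPs are never removed, only depleted; the new background is the
#' intersection of the old background with the measurable set.
#'
#' @param ontology an `scp_ontology`.
#' @param measurable_genes non-empty character vector of gene symbols.
#' @return The restricted `scp_ontology`.
#' @export
restrict_to_background <- function(ontology, measurable_genes) {
  if (length(measurable_genes) == 0) {
    stop("measurable_genes must be non-empty", call. = FALSE)
  }
  keep <- intersect(ontology$background, unique(toupper(measurable_genes)))
  if (length(keep) == 0) {
    stop("no measurable gene is part of the background; ",
         "check symbol conventions", call. = FALSE)
  }
  ontology$background <- keep
  ontology$annotations <- lapply(ontology$annotations, intersect, y = keep)
  validate_ontology(ontology)
  ontology
}

#' Add a composite SCP built from existing SCPs
#'
#' Creates a new SCP whose gene set is the union of the member gene sets
#' (used, for instance, to gather mitochondria-related SCPs scattered over
#' several ontology branches under one umbrella process).  Members whose
#' level is exactly one below the composite's level are re-parented to it;
#' all original SCPs are retained.
#'
#' @param ontology an `scp_ontology`.
#' @param new_id,new_name identifier and display name of the composite.
#' @param level level of the composite SCP (1--4).
#' @param member_scp_ids non-empty character vector of existing SCP ids.
#' @param include_in_interactions should the composite take part in
#'   horizontal-interaction percentile computations?  Default `FALSE`: the
#'   composite carries no interactions of its own and its creation must not
#'   shift the strength cutoffs of the level it joins.
#' @return The extended `scp_ontology`.
#' @export
create_composite_scp <- function(ontology, new_id, new_name, level,
                                 member_scp_ids,
                                 include_in_interactions = FALSE) {
  if (length(member_scp_ids) == 0) {
    stop("composite SCP needs at least one member", call. = FALSE)
  }
  if (new_id %in% ontology$scps$scp_id) {
    stop("scp_id already exists: ", new_id, call. = FALSE)
  }
  missing <- setdiff(member_scp_ids, ontology$scps$scp_id)
  if (length(missing) > 0) {
    stop("unknown member SCP: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(level %in% 1:4)

  ontology$scps <- dplyr::bind_rows(
    ontology$scps,
    tibble::tibble(scp_id = new_id, name = new_name, level = as.integer(level))
  )
  ontology$annotations[[new_id]] <- scp_genes(ontology, member_scp_ids)

  lev <- stats::setNames(ontology$scps$level, ontology$scps$scp_id)
  children <- member_scp_ids[lev[member_scp_ids] == level + 1L]
  if (length(children) > 0) {
    ontology$parents <- dplyr::bind_rows(
      ontology$parents,
      tibble::tibble(scp_id = children, parent_id = new_id)
    )
  }
  attr(ontology$annotations[[new_id]], "composite") <- TRUE
  if (!include_in_interactions) {
    # marker consulted by interaction_strength_cutoff()
    excl <- attr(ontology, "interaction_excluded")
    attr(ontology, "interaction_excluded") <- union(excl, new_id)
  }
  validate_ontology(ontology)
  ontology
}

#' Strength threshold for the top fraction of same-level interactions
#'
#' Returns the strength value such that interactions of the given level
#' with `strength >= threshold` make up the requested top fraction of that
#' level's interactions.  Ties at the threshold are included, so the top
#' set can be slightly larger than `top_fraction` of the level.
#'
#' @param ontology an `scp_ontology`.
#' @param level interaction level (1--4).
#' @param top_fraction fraction in (0, 1]; e.g. 0.20 keeps the strongest
#'   fifth of the level's interactions.
#' @return The threshold strength (numeric scalar).
#' @export
interaction_strength_cutoff <- function(ontology, level, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  ia <- ontology$interactions
  excl <- attr(ontology, "interaction_excluded")
  if (length(excl) > 0) {
    ia <- ia[!(ia$scp_a %in% excl | ia$scp_b %in% excl), ]
  }
  s <- sort(ia$strength[ia$level == level], decreasing = TRUE)
  if (length(s) == 0) {
    stop("no horizontal interactions at level ", level, call. = FALSE)
  }
  k <- ceiling(top_fraction * length(s))
  s[k]
}

#' Interactions at or above the level's strength cutoff
#'
#' Convenience wrapper used by the combination generator: returns the
#' interaction rows of one level whose strength reaches the top-fraction
#' threshold (ties included).
#'
#' @inheritParams interaction_strength_cutoff
#' @return Tibble of interaction rows.
#' @export
top_interactions <- function(ontology, level, top_fraction) {
  thr <- interaction_strength_cutoff(ontology, level, top_fraction)
  ia <- ontology$interactions
  ia[ia$level == level & ia$strength >= thr, ]
}
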