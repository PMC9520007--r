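#' Write an ontology to its standard text files
#'
#' Emits the four text files read back by [load_ontology()]: hierarchy
#' TSV, GMT annotations, interaction TSV and background gene list.
#'
#' @param ontology an `scp_ontology`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_ontology_files <- function(ontology, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    hierarchy = file.path(dir, "hierarchy.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    interactions = file.path(dir, "interactions.tsv"),
    background = file.path(dir, "background.txt")
  )
  par_lut <- stats::setNames(ontology$parents$parent_id,
                             ontology$parents$scp_id)
  parent_of <- unname(par_lut[ontology$scps$scp_id])
  hier <- data.frame(
    scp_id = ontology$scps$scp_id,
    parent_id = ifelse(is.na(parent_of), "", parent_of),
    level = ontology$scps$level,
    name = ontology$scps$name
  )
  utils::write.table(hier, paths["hierarchy"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt <- vapply(names(ontology$annotations), function(id) {
    paste(c(id, "synthetic", ontology$annotations[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, paths["annotations"])
  utils::write.table(
    ontology$interactions[, c("scp_a", "scp_b", "strength")],
    paths["interactions"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(ontology$background, paths["background"])
  invisible(paths)
}

#' Write synthetic chamber scans as ImageJ-style CSVs plus manifest
#'
#' One two-column CSV (distance in um, mean gray value) per chamber on
#' the neurite side, and a manifest TSV locating each file.
#'
#' @param profiles output of [synth_profiles()].
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_profile_csvs <- function(profiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- profiles$manifest
  manifest$file <- file.path(dir, paste0(manifest$chamber, ".csv"))
  for (i in seq_len(nrow(manifest))) {
    utils::write.csv(profiles$raw[[manifest$chamber[i]]], manifest$file[i],
                     row.names = FALSE)
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
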