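#' Pseudocounted log2 fold change
#'
#' Fold change between FPKM-like abundances with a pseudocount of 1 on
#' both sides, `log2((treated + 1) / (control + 1))`, so that zero
#' abundances are defined and (0, 0) maps to 0.
#'
#' @param treated,control non-negative finite abundances (vectorised).
#' @return Numeric vector of log2 fold changes.
#' @export
log2fc_pseudocount <- function(treated, control) {
  if (any(!is.finite(treated)) || any(!is.finite(control)) ||
      any(treated < 0) || any(control < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  log2((treated + 1) / (control + 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1), delegated to
#' `stats::p.adjust(method = "BH")` after domain checks.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the two DEG filters to a per-gene, per-time-point expression
#' table: adjusted p-value at most `fdr_alpha` AND absolute pseudocounted
#' log2 fold change at least `min_abs_log2fc`.  Both cutoffs are
#' inclusive.  If the table carries only raw p-values (`p` column, no
#' `p_adj`), Benjamini-Hochberg adjustment is applied within each time
#' point first.
#'
#' @param records tibble with columns `gene`, `time_h`, `fpkm_treated`,
#'   `fpkm_control`, and `p_adj` (or `p`).
#' @param fdr_alpha FDR level, default 0.05.
#' @param min_abs_log2fc minimum absolute log2 fold change; e.g.
#'   `log2(1.5)` for the stringent gene list or `log2(1.3)` for the
#'   relaxed one.
#' @return Tibble of calls: `feature`, `time_h`, `log2_fold_change`,
#'   `direction` (`"up"`/`"down"`), `significance` (the adjusted p).
#' @export
call_degs <- function(records, fdr_alpha = 0.05, min_abs_log2fc) {
  stopifnot(min_abs_log2fc >= 0)
  records <- tibble::as_tibble(records)
  need <- c("gene", "time_h", "fpkm_treated", "fpkm_control")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"p_adj" %in% names(records)) {
    if (!"p" %in% names(records)) {
      stop("records must carry p_adj (or raw p for BH adjustment)",
           call. = FALSE)
    }
    records <- records |>
      dplyr::group_by(.data$time_h) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  }
  if (any(is.na(records$p_adj))) {
    stop("missing p-values in expression records", call. = FALSE)
  }
  records |>
    dplyr::mutate(
      log2_fold_change = log2fc_pseudocount(.data$fpkm_treated,
                                            .data$fpkm_control)
    ) |>
    dplyr::filter(.data$p_adj <= fdr_alpha,
                  abs(.data$log2_fold_change) >= min_abs_log2fc) |>
    dplyr::transmute(
      feature = toupper(.data$gene),
      time_h = .data$time_h,
      log2_fold_change = .data$log2_fold_change,
      direction = ifelse(.data$log2_fold_change >= 0, "up", "down"),
      significance = .data$p_adj
    ) |>
    dplyr::arrange(.data$time_h, .data$feature)
}

#' Features differential at least one time point
#'
#' @param calls output of [call_degs()] or [call_deps()].
#' @return Character vector of unique feature symbols.
#' @export
union_over_time <- function(calls) {
  sort(unique(calls$feature))
}

#' Normalize a proteomics run against its untreated references
#'
#' Within each run, every treated or vehicle sample value of a protein is
#' divided by the mean value of that protein across the run's untreated
#' samples; untreated values themselves are left untouched.  Proteins
#' whose untreated mean is zero or that are absent from the run's
#' untreated samples are flagged and excluded with a warning.
#'
#' @param records long tibble with columns `protein`, `peptides`, `run`,
#'   `sample`, `role` (`"treated"`, `"vehicle"` or `"untreated"`), `value`.
#' @return The tibble with an added `normalized` column (NA rows removed).
#' @export
normalize_proteomics_run <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("protein", "peptides", "run", "sample", "role", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$role %in% c("treated", "vehicle", "untreated"))) {
    stop("role must be one of treated/vehicle/untreated", call. = FALSE)
  }
  ref <- records |>
    dplyr::filter(.data$role == "untreated") |>
    dplyr::group_by(.data$run, .data$protein) |>
    dplyr::summarise(untreated_mean = mean(.data$value), .groups = "drop")

  out <- records |>
    dplyr::left_join(ref, by = c("run", "protein")) |>
    dplyr::mutate(
      normalized = dplyr::case_when(
        .data$role == "untreated" ~ .data$value,
        TRUE ~ .data$value / .data$untreated_mean
      )
    )

  bad <- out$role != "untreated" &
    (is.na(out$untreated_mean) | out$untreated_mean <= 0)
  if (any(bad)) {
    flagged <- unique(out$protein[bad])
    warning("excluding ", length(flagged),
            " protein(s) without usable untreated reference: ",
            paste(utils::head(flagged, 5), collapse = ", "),
            if (length(flagged) > 5) ", ..." else "",
            call. = FALSE)
    out <- out[!out$protein %in% flagged, ]
  }
  dplyr::select(out, -"untreated_mean")
}

#' Call differentially expressed proteins
#'
#' Implements the proteomics filter chain: proteins identified by fewer
#' than `min_peptides` distinct peptides are dropped first; remaining
#' proteins are tested treated vs. vehicle with a two-sided two-sample
#' t-test under equal variance on log2 normalized values; a call requires
#' p at most `alpha` AND an absolute mean log2 ratio of at least
#' `min_abs_log2fc` (both inclusive).  Replicates are pooled across runs
#' by default; `per_run = TRUE` tests each run separately instead.
#'
#' @param records long proteomics tibble (see
#'   [normalize_proteomics_run()]); a `normalized` column is computed if
#'   absent.
#' @param alpha nominal p cutoff, default 0.05.
#' @param min_abs_log2fc minimum absolute mean log2 ratio, default
#'   `log2(1.1)`.
#' @param min_peptides minimum number of distinct peptides, default 2.
#' @param per_run test within runs instead of pooling, default `FALSE`.
#' @param time_h time point label attached to the calls (default `NA`).
#' @return Tibble of calls with the same shape as [call_degs()] output.
#' @export
call_deps <- function(records, alpha = 0.05, min_abs_log2fc = log2(1.1),
                      min_peptides = 2, per_run = FALSE, time_h = NA_real_) {
  records <- tibble::as_tibble(records)
  if (!"normalized" %in% names(records)) {
    records <- normalize_proteomics_run(records)
  }
  records <- records[records$peptides >= min_peptides, ]
  records <- records[records$role %in% c("treated", "vehicle"), ]
  if (nrow(records) == 0) {
    return(tibble::tibble(feature = character(), time_h = numeric(),
                          log2_fold_change = numeric(),
                          direction = character(), significance = numeric()))
  }
  grouping <- if (per_run) c("protein", "run") else "protein"
  res <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(function(d, key) {
      tr <- log2(d$normalized[d$role == "treated"])
      vh <- log2(d$normalized[d$role == "vehicle"])
      if (length(tr) < 2 || length(vh) < 2) {
        warning("protein skipped (fewer than 2 replicates per group): ",
                key$protein, call. = FALSE)
        return(tibble::tibble())
      }
      lfc <- mean(tr) - mean(vh)
      if (stats::sd(c(tr - mean(tr), vh - mean(vh))) == 0) {
        p <- if (lfc == 0) 1 else 0
      } else {
        p <- stats::t.test(tr, vh, var.equal = TRUE)$p.value
      }
      tibble::tibble(log2_fold_change = lfc, p_value = p)
    }) |>
    dplyr::ungroup()
  if (!"p_value" %in% names(res)) {   # every protein skipped
    return(tibble::tibble(feature = character(), time_h = numeric(),
                          log2_fold_change = numeric(),
                          direction = character(), significance = numeric()))
  }
  res |>
    dplyr::filter(.data$p_value <= alpha,
                  abs(.data$log2_fold_change) >= min_abs_log2fc) |>
    dplyr::transmute(
      feature = toupper(.data$protein),
      time_h = time_h,
      log2_fold_change = .data$log2_fold_change,
      direction = ifelse(.data$log2_fold_change >= 0, "up", "down"),
      significance = .data$p_value
    ) |>
    dplyr::arrange(.data$feature)
}
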