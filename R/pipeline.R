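#' Run the full PPI identification pipeline
#'
#' Reproduces the complete flow for one or two crosslinker datasets:
#' prefilter CSMs, deduplicate, grouped cascaded FDR at PPI level per
#' dataset, local-FDR score normalisation, and — with two datasets —
#' concatenation and re-thresholding of the combined table at
#' `alpha_merge` heteromeric PPI-FDR. Deterministic for fixed inputs.
#'
#' @param datasets A CSM tibble, a file path, or a (optionally named) list
#'   of one or two of either.
#' @param alpha_dataset Per-dataset PPI-FDR threshold (default 0.01).
#' @param alpha_merge FDR threshold for the merged table (default 0.01).
#' @param min_fragments,delta_ratio,min_peptide_length Prefilter settings.
#' @param group_self_separately,cascade FDR settings (see [apply_fdr()]).
#' @param window Local-FDR normalisation window (see [normalize_scores()]).
#' @param decoy_prefix Accession prefix marking decoys.
#' @param out_dir Optional directory; when given, per-dataset and merged
#'   result TSVs plus a JSON run report are written there.
#' @return A list of class `xl_pipeline`: `datasets` (per-dataset
#'   `xl_fdr_result`s), `merged` (`xl_fdr_result` or `NULL` for a single
#'   dataset), `final_ppis` (accepted heteromeric target PPIs of the final
#'   stage), `report` (nested list of parameters and per-stage counts).
#' @export
run_pipeline <- function(datasets, alpha_dataset = 0.01, alpha_merge = 0.01,
                         min_fragments = 3L, delta_ratio = 0.15,
                         min_peptide_length = 6L,
                         group_self_separately = TRUE, cascade = TRUE,
                         window = 101L, decoy_prefix = "REV_",
                         out_dir = NULL) {
  if (is_tibble(datasets) || is.character(datasets)) datasets <- list(datasets)
  if (length(datasets) < 1 || length(datasets) > 2) {
    abort("supply one or two datasets", class = "xlinkfdr_config_error")
  }
  names(datasets) <- names(datasets) %||%
    paste0("dataset_", seq_along(datasets))
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("dataset_", seq_along(datasets))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "xlinkfdr_stage_error")
    })
  }

  results <- list()
  report <- list(parameters = list(
    alpha_dataset = alpha_dataset, alpha_merge = alpha_merge,
    min_fragments = min_fragments, delta_ratio = delta_ratio,
    min_peptide_length = min_peptide_length,
    group_self_separately = group_self_separately, cascade = cascade,
    window = window, decoy_prefix = decoy_prefix))
  normalized <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    csms <- stage(paste0(nm, "/read"), {
      if (is.character(d)) {
        if (!file.exists(d)) abort(paste0("input not found: ", d))
        read_csm_table(d, decoy_prefix = decoy_prefix)
      } else d
    })
    filtered <- stage(paste0(nm, "/filter"), filter_csms(
      csms, min_fragments = min_fragments, delta_ratio = delta_ratio,
      min_peptide_length = min_peptide_length, decoy_prefix = decoy_prefix))
    unique_csms <- stage(paste0(nm, "/dedupe"), deduplicate_csms(filtered))
    matches <- stage(paste0(nm, "/aggregate"),
                     as_matches(unique_csms, decoy_prefix = decoy_prefix))
    res <- stage(paste0(nm, "/fdr"), apply_fdr(
      matches, level = "ppi", alpha = alpha_dataset,
      group_self_separately = group_self_separately, cascade = cascade))
    normalized[[nm]] <- stage(paste0(nm, "/normalize"), normalize_scores(
      as_tibble(res$curve)[, names(matches)], window = window,
      group_self_separately = group_self_separately))
    results[[nm]] <- res
    report$stages[[nm]] <- list(
      n_input = nrow(csms),
      n_filtered = nrow(filtered),
      rejections = as.list(rejection_counts(filtered)),
      n_unique_csms = nrow(unique_csms),
      n_ppi_records = nrow(res$curve),
      n_accepted_tt = nrow(res$accepted),
      n_accepted_het_tt = sum(!res$accepted$is_self),
      cutoffs = lapply(seq_len(nrow(res$cutoffs)),
                       function(i) as.list(res$cutoffs[i, ]))
    )
  }

  merged <- NULL
  if (length(datasets) == 2) {
    merged <- stage("merge_datasets", merge_datasets(
      normalized[[1]], normalized[[2]], alpha = alpha_merge,
      group_self_separately = group_self_separately))
    report$stages$merged <- list(
      n_records = nrow(merged$curve),
      n_accepted_tt = nrow(merged$accepted),
      n_accepted_het_tt = sum(!merged$accepted$is_self))
  }
  final <- if (is.null(merged)) results[[1]] else merged
  final_ppis <- final$accepted[!final$accepted$is_self, ]

  out <- structure(list(datasets = results, merged = merged,
                        final_ppis = final_ppis, report = report),
                   class = "xl_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      write_results_table(as_tibble(results[[nm]]$accepted),
                          file.path(out_dir, paste0(nm, "_ppis.tsv")))
    }
    if (!is.null(merged)) {
      write_results_table(as_tibble(merged$accepted),
                          file.path(out_dir, "merged_ppis.tsv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.xl_pipeline <- function(x, ...) {
  cat("<xl_pipeline>\n")
  for (nm in names(x$datasets)) {
    s <- x$report$stages[[nm]]
    cat(sprintf("  %s: %d CSMs -> %d filtered -> %d unique -> %d het TT PPIs\n",
                nm, s$n_input, s$n_filtered, s$n_unique_csms,
                s$n_accepted_het_tt))
  }
  if (!is.null(x$merged)) {
    cat(sprintf("  merged: %d heteromeric target PPIs accepted\n",
                nrow(x$final_ppis)))
  }
  invisible(x)
}
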