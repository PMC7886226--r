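#' Write an mQTL analysis report bundle
#'
#' Emits the tabular deliverables of a run into a directory:
#' `manhattan.tsv` (per-SNP detection rates with map positions and the
#' significance flag), `mqtl_summary.tsv` (one row per region),
#' `family_effects.tsv`, optionally `h2.tsv`, `runs.tsv` (per-run
#' prediction abilities) and `run_metadata.json` (seed, parameters and a
#' content hash). All writers are deterministic: identical inputs give
#' byte-identical files.
#'
#' @param detections `nam_detection` from [cross_validate()].
#' @param map Genetic map tibble.
#' @param dir Output directory (created if needed).
#' @param threshold Integer DR threshold used for the significance flag.
#' @param regions Optional `nam_regions` (with `region_r2` columns if
#'   computed).
#' @param family_effects Optional tibble from [family_effects()].
#' @param h2 Optional tibble of heritability results.
#' @param config Optional named list of run parameters to record.
#'
#' @return Invisibly, the named vector of file paths written.
#' @export
write_mqtl_report <- function(detections, map, dir, threshold = NULL,
                              regions = NULL, family_effects = NULL,
                              h2 = NULL, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  manhattan <- dplyr::inner_join(detections$detections, map, by = "snp_id") |>
    dplyr::arrange(.data$chrom, .data$pos_bp) |>
    dplyr::transmute(
      snp_id = .data$snp_id, chrom = .data$chrom, pos_bp = .data$pos_bp,
      dr = .data$dr, mean_beta = .data$mean_beta,
      significant = if (is.null(threshold)) NA else .data$dr >= threshold
    )
  paths["manhattan"] <- file.path(dir, "manhattan.tsv")
  readr::write_tsv(manhattan, paths["manhattan"], progress = FALSE)

  paths["runs"] <- file.path(dir, "runs.tsv")
  readr::write_tsv(detections$runs, paths["runs"], progress = FALSE)

  if (!is.null(regions)) {
    flat <- dplyr::mutate(
      regions,
      member_snps = vapply(.data$member_snps, paste, character(1),
                           collapse = ",")
    )
    paths["mqtl_summary"] <- file.path(dir, "mqtl_summary.tsv")
    readr::write_tsv(flat, paths["mqtl_summary"], progress = FALSE)
  }
  if (!is.null(family_effects)) {
    paths["family_effects"] <- file.path(dir, "family_effects.tsv")
    readr::write_tsv(family_effects, paths["family_effects"], progress = FALSE)
  }
  if (!is.null(h2)) {
    paths["h2"] <- file.path(dir, "h2.tsv")
    readr::write_tsv(h2, paths["h2"], progress = FALSE)
  }
  meta <- list(
    metabolite = detections$metabolite,
    n_runs = detections$n_runs,
    mean_r2 = detections$mean_r2,
    threshold = threshold,
    config = config,
    content_hash = rlang::hash(list(detections$detections, regions,
                                    family_effects, h2))
  )
  paths["metadata"] <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

#' Read back a report bundle
#'
#' @param dir Directory written by [write_mqtl_report()].
#' @return Named list of tibbles (and the metadata list).
#' @export
read_mqtl_report <- function(dir) {
  out <- list(
    manhattan = readr::read_tsv(file.path(dir, "manhattan.tsv"),
                                show_col_types = FALSE, progress = FALSE),
    runs = readr::read_tsv(file.path(dir, "runs.tsv"),
                           show_col_types = FALSE, progress = FALSE),
    metadata = jsonlite::read_json(file.path(dir, "run_metadata.json"))
  )
  for (nm in c("mqtl_summary", "family_effects", "h2")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p)) {
      out[[nm]] <- readr::read_tsv(p, show_col_types = FALSE,
                                   progress = FALSE)
    }
  }
  out
}
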