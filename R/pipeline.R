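#' CRISPR-Cas prevalence percentage
#'
#' Percentage of genomes carrying at least one complete system, rounded
#' half-up to one decimal.
#'
#' @param n_with_system Number of genomes with a complete system.
#' @param n_genomes Total number of genomes (> 0).
#' @return Percentage, one decimal.
#' @export
#' @examples
#' prevalence(2, 27)   # 7.4
prevalence <- function(n_with_system, n_genomes) {
  if (n_genomes <= 0) {
    abort("n_genomes must be positive", class = "phagecode_division_error")
  }
  stopifnot(n_with_system >= 0, n_with_system <= n_genomes)
  round_half_up(100 * n_with_system / n_genomes, 1)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold with its default, plus input paths, the
#' random seed and the output directory. The object round-trips through
#' YAML unchanged ([write_config()] / [read_config()]).
#'
#' @param genomes_fasta,phages_fasta,cas_tsv,host_map_tsv Input paths (may
#'   be NULL when the corresponding tibbles are passed to [run_pipeline()]
#'   directly).
#' @param out_dir Output directory.
#' @param min_coverage,max_mismatch Spacer-matching thresholds.
#' @param min_orf_len,density_min_orf_len,size_floor,delta_threshold ORF /
#'   code-profiling parameters (`density_min_orf_len` is the long-ORF floor
#'   used for coding-density estimation; see [profile_code()]).
#' @param k_seed,min_spacers,min_repeat_identity,max_spacer_identity Array
#'   detector parameters.
#' @param window Backup-stop scan window (codons).
#' @param seed Random seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes_fasta = NULL, phages_fasta = NULL,
                            cas_tsv = NULL, host_map_tsv = NULL,
                            out_dir = NULL, min_coverage = 0.95,
                            max_mismatch = 1L, min_orf_len = 90L,
                            density_min_orf_len = 300L,
                            size_floor = 20000L, delta_threshold = 10,
                            k_seed = 8L, min_spacers = 3L,
                            min_repeat_identity = 0.90,
                            max_spacer_identity = 0.60, window = 10L,
                            seed = 1L) {
  structure(list(
    genomes_fasta = genomes_fasta, phages_fasta = phages_fasta,
    cas_tsv = cas_tsv, host_map_tsv = host_map_tsv, out_dir = out_dir,
    min_coverage = min_coverage, max_mismatch = as.integer(max_mismatch),
    min_orf_len = as.integer(min_orf_len),
    density_min_orf_len = as.integer(density_min_orf_len),
    size_floor = as.integer(size_floor),
    delta_threshold = delta_threshold, k_seed = as.integer(k_seed),
    min_spacers = as.integer(min_spacers),
    min_repeat_identity = min_repeat_identity,
    max_spacer_identity = max_spacer_identity, window = as.integer(window),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' End to end: detect CRISPR arrays in the host genomes, build the
#' dereplicated spacer database from high-evidence arrays, classify each
#' genome's CRISPR-Cas subtype from its cas annotations, match spacers
#' against the candidate phages, flag co-targeted phages, profile every
#' phage's genetic code, and summarise per-group prevalence. All outputs
#' are written under `config$out_dir` with deterministic bytes: the same
#' inputs, config and seed give byte-identical output trees.
#'
#' @param config A [pipeline_config()].
#' @param genomes,phages Optional sequence tibbles overriding the FASTA
#'   paths in `config`.
#' @param cas_annotations,host_map Optional tibbles overriding the TSV
#'   paths in `config`.
#' @return An object of class `phage_run`: a list with `arrays`,
#'   `spacer_db`, `cas_calls`, `budget`, `hits`, `links`, `cotargeted`,
#'   `profiles`, `prevalence`, `config`, `warnings`.
#' @export
run_pipeline <- function(config, genomes = NULL, phages = NULL,
                         cas_annotations = NULL, host_map = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  collected <- character(0)
  note <- function(msg) collected <<- c(collected, msg)

  genomes <- genomes %||% read_fasta(config$genomes_fasta)
  phages <- phages %||% read_fasta(config$phages_fasta)
  cas_annotations <- cas_annotations %||% read_cas_annotations(config$cas_tsv)
  host_map <- host_map %||% read_host_map(config$host_map_tsv)
  genomes <- check_seq_tbl(genomes, "genomes")
  phages <- check_seq_tbl(phages, "phages")

  arrays <- detect_arrays(
    genomes, k_seed = config$k_seed, min_spacers = config$min_spacers,
    min_repeat_identity = config$min_repeat_identity,
    max_spacer_identity = config$max_spacer_identity
  )
  db <- withCallingHandlers(
    extract_spacers(arrays, only_high = TRUE),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  db <- left_join(db, rename(host_map, seq_id = "genome_id"), by = "seq_id")
  short <- nchar(db$spacer) < 20L
  if (any(short)) note(sprintf("%d spacer(s) shorter than 20 nt", sum(short)))

  cas_calls <- withCallingHandlers(
    classify_cas_table(cas_annotations, arrays),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  budget <- purrr::map2(genomes$seq_id, nchar(genomes$seq), function(id, len) {
    cas_iv <- cas_annotations[cas_annotations$seq_id == id, c("start", "end")]
    arr_iv <- arrays[arrays$seq_id == id, c("start", "end")]
    b <- crispr_budget(len, cas_iv, arr_iv)
    tibble(genome_id = id, genome_length = len, crispr_bp = b$total_bp,
           crispr_fraction = b$fraction)
  }) |> bind_rows()

  matched <- withCallingHandlers(
    link_hosts(db, phages, min_coverage = config$min_coverage,
               max_mismatch = config$max_mismatch),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  cot <- find_cotargeted(matched$links)
  profiles <- profile_code(phages, min_orf_len = config$density_min_orf_len,
                           size_floor = config$size_floor,
                           delta_threshold = config$delta_threshold)

  complete <- cas_calls |>
    filter(.data$subtype != "incomplete") |>
    distinct(.data$genome_id)
  prev <- host_map |>
    group_by(.data$host_group) |>
    summarise(
      n_genomes = dplyr::n(),
      n_with_system = sum(.data$genome_id %in% complete$genome_id),
      n_systems = sum(cas_calls$subtype != "incomplete" &
                        cas_calls$genome_id %in% .data$genome_id)
    ) |>
    mutate(
      prevalence_percent = purrr::map2_dbl(.data$n_with_system,
                                           .data$n_genomes, prevalence),
      systems_per_100_genomes = purrr::map2_dbl(.data$n_systems,
                                                .data$n_genomes, prevalence)
    ) |>
    arrange(.data$host_group)

  run <- structure(list(
    arrays = arrays, spacer_db = db, cas_calls = cas_calls, budget = budget,
    hits = matched$hits, links = matched$links, cotargeted = cot,
    profiles = profiles, prevalence = prev, config = config,
    warnings = collected
  ), class = "phage_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# Serialize every result table plus the run manifest. List-columns are
# flattened to comma-separated strings for the TSVs.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_arrays_gff3(run$arrays, p("arrays.gff3"))
  write_spacer_db(run$spacer_db, p("spacers.fasta"), p("spacers.tsv"))
  readr::write_tsv(run$cas_calls, p("cas_subtypes.tsv"))
  readr::write_tsv(run$budget, p("crispr_budget.tsv"))
  readr::write_tsv(run$hits, p("spacer_hits.tsv"))
  readr::write_tsv(
    mutate(run$links, host_groups = purrr::map_chr(
      .data$host_groups, paste, collapse = ",")),
    p("host_links.tsv")
  )
  readr::write_tsv(
    run$cotargeted |>
      mutate(dplyr::across(c("host_groups", "sga_groups", "non_sga_groups"),
                           ~ purrr::map_chr(.x, paste, collapse = ","))),
    p("cotargeted.tsv")
  )
  readr::write_tsv(as_tibble(run$profiles), p("code_profiles.tsv"))
  readr::write_tsv(run$prevalence, p("prevalence.tsv"))
  cfg <- unclass(run$config)
  cfg$out_dir <- NULL  # the output location must not perturb its own bytes
  manifest <- list(
    package = "phagecode",
    version = as.character(utils::packageVersion("phagecode")),
    seed = run$config$seed,
    config = cfg,
    counts = list(
      genomes = nrow(run$budget), phages = nrow(run$profiles),
      arrays = nrow(run$arrays), spacers = nrow(run$spacer_db),
      hits = nrow(run$hits), links = nrow(run$links),
      cotargeted = nrow(run$cotargeted)
    ),
    warnings = run$warnings
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.phage_run <- function(x, ...) {
  cat("<phage_run>\n")
  cat(sprintf("  genomes: %d  arrays: %d (high: %d)  spacers: %d\n",
              nrow(x$budget), nrow(x$arrays),
              sum(x$arrays$evidence == "high"), nrow(x$spacer_db)))
  cat(sprintf("  phages: %d  linked: %d  co-targeted: %d\n",
              nrow(x$profiles), nrow(x$links), nrow(x$cotargeted)))
  calls <- table(x$profiles$call)
  cat(sprintf("  code calls: %s\n",
              paste(sprintf("%s=%d", names(calls), calls), collapse = " ")))
  invisible(x)
}

#' Tidy a pipeline run
#'
#' `tidy()` returns the per-phage result table (one row per phage: code
#' profile, number of supporting spacer hits, host groups, co-targeting
#' flag); `glance()` returns a one-row run summary.
#'
#' @param x A `phage_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phage_run
#' @export
tidy.phage_run <- function(x, ...) {
  links <- x$links |>
    mutate(host_groups = purrr::map_chr(.data$host_groups, paste,
                                        collapse = ","))
  as_tibble(x$profiles) |>
    left_join(links, by = c(seq_id = "target_id")) |>
    mutate(
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      n_spacers = dplyr::coalesce(.data$n_spacers, 0L),
      host_groups = dplyr::coalesce(.data$host_groups, ""),
      cotargeted = .data$seq_id %in% x$cotargeted$target_id
    )
}

#' @rdname tidy.phage_run
#' @method glance phage_run
#' @export
glance.phage_run <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$budget),
    n_phages = nrow(x$profiles),
    n_arrays = nrow(x$arrays),
    n_high_evidence_arrays = sum(x$arrays$evidence == "high"),
    n_spacers = nrow(x$spacer_db),
    n_hits = nrow(x$hits),
    n_linked_phages = nrow(x$links),
    n_cotargeted = nrow(x$cotargeted),
    n_code25_calls = sum(x$profiles$call == "code25"),
    n_code11_compatible = sum(x$profiles$call == "code11_compatible"),
    seed = x$config$seed
  )
}
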