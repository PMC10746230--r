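#' Simulate a complete small study world
#'
#' Builds a seed-reproducible scenario exercising every pipeline stage:
#' six host genomes across five host groups (standard-coded
#' Saccharibacteria and Actinobacteria; alternatively coded Gracilibacteria
#' and Absconditabacteria) with planted CRISPR arrays and labeled cas
#' operons, and twelve candidate phages, half written in code 25
#' (TGA-glycine fraction 0.3) and half in code 11. Nine protospacers are
#' planted: exact and single-mismatch copies that must be recovered, two-
#' and three-mismatch copies that must not, one minus-strand copy, two
#' phages co-targeted by SGA and non-SGA spacers, and three decoy phages
#' with no planted target (one decoy below the 20 kb profiling floor).
#'
#' @param seed Integer seed; the whole world is a pure function of it.
#' @param host_length,phage_length Target genome lengths in bp (defaults
#'   30000 and 24000).
#' @return A list: `genomes`, `phages` (sequence tibbles),
#'   `cas_annotations`, `host_map`, and `truth` (host genome truths,
#'   planted protospacer table, per-phage expected code call, expected
#'   linked phages with host groups, expected co-targeted phage ids).
#' @export
simulate_world <- function(seed = 1L, host_length = 30000L,
                           phage_length = 24000L) {
  seed <- as.integer(seed)
  arr <- function(n_spacers = 5L) list(list(n_spacers = n_spacers))
  hosts <- list(
    list(id = "SACC1", group = "Saccharibacteria", code = 11L,
         arrays = arr(5L), cas = c("cas9", "csn2", "cas1", "cas2")),
    # SACC2's second "array" has a single spacer: two repeat copies fall
    # below the detector's minimum and it must stay undetected; its cas
    # complement is deliberately incomplete.
    list(id = "SACC2", group = "Saccharibacteria", code = 11L,
         arrays = c(arr(4L), arr(1L)), cas = c("cas1", "cas2")),
    list(id = "GRAC1", group = "Gracilibacteria", code = 25L,
         arrays = c(arr(5L), arr(4L)),
         cas = c("cpf1", "cas1", "cas4", "cas2")),
    list(id = "GRAC2", group = "Gracilibacteria", code = 25L,
         arrays = arr(6L), cas = c("cas10", "cas7", "cas5", "csm2")),
    list(id = "ABSC1", group = "Absconditabacteria", code = 25L,
         arrays = arr(5L), cas = c("cpf1", "cas1", "cas4", "cas2")),
    list(id = "ACTI1", group = "Actinobacteria", code = 11L,
         arrays = arr(5L), cas = c("cas9", "cas1", "cas2"))
  )
  sub <- withr::with_seed(seed, sample.int(2000000000L, length(hosts) + 1L))
  host_sims <- purrr::imap(hosts, function(h, i) {
    simulate_genome(genome_spec(
      h$id, length = host_length, code_id = h$code,
      array_specs = h$arrays, cas_labels = h$cas, seed = sub[i]
    ))
  })
  genomes <- bind_rows(purrr::map(host_sims, "seq"))
  host_truth <- purrr::map(host_sims, "truth")
  names(host_truth) <- genomes$seq_id
  host_map <- tibble(
    genome_id = purrr::map_chr(hosts, "id"),
    host_group = purrr::map_chr(hosts, "group")
  )
  cas_annotations <- bind_rows(purrr::map(host_truth, function(tr) {
    if (is.null(tr$cas)) return(NULL)
    mutate(tr$cas, genome_id = tr$genome_id, seq_id = tr$genome_id,
           .before = 1L)
  }))

  # planted spacer lookup: array a, spacer s of a host genome
  sp <- function(id, a, s) host_truth[[id]]$arrays$spacers[[a]][s]

  phage_codes <- c(
    PHG01 = 11L, PHG02 = 11L, PHG03 = 25L, PHG04 = 25L, PHG05 = 11L,
    PHG06 = 25L, PHG07 = 25L, PHG08 = 11L, PHG09 = 25L, PHG10 = 11L,
    PHG11 = 25L, PHG12 = 11L
  )
  pseed <- withr::with_seed(sub[length(sub)],
                            sample.int(2000000000L, length(phage_codes)))
  specs <- purrr::imap(phage_codes, function(code, id) {
    genome_spec(id, length = if (id == "PHG12") 12000L else phage_length,
                code_id = code, seed = pseed[match(id, names(phage_codes))])
  })
  schedule <- tibble(
    phage_id = c("PHG01", "PHG02", "PHG02", "PHG03", "PHG04", "PHG04",
                 "PHG05", "PHG06", "PHG07", "PHG08", "PHG09"),
    source = c("SACC1", "GRAC1", "ACTI1", "GRAC2", "ABSC1", "ACTI1",
               "SACC1", "SACC2", "ABSC1", "ACTI1", "GRAC1"),
    spacer = c(sp("SACC1", 1, 1), sp("GRAC1", 1, 2), sp("ACTI1", 1, 1),
               sp("GRAC2", 1, 3), sp("ABSC1", 1, 2), sp("ACTI1", 1, 3),
               sp("SACC1", 1, 4), sp("SACC2", 1, 1), sp("ABSC1", 1, 5),
               sp("ACTI1", 1, 4), sp("GRAC1", 2, 1)),
    n_mismatch = c(0L, 0L, 0L, 1L, 0L, 1L, 2L, 0L, 3L, 0L, 0L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-")
  )
  phage_set <- simulate_phage_set(unname(specs), schedule)

  linkable <- schedule$n_mismatch <= 1L
  expected_links <- schedule[linkable, c("phage_id", "source")] |>
    left_join(rename(host_map, source = "genome_id"), by = "source") |>
    distinct(.data$phage_id, .data$host_group) |>
    arrange(.data$phage_id, .data$host_group)
  expected_calls <- tibble(
    phage_id = names(phage_codes),
    code_id = unname(phage_codes),
    expected_call = dplyr::if_else(
      names(phage_codes) == "PHG12", "not_evaluated",
      dplyr::if_else(phage_codes == 25L, "code25", "code11_compatible")
    )
  )
  sga <- sga_groups()
  exp_cot <- expected_links |>
    group_by(.data$phage_id) |>
    summarise(has_sga = any(.data$host_group %in% sga),
              has_non = any(!.data$host_group %in% sga)) |>
    filter(.data$has_sga, .data$has_non)

  list(
    genomes = genomes, phages = phage_set$seqs,
    cas_annotations = cas_annotations, host_map = host_map,
    truth = list(
      hosts = host_truth, phage_genomes = phage_set$truth,
      planted = phage_set$planted, schedule = schedule,
      expected_links = expected_links, expected_calls = expected_calls,
      expected_cotargeted = exp_cot$phage_id
    )
  )
}
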