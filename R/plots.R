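#' Plot a dual-code density profile
#'
#' Histogram of the change in coding density between code 25 and code 11
#' (percentage points) for evaluated sequences, with the calling threshold
#' marked. Sequences near zero are compatible with the standard code;
#' sequences far right are clearly alternatively coded.
#'
#' @param object A `code_profile` tibble from [profile_code()].
#' @param binwidth Histogram bin width in percentage points (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot code_profile
#' @export
autoplot.code_profile <- function(object, binwidth = 2, ...) {
  thr <- attr(object, "delta_threshold") %||% 10
  dat <- filter(as_tibble(object), .data$call != "not_evaluated")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta, fill = .data$call)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(code25 = "#b2182b",
                                          code11_compatible = "#2166ac")) +
    ggplot2::labs(
      x = "coding density change, code 25 - code 11 (percentage points)",
      y = "sequences", fill = "code call"
    ) +
    ggplot2::theme_minimal()
}

#' Plot CRISPR array architectures
#'
#' Repeat/spacer decomposition of each detected array: repeats as dark
#' boxes, spacers as light boxes, one panel per array.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @return A ggplot object.
#' @export
plot_arrays <- function(arrays) {
  if (nrow(arrays) == 0L) abort("no arrays to plot")
  feat <- arrays |>
    mutate(panel = sprintf("%s array %d (%s)", .data$seq_id,
                           .data$array_index, .data$evidence)) |>
    select("panel", "repeats", "spacers") |>
    tidyr::pivot_longer(c("repeats", "spacers"), names_to = "part",
                        values_to = "tbl") |>
    tidyr::unnest("tbl") |>
    mutate(end = .data$start + nchar(.data$seq))
  ggplot2::ggplot(feat) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
      fill = .data$part
    ), colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(repeats = "grey25",
                                          spacers = "#fddbc7")) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dual-code genome map of one sequence
#'
#' ORFs predicted under codes 11 and 25 drawn as two tracks, with in-frame
#' TGA codons marked as ticks: alternatively coded genomes show long
#' TGA-dense ORFs in code 25 that shatter in code 11.
#'
#' @param seqs Sequence tibble or single DNA string.
#' @param seq_id Which sequence to draw (default: the first).
#' @param min_orf_len Minimum ORF length passed to [find_orfs()].
#' @return A ggplot object.
#' @export
plot_dual_code_map <- function(seqs, seq_id = NULL, min_orf_len = 90L) {
  seqs <- as_seq_tbl(seqs)
  seq_id <- seq_id %||% seqs$seq_id[1L]
  seqs <- seqs[seqs$seq_id == seq_id, ]
  orfs <- bind_rows(
    mutate(find_orfs(seqs, 11L, min_orf_len), code = "code 11"),
    mutate(find_orfs(seqs, 25L, min_orf_len), code = "code 25")
  )
  tga <- orfs |>
    select("code", "inframe_tga") |>
    tidyr::unnest("inframe_tga")
  p <- ggplot2::ggplot(orfs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = ifelse(.data$strand == "+", 0.55, 0.05),
      ymax = ifelse(.data$strand == "+", 0.95, 0.45)
    ), fill = "#92c5de", colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~code, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = c(0.25, 0.75),
                                labels = c("-", "+")) +
    ggplot2::labs(title = seq_id, x = "position (bp)", y = "strand") +
    ggplot2::theme_minimal()
  if (nrow(tga) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = tga,
      ggplot2::aes(x = .data$inframe_tga, xend = .data$inframe_tga,
                   y = 0.05, yend = 0.95),
      colour = "black", linewidth = 0.2
    )
  }
  p
}
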