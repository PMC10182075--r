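#' Define associated genomic regions from one GWAS
#'
#' Variants with `p < p_seed` are chained per chromosome; a gap strictly
#' greater than `gap_kb` kilobases between consecutive seed variants splits
#' the chain into separate regions. Region bounds are the min/max seed
#' positions (1-based inclusive, no padding). A region is flagged
#' significant when at least one of its variants reaches `p < p_sig`.
#'
#' @param gwas Summary-statistics tibble with columns SNP, CHR, BP, P.
#' @param p_seed Seed threshold (default 1e-6).
#' @param gap_kb Split distance in kb (default 250; split iff gap > 250 kb).
#' @param p_sig Significance threshold (default 5e-8).
#' @param trait Optional trait label recorded in the output.
#' @return Tibble with columns chr, start, end, n_seed, lead_rsid, lead_p,
#'   significant, trait.
#' @export
define_regions <- function(gwas, p_seed = 1e-6, gap_kb = 250, p_sig = 5e-8,
                           trait = NA_character_) {
  if (nrow(gwas) == 0) {
    return(tibble::tibble(chr = integer(), start = integer(), end = integer(),
                          n_seed = integer(), lead_rsid = character(),
                          lead_p = numeric(), significant = logical(),
                          trait = character()))
  }
  gwas <- dplyr::arrange(gwas, .data$CHR, .data$BP)
  seeds <- dplyr::filter(gwas, .data$P < p_seed)
  if (nrow(seeds) == 0) return(define_regions(gwas[0, ], p_seed, gap_kb, p_sig, trait))

  out <- seeds |>
    dplyr::group_by(.data$CHR) |>
    dplyr::mutate(
      gap = .data$BP - dplyr::lag(.data$BP, default = dplyr::first(.data$BP)),
      region_id = cumsum(.data$gap > gap_kb * 1000)
    ) |>
    dplyr::group_by(.data$CHR, .data$region_id) |>
    dplyr::summarise(start = min(.data$BP), end = max(.data$BP),
                     n_seed = dplyr::n(), .groups = "drop")

  # lead = minimum-p variant among all table variants inside the bounds
  lead <- purrr::pmap_dfr(out, function(CHR, region_id, start, end, n_seed) {
    inside <- dplyr::filter(gwas, .data$CHR == !!CHR,
                            .data$BP >= start, .data$BP <= end)
    i <- which.min(inside$P)
    tibble::tibble(lead_rsid = inside$SNP[i], lead_p = inside$P[i],
                   significant = any(inside$P < p_sig))
  })
  dplyr::bind_cols(
    dplyr::transmute(out, chr = .data$CHR, start = .data$start,
                     end = .data$end, n_seed = .data$n_seed),
    lead
  ) |>
    dplyr::mutate(trait = trait)
}

#' Merge overlapping regions across GWAS
#'
#' Overlap is transitively closed: any chain of pairwise-overlapping regions
#' collapses into one region whose bounds are the min and max positions
#' across the chain, so an asymmetric overlap (one region spanning several
#' of another GWAS's regions) counts once. The trait set of a merged region
#' is the union of contributors.
#'
#' @param per_gwas A list of region tibbles from [define_regions()] (or one
#'   already-bound tibble). Coordinates are 1-based inclusive; regions
#'   touching at a shared endpoint overlap.
#' @return Merged tibble: chr, start, end, traits (comma-joined), n_merged,
#'   significant.
#' @export
merge_regions <- function(per_gwas) {
  regions <- if (is.data.frame(per_gwas)) per_gwas else dplyr::bind_rows(per_gwas)
  if (nrow(regions) == 0) {
    return(tibble::tibble(chr = integer(), start = integer(), end = integer(),
                          traits = character(), n_merged = integer(),
                          significant = logical()))
  }
  regions |>
    dplyr::arrange(.data$chr, .data$start, .data$end) |>
    dplyr::group_by(.data$chr) |>
    dplyr::mutate(
      new_cluster = .data$start > cummax(dplyr::lag(.data$end,
                                                    default = .data$end[1] - 1L) + 0),
      cluster = cumsum(.data$new_cluster)
    ) |>
    dplyr::group_by(.data$chr, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      traits = paste(sort(unique(stats::na.omit(.data$trait))), collapse = ","),
      n_merged = dplyr::n(),
      significant = any(.data$significant),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster")
}

#' Remove regions overlapping the HLA locus
#'
#' Drops any region with one or more base pairs of overlap with the extended
#' HLA window (chromosome 6, 25,000,000-35,000,000 by default), which is
#' excluded from signal decomposition because of its extreme LD and allelic
#' heterogeneity.
#'
#' @param regions A region tibble (columns chr, start, end).
#' @param hla_chr,hla_start,hla_end The excluded window.
#' @return The filtered tibble.
#' @export
exclude_hla <- function(regions, hla_chr = 6, hla_start = 25e6, hla_end = 35e6) {
  dplyr::filter(
    regions,
    !(.data$chr == hla_chr & .data$start <= hla_end & .data$end >= hla_start)
  )
}

#' Write regions as a BED-like tab-separated file
#'
#' Coordinates are written 1-based inclusive, declared in a header comment.
#'
#' @param regions A region tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(regions, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
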