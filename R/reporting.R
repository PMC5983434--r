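#' Filtration summary table
#'
#' Per-breed totals and survivor counts of the within-breed filtration, with
#' the percentage retained, rounded half-up to three decimals — the layout
#' of the published per-breed SNP filtration table.
#'
#' @param counts A tibble with columns `breed`, `total_snps`,
#'   `after_filtration`.
#' @return A tibble `breed`, `total_snps`, `after_filtration`, `percent`.
#' @export
filtration_summary <- function(counts) {
  if (any(counts$total_snps <= 0)) {
    abort("total_snps must be positive for every breed")
  }
  if (any(counts$after_filtration < 0 | counts$after_filtration > counts$total_snps)) {
    abort("after_filtration must lie in [0, total_snps]")
  }
  tibble(
    breed = counts$breed,
    total_snps = counts$total_snps,
    after_filtration = counts$after_filtration,
    percent = round_half_up(100 * counts$after_filtration / counts$total_snps, 3)
  )
}

#' Cohort composition percentages
#'
#' Share of samples contributed by each breed, rounded half-up to two
#' decimals.
#'
#' @param panel A breed panel tibble (`breed`, `sample`), see [read_panel()].
#' @return A tibble `breed`, `n_samples`, `percent`, in the panel's breed
#'   order.
#' @export
cohort_composition <- function(panel) {
  if (nrow(panel) == 0L) {
    abort("panel is empty")
  }
  breeds <- unique(panel$breed)
  n <- vapply(breeds, function(b) sum(panel$breed == b), integer(1))
  tibble(
    breed = breeds,
    n_samples = unname(n),
    percent = unname(round_half_up(100 * n / sum(n), 2))
  )
}
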