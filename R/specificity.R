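#' Exclusive Venn partition of per-breed variant sets
#'
#' Assigns every variant key in the union of the per-breed fixed-SNP sets to
#' exactly one cell, labelled by the subset of breeds carrying it. All
#' `2^B - 1` non-empty subsets are reported, including empty cells, so the
#' table is the complete Venn partition: cells are disjoint and their counts
#' sum to the union size.
#'
#' @param keys A tibble with columns `breed` and `key` (one row per breed
#'   carrying the key), e.g. per-breed [fixed_alt_sites()] outputs stacked
#'   with `dplyr::bind_rows(.id = "breed")`.
#' @param breeds Breed order for the labels; defaults to order of first
#'   appearance in `keys`.
#' @return A tibble with columns `breed_set` (comma-joined breed names),
#'   `n_breeds` and `count`, of class `venn_table`.
#' @export
venn_partition <- function(keys, breeds = unique(keys$breed)) {
  if (length(breeds) < 2L) {
    abort("venn_partition() needs at least 2 breeds")
  }
  stray <- setdiff(unique(keys$breed), breeds)
  if (length(stray)) {
    abort(paste0("breed '", stray[1], "' in keys but not in `breeds`"))
  }
  keys <- distinct(keys, .data$breed, .data$key)
  membership <- keys %>%
    mutate(breed = factor(.data$breed, levels = breeds)) %>%
    arrange(.data$breed) %>%
    group_by(.data$key) %>%
    summarise(
      breed_set = paste(.data$breed, collapse = ","),
      n_breeds = dplyr::n(),
      .groups = "drop"
    )
  all_cells <- subset_labels(breeds)
  counts <- membership %>% count(.data$breed_set, name = "count")
  out <- all_cells %>%
    left_join(counts, by = "breed_set") %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  class(out) <- c("venn_table", class(out))
  out
}

# All non-empty subsets of `breeds`, labelled in breed order,
# ordered by subset size then lexicographic position.
subset_labels <- function(breeds) {
  b <- length(breeds)
  combos <- unlist(
    lapply(seq_len(b), function(k) {
      utils::combn(breeds, k, FUN = function(x) paste(x, collapse = ","), simplify = FALSE)
    }),
    use.names = FALSE
  )
  sizes <- unlist(lapply(seq_len(b), function(k) rep(k, choose(b, k))))
  tibble(breed_set = combos, n_breeds = sizes)
}

#' Breed-specific variant keys
#'
#' A variant is breed-specific when it is present in exactly one breed's
#' filtered set and absent from every other breed's set — the singleton
#' cells of the Venn partition.
#'
#' @inheritParams venn_partition
#' @return A tibble with columns `breed` and `key`, one row per
#'   breed-specific variant, sorted by breed then key.
#' @export
breed_specific_sets <- function(keys, breeds = unique(keys$breed)) {
  keys <- distinct(keys, .data$breed, .data$key)
  out <- keys %>%
    group_by(.data$key) %>%
    filter(dplyr::n() == 1L) %>%
    ungroup() %>%
    mutate(breed = factor(.data$breed, levels = breeds)) %>%
    arrange(.data$breed, .data$key) %>%
    mutate(breed = as.character(.data$breed)) %>%
    select("breed", "key")
  out
}

#' @export
print.venn_table <- function(x, ...) {
  cat("<venn_table> ", max(x$n_breeds), " breeds, ", nrow(x), " cells, union size ",
    sum(x$count), "\n",
    sep = ""
  )
  NextMethod()
}
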