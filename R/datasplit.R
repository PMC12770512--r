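#' Split configuration
#'
#' @param per_class_cap Images retained per class by [seal_classes()]
#'   (default 1500).
#' @param train_fraction Fraction of each sealed class assigned to training
#'   by [holdout_split()] (default 0.75).
#' @param k Number of cross-validation folds (default 5).
#' @param seed RNG seed for all seeded subsampling/shuffling (default 1).
#' @return A list of class `split_config`.
#' @export
split_config <- function(per_class_cap = 1500, train_fraction = 0.75, k = 5,
                         seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_config("`train_fraction` must be in (0, 1)")
  }
  if (k < 2) abort_config("`k` must be >= 2")
  if (per_class_cap < 1) abort_config("`per_class_cap` must be >= 1")
  structure(list(per_class_cap = as.integer(per_class_cap),
                 train_fraction = train_fraction,
                 k = as.integer(k),
                 seed = as.integer(seed)),
            class = "split_config")
}

assert_manifest <- function(manifest) {
  if (!is.data.frame(manifest) || !all(c("path", "label") %in% names(manifest))) {
    abort_data("manifest must be a data frame with `path` and `label` columns")
  }
  if (anyDuplicated(manifest$path)) abort_data("manifest paths must be unique")
  manifest <- tibble::as_tibble(manifest)
  if (!"split" %in% names(manifest)) manifest$split <- NA_character_
  if (!"fold" %in% names(manifest)) manifest$fold <- NA_integer_
  manifest
}

# canonical ordering so that seeded sampling never depends on input row order
canonical_order <- function(manifest) {
  dplyr::arrange(manifest, .data$label, .data$path)
}

#' Seal classes to a common size
#'
#' Uniform seeded subsampling of exactly `per_class_cap` rows per class, so
#' the class distribution is perfectly balanced. The selected set is
#' independent of the input row order.
#'
#' @param manifest Manifest tibble (`path`, `label`, ...).
#' @param config A [split_config()].
#' @return Sealed manifest tibble.
#' @export
seal_classes <- function(manifest, config = split_config()) {
  manifest <- canonical_order(assert_manifest(manifest))
  sizes <- dplyr::count(manifest, .data$label)
  short <- sizes$label[sizes$n < config$per_class_cap]
  if (length(short) > 0L) {
    abort_data(sprintf("class(es) below the cap of %d: %s",
                       config$per_class_cap, paste(short, collapse = ", ")))
  }
  withr::with_seed(config$seed, {
    manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        df[sort(sample.int(nrow(df), config$per_class_cap)), , drop = FALSE]
      }) |>
      dplyr::ungroup()
  })
}

#' Stratified hold-out split
#'
#' Per class, exactly `round(n * train_fraction)` rows (rounding half away
#' from zero) are marked `train` and the remainder `test`, after a seeded
#' shuffle; independent of the input row order.
#'
#' @param manifest Manifest tibble (typically sealed).
#' @param config A [split_config()].
#' @return Manifest tibble with the `split` column filled.
#' @export
holdout_split <- function(manifest, config = split_config()) {
  manifest <- canonical_order(assert_manifest(manifest))
  withr::with_seed(config$seed, {
    out <- manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        n_train <- round_half_away(n * config$train_fraction)
        if (n_train < 1 || n_train >= n) {
          abort_config(sprintf(
            "train_fraction %.3f leaves an empty split for a class of %d",
            config$train_fraction, n))
        }
        df$split <- "test"
        df$split[sample.int(n, n_train)] <- "train"
        df
      }) |>
      dplyr::ungroup()
    out
  })
}

#' Stratified k-fold assignment
#'
#' Per class, rows are seeded-shuffled and dealt round-robin into `k` folds,
#' so per-class fold sizes differ by at most one and every fold preserves
#' the global class proportions to within one item.
#'
#' @param manifest Manifest tibble.
#' @param config A [split_config()].
#' @return Manifest tibble with the `fold` column filled (1..k).
#' @export
stratified_kfold <- function(manifest, config = split_config()) {
  manifest <- canonical_order(assert_manifest(manifest))
  sizes <- dplyr::count(manifest, .data$label)
  if (any(sizes$n < config$k)) {
    abort_config(sprintf("k = %d exceeds the smallest class size (%d)",
                         config$k, min(sizes$n)))
  }
  withr::with_seed(config$seed, {
    manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        ord <- sample.int(nrow(df))
        df$fold[ord] <- ((seq_len(nrow(df)) - 1L) %% config$k) + 1L
        df
      }) |>
      dplyr::ungroup()
  })
}

#' Read / write a manifest CSV
#'
#' @param path CSV path with columns `path`, `label`, `split`, `fold`.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("manifest not found: %s", path))
  assert_manifest(readr::read_csv(path, show_col_types = FALSE,
                                  col_types = readr::cols(
                                    path = readr::col_character(),
                                    label = readr::col_character(),
                                    split = readr::col_character(),
                                    fold = readr::col_integer())))
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(assert_manifest(manifest), path)
  invisible(path)
}
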