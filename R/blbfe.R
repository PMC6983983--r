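#' Block location-based feature extraction (BLBFE)
#'
#' Converts each sequence into an observation: an integer vector whose i-th
#' entry is the 1-based first-occurrence location of the i-th block's motif
#' in the sequence, or 0 when the motif is absent. Column order follows the
#' row order of `blocks` and is recorded in column names as
#' `<family>.<motif>` (a motif shared by two families occupies one column
#' per owning family).
#'
#' @param records Tibble with columns `id`, `family`, `residues`; `family`
#'   may be empty for unlabeled queries.
#' @param blocks Block tibble (`family`, `motif`, ...) with a fixed row
#'   order, e.g. from [find_blocks()] or [riboswitch_blocks()].
#' @return Tibble with columns `id`, `family`, then one integer column per
#'   block.
#' @examples
#' fa <- system.file("extdata", "worked_example.fasta", package = "riboblock")
#' recs <- read_rna_fasta(fa)
#' extract_features(recs, riboswitch_blocks())
#' @export
extract_features <- function(records, blocks) {
  stopifnot(nrow(blocks) >= 1,
            all(c("id", "family", "residues") %in% names(records)))
  cols <- purrr::map(blocks$motif, ~ locate_block(records$residues, .x))
  names(cols) <- make.unique(paste(blocks$family, blocks$motif, sep = "."))
  dplyr::bind_cols(
    tibble(id = records$id, family = records$family),
    as_tibble(cols)
  )
}

#' Build the observations-by-blocks feature matrix
#'
#' One row per member across all families, in dataset-then-file order; one
#' column per block in block-set order. With the seven riboswitch families
#' (808 members) and their 22 blocks this is the 808 x 22 observation
#' matrix used for classification.
#'
#' @param records Tibble of sequence records covering one or more families.
#' @param blocks Combined block tibble over all families.
#' @return Feature tibble as in [extract_features()].
#' @export
build_feature_matrix <- function(records, blocks) {
  if (anyDuplicated(records$id)) {
    stop("duplicate observation id '",
         records$id[duplicated(records$id)][1], "'", call. = FALSE)
  }
  extract_features(records, blocks)
}

#' Extract the numeric matrix from a feature tibble
#'
#' @param features Tibble from [extract_features()].
#' @return Integer matrix (rows named by `id`) without the `id`/`family`
#'   columns.
#' @export
feature_values <- function(features) {
  m <- as.matrix(features[setdiff(names(features), c("id", "family"))])
  rownames(m) <- features$id
  storage.mode(m) <- "integer"
  m
}

#' Read/write feature matrices as TSV
#'
#' The on-disk dialect has one row per observation: first column `id`,
#' second column `family`, remaining columns one per block in block-set
#' order.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    family = readr::col_character(),
    .default = readr::col_integer()
  ))
  if (!all(c("id", "family") %in% names(out))) {
    stop("feature file must start with 'id' and 'family' columns",
         call. = FALSE)
  }
  out
}
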