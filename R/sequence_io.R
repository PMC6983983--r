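#' Normalize raw sequence text to the RNA alphabet
#'
#' Uppercases, maps T to U (Rfam seed files may carry the DNA alphabet), and
#' strips alignment gap characters `-` and `.`. Any other character is an
#' error. Normalization is idempotent.
#'
#' @param x Character vector of raw sequences.
#' @param ids Optional identifiers used in error messages, recycled to
#'   `length(x)`.
#' @return Character vector over `{A, C, G, U}`.
#' @examples
#' normalize_rna("acg-t.u")
#' @export
normalize_rna <- function(x, ids = NULL) {
  ids <- ids %||% as.character(seq_along(x))
  out <- toupper(x)
  n_gap <- sum(stringr::str_count(out, "[-.]"))
  if (n_gap > 0) {
    message("normalize_rna: stripped ", n_gap, " gap character(s)")
  }
  out <- stringr::str_remove_all(out, "[-.]")
  out <- stringr::str_replace_all(out, "T", "U")
  bad <- stringr::str_locate(out, "[^ACGU]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    ch <- substr(out[i], bad[i], bad[i])
    stop("invalid character '", ch, "' in sequence '", ids[i], "'",
         call. = FALSE)
  }
  if (any(!nzchar(out))) {
    i <- which(!nzchar(out))[1]
    stop("sequence '", ids[i], "' is empty after normalization",
         call. = FALSE)
  }
  out
}

#' Read an un-gapped RNA family from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns one
#' row per sequence. Residues are normalized with [normalize_rna()]:
#' uppercased, T mapped to U, gap characters stripped. Record order follows
#' file order so downstream fold assignment is reproducible.
#'
#' @param path Path to a FASTA file.
#' @param family Family label attached to every record (default: empty
#'   string, for unlabeled query sets).
#' @return A tibble with columns `id`, `family`, `residues`.
#' @examples
#' fa <- system.file("extdata", "worked_example.fasta", package = "riboblock")
#' read_rna_fasta(fa, family = "example")
#' @export
read_rna_fasta <- function(path, family = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file has no records: ", path, call. = FALSE)
  ids <- stringr::str_extract(names(set), "^\\S+")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  }
  tibble(
    id = ids,
    family = family,
    residues = normalize_rna(as.character(set), ids = ids)
  )
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `residues` (as produced by
#'   [read_rna_fasta()] or [generate_family()]).
#' @param path Output file path.
#' @param width Line-wrap width in nucleotides.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Summarise sequence families
#'
#' Per-family member counts and empirical length moments, recomputed from the
#' records (never stored stale).
#'
#' @param records Tibble with columns `id`, `family`, `residues`.
#' @return Tibble with columns `family`, `n`, `mean_length`,
#'   `length_variance`.
#' @export
family_summary <- function(records) {
  records |>
    mutate(.len = nchar(.data$residues)) |>
    group_by(.data$family) |>
    summarise(
      n = n(),
      mean_length = mean(.data$.len),
      length_variance = stats::var(.data$.len),
      .groups = "drop"
    )
}

#' Read a block set from TSV
#'
#' The block-set dialect is a tab-separated file with header
#' `family<TAB>motif<TAB>location<TAB>prevalence`. Motifs are validated over
#' `{A, C, G, U}`; `prevalence` may be `NA` for reference sets whose
#' prevalences were not published.
#'
#' @param path Path to a block-set TSV.
#' @return Tibble with columns `family`, `motif`, `canonical_location`,
#'   `prevalence`, in file order.
#' @seealso [write_blockset()], [riboswitch_blocks()]
#' @export
read_blockset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    family = readr::col_character(),
    motif = readr::col_character(),
    location = readr::col_integer(),
    prevalence = readr::col_double()
  ))
  req <- c("family", "motif", "location", "prevalence")
  if (!all(req %in% names(raw))) {
    stop("block-set file must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(raw))) {
    m <- raw$motif[i]
    if (is.na(m) || !grepl("^[ACGU]+$", m)) {
      stop("line ", i + 1L, ": invalid motif '", m, "' (alphabet is ACGU)",
           call. = FALSE)
    }
    if (is.na(raw$location[i]) || raw$location[i] < 1) {
      stop("line ", i + 1L, ": location must be a positive integer",
           call. = FALSE)
    }
  }
  tibble(
    family = raw$family,
    motif = raw$motif,
    canonical_location = as.integer(raw$location),
    prevalence = raw$prevalence
  )
}

#' Write a block set to TSV
#'
#' Round-trips losslessly through [read_blockset()].
#'
#' @param blocks Tibble with columns `family`, `motif`, `canonical_location`,
#'   `prevalence` (as produced by [find_blocks()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blockset <- function(blocks, path) {
  if (nrow(blocks) == 0) stop("block set is empty", call. = FALSE)
  out <- tibble(
    family = blocks$family,
    motif = blocks$motif,
    location = as.integer(blocks$canonical_location),
    prevalence = blocks$prevalence
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Reference riboswitch block set
#'
#' The 22 family-specific sequential blocks reported for the seven riboswitch
#' families lysine, cobalamin, glycine, SAM-alpha, SAM-IV, cyclic-di-GMP-I
#' and SAH, with their approximate canonical locations. Prevalences were not
#' published and are `NA`.
#'
#' @return Tibble with 22 rows: `family`, `motif`, `canonical_location`,
#'   `prevalence`.
#' @export
riboswitch_blocks <- function() {
  read_blockset(system.file("extdata", "riboswitch_blocks.tsv",
                            package = "riboblock"))
}
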