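#' Locate the first occurrence of a motif in sequences
#'
#' The start point of a block on a sequence is its location: the 1-based
#' index of the motif's first occurrence, or 0 when the motif is absent.
#'
#' @param residues Character vector of RNA sequences over `{A, C, G, U}`.
#' @param motif A single non-empty RNA motif.
#' @return Integer vector of the same length as `residues`.
#' @examples
#' locate_block(c("ACGUACGU", "AAAA"), "CGU")
#' @export
locate_block <- function(residues, motif) {
  if (length(motif) != 1 || is.na(motif) || !nzchar(motif)) {
    stop("motif must be a single non-empty string", call. = FALSE)
  }
  if (!grepl("^[ACGU]+$", motif)) {
    stop("motif '", motif, "' contains characters outside ACGU",
         call. = FALSE)
  }
  pos <- regexpr(motif, residues, fixed = TRUE)
  as.integer(ifelse(pos < 0, 0L, pos))
}

#' Enumerate candidate motifs of a family
#'
#' The first stage of sequential block finding: every distinct substring with
#' length in `[min_len, max_len]` occurring in at least one member is
#' enumerated, together with its 1-based first-occurrence location in each
#' member that contains it. Members lacking a motif are implicit (location
#' 0); the member universe is carried in the `n_members` attribute so that
#' prevalence denominators include them.
#'
#' @param records Tibble with columns `id`, `residues` (one family).
#' @param min_len,max_len Motif length bounds in nucleotides.
#' @return Tibble with columns `motif`, `id`, `location` (first occurrence,
#'   always > 0; absence is implicit), with attributes `n_members` and `ids`.
#' @export
candidate_motifs <- function(records, min_len = 3, max_len = 8) {
  stopifnot(min_len >= 1, min_len <= max_len, nrow(records) >= 1)
  per_record <- purrr::map2(records$residues, records$id, function(seq, id) {
    L <- nchar(seq)
    lens <- min_len:max_len
    lens <- lens[lens <= L]
    if (length(lens) == 0) return(NULL)
    pieces <- lapply(lens, function(k) {
      starts <- seq_len(L - k + 1L)
      data.frame(motif = substring(seq, starts, starts + k - 1L),
                 location = starts)
    })
    df <- do.call(rbind, pieces)
    # first occurrence within this member = min start over repeats
    firsts <- tapply(df$location, df$motif, min)
    data.frame(motif = names(firsts), id = id,
               location = as.integer(firsts), row.names = NULL)
  })
  out <- as_tibble(do.call(rbind, per_record))
  attr(out, "n_members") <- nrow(records)
  attr(out, "ids") <- records$id
  out
}

#' Filter candidate motifs by positional prevalence
#'
#' A motif survives when the fraction of family members whose first
#' occurrence is non-zero and lies within `location_window` nucleotides of
#' the modal first-occurrence location reaches `prevalence_threshold`. The
#' canonical location is the mode of the first-occurrence locations, ties
#' broken toward the smallest location.
#'
#' @param candidates Output of [candidate_motifs()].
#' @param prevalence_threshold Minimum surviving fraction, in `(0, 1]`.
#' @param location_window Allowed deviation `w` from the modal start, in
#'   nucleotides.
#' @param family Family label attached to surviving blocks.
#' @param n_members Family size used as the prevalence denominator; defaults
#'   to the `n_members` attribute of `candidates`.
#' @return Block tibble: `family`, `motif`, `canonical_location`,
#'   `prevalence`.
#' @export
filter_blocks <- function(candidates, prevalence_threshold = 0.7,
                          location_window = 5, family = "",
                          n_members = NULL) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold <= 1,
            location_window >= 0)
  n_members <- n_members %||% attr(candidates, "n_members") %||%
    n_distinct(candidates$id)
  # modal first-occurrence location per motif, ties toward the smallest
  modes <- candidates |>
    count(.data$motif, .data$location) |>
    group_by(.data$motif) |>
    arrange(desc(.data$n), .data$location, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("motif", canonical_location = "location")
  candidates |>
    left_join(modes, by = "motif") |>
    group_by(.data$motif, .data$canonical_location) |>
    summarise(
      prevalence = sum(abs(.data$location - .data$canonical_location) <=
                         location_window) / n_members,
      .groups = "drop"
    ) |>
    filter(.data$prevalence >= prevalence_threshold) |>
    mutate(family = family, .before = 1) |>
    arrange(.data$canonical_location, .data$motif)
}

#' Eliminate redundant blocks
#'
#' A motif that is a substring of a longer surviving motif, placed so that
#' the two occurrences overlap (canonical locations within the longer
#' motif's length), carries no extra information and is removed; longer
#' motifs are preferred. Blocks are compared within a family only.
#'
#' @param blocks Block tibble from [filter_blocks()].
#' @return Block tibble sorted by `canonical_location` then `motif`.
#' @export
eliminate_redundant <- function(blocks) {
  if (nrow(blocks) == 0) return(blocks)
  per_family <- split(blocks, blocks$family)
  kept <- lapply(per_family, function(b) {
    n <- nrow(b)
    drop <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || drop[j]) next
        shorter <- nchar(b$motif[i]) < nchar(b$motif[j])
        if (shorter &&
            grepl(b$motif[i], b$motif[j], fixed = TRUE) &&
            abs(b$canonical_location[i] - b$canonical_location[j]) <=
              nchar(b$motif[j])) {
          drop[i] <- TRUE
          break
        }
      }
    }
    b[!drop, , drop = FALSE]
  })
  bind_rows(kept) |>
    arrange(.data$family, .data$canonical_location, .data$motif)
}

#' Find family-specific sequential blocks (SBF)
#'
#' The full sequential block finding pipeline: enumerate all candidate motifs
#' ([candidate_motifs()]), keep those present in a high fraction of members
#' at nearly the same location ([filter_blocks()]), and remove redundant
#' substring blocks ([eliminate_redundant()]). Deterministic for fixed input
#' and settings. When `records` contains several families, blocks are found
#' independently per family.
#'
#' @param records Tibble with columns `id`, `family`, `residues`.
#' @param min_len,max_len Motif length bounds (nucleotides).
#' @param prevalence_threshold Minimum fraction of members that must carry
#'   the motif near its modal location.
#' @param location_window Allowed deviation from the modal start
#'   (nucleotides).
#' @return Block tibble: `family`, `motif`, `canonical_location`,
#'   `prevalence`. Settings are recorded in the `sbf_config` attribute.
#' @examples
#' spec <- family_spec("demo", n_members = 20, mean_length = 60,
#'                     length_sd = 2,
#'                     motifs = data.frame(motif = "GAGGUGGA", location = 15,
#'                                         prevalence = 1, jitter = 0))
#' recs <- generate_family(spec, seed = 1)
#' find_blocks(recs)
#' @export
find_blocks <- function(records, min_len = 3, max_len = 8,
                        prevalence_threshold = 0.7, location_window = 5) {
  stopifnot(all(c("id", "family", "residues") %in% names(records)))
  fams <- split(records, records$family)
  res <- lapply(names(fams), function(fam) {
    recs <- fams[[fam]]
    if (nrow(recs) < 2) {
      stop("family '", fam, "' has fewer than 2 members; ",
           "prevalence is undefined", call. = FALSE)
    }
    cand <- candidate_motifs(recs, min_len = min_len, max_len = max_len)
    surv <- filter_blocks(cand, prevalence_threshold = prevalence_threshold,
                          location_window = location_window, family = fam)
    eliminate_redundant(surv)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    warning("no blocks passed filtering; returning an empty block set",
            call. = FALSE)
  }
  attr(out, "sbf_config") <- list(
    min_len = min_len, max_len = max_len,
    prevalence_threshold = prevalence_threshold,
    location_window = location_window
  )
  out
}
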