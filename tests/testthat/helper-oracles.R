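# Independent brute-force oracles and small generators shared across tests.

# character-by-character first-occurrence scan (independent of locate_block)
naive_locate <- function(residues, motif) {
  m <- nchar(motif)
  n <- nchar(residues)
  if (m > n) return(0L)
  for (start in seq_len(n - m + 1L)) {
    if (substr(residues, start, start + m - 1L) == motif) return(start)
  }
  0L
}

# double-loop substring enumeration: dense motif x member first-occurrence
# table (0 = absent), independent of candidate_motifs
naive_candidates <- function(records, min_len, max_len) {
  motifs <- character(0)
  for (s in records$residues) {
    for (k in min_len:max_len) {
      if (k > nchar(s)) next
      for (start in seq_len(nchar(s) - k + 1L)) {
        motifs <- c(motifs, substr(s, start, start + k - 1L))
      }
    }
  }
  motifs <- sort(unique(motifs))
  locs <- sapply(records$residues, function(s) {
    vapply(motifs, function(m) naive_locate(s, m), integer(1))
  })
  matrix(locs, nrow = length(motifs),
         dimnames = list(motifs, records$id))
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

worked_example_records <- function() {
  read_rna_fasta(
    system.file("extdata", "worked_example.fasta", package = "riboblock"),
    family = "example"
  )
}

worked_example_blocks <- c("GGUUC", "CCC", "AAAAACUA", "GUGC", "UAUA",
                           "UCUACC", "GGGC", "GGAUG", "GGG", "CUGAGA")

# densify a candidate_motifs() result to a motif x member matrix with zeros
densify_candidates <- function(cand, ids) {
  motifs <- sort(unique(cand$motif))
  m <- matrix(0L, nrow = length(motifs), ncol = length(ids),
              dimnames = list(motifs, ids))
  m[cbind(match(cand$motif, motifs), match(cand$id, ids))] <-
    as.integer(cand$location)
  m
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
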