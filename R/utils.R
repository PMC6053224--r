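#' @importFrom stats rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

DNA <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`; ambiguity codes are complemented per IUPAC.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

## random sequence screened against a set of forbidden exact substrings
## (both the strings and, when screen_rc, their reverse complements)
random_dna_clean <- function(n, forbid = character(0), screen_rc = TRUE,
                             forbid_pyrimidine_run = FALSE, tries = 50) {
  pats <- forbid
  if (screen_rc && length(forbid)) pats <- unique(c(pats, revcomp(forbid)))
  for (t in seq_len(tries)) {
    s <- random_dna(n)
    bad <- length(pats) && any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1)))
    if (!bad && forbid_pyrimidine_run)
      bad <- has_pyrimidine_terminator(s)
    if (!bad) return(s)
  }
  stop("could not generate background sequence free of forbidden motifs after ",
       tries, " attempts")
}

has_pyrimidine_terminator <- function(s, min_len = 6, min_polyT = 3) {
  nrow(find_pyrimidine_terminator(s, min_len = min_len, min_polyT = min_polyT)) > 0
}

## per-site substitution mutation; positions in `protect` are never touched
mutate_seq <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate & chars %in% DNA)
  hit <- setdiff(hit, protect)
  for (i in hit) chars[i] <- sample(setdiff(DNA, chars[i]), 1)
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Enumerate the k-mers of a sequence
#'
#' @param s a single sequence string.
#' @param k word length.
#' @param unique drop duplicate words.
#' @return character vector of k-mers (empty when `nchar(s) < k`).
#' @export
kmers <- function(s, k, unique = TRUE) {
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- substring(s, 1:(n - k + 1), k:n)
  if (unique) unique(out) else out
}

## global identity of two sequences: matches / length of the longer sequence
seq_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) return(1 - hamming(a, b) / nchar(a))
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::nmatch(pa) / max(nchar(a), nchar(b))
}

## positions (start) of exact occurrences of pattern in subject
find_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
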