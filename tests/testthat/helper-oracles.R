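## independent brute-force oracles: enumerate substrings (or pairs, or
## structures) and test the predicate directly, no reuse of package code

oracle_polya <- function(seq, search_start = 0) {
  n <- nchar(seq)
  hits <- integer(0)
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(seq, i, i + 5) == "AATAAA" && i > search_start) hits <- c(hits, i)
  }
  hits
}

## maximal C/T substrings of length >= min_len containing TTT
oracle_pyrimidine <- function(seq, min_len = 6, min_polyT = 3) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_len) next
      sub <- substr(s, i, j)
      if (grepl("[^CT]", sub)) break  # longer substrings at i also fail
      if (!grepl(strrep("T", min_polyT), sub, fixed = TRUE)) next
      left_ok <- i == 1 || !(substr(s, i - 1, i - 1) %in% c("C", "T"))
      right_ok <- j == n || !(substr(s, j + 1, j + 1) %in% c("C", "T"))
      if (left_ok && right_ok) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

oracle_3prime_box <- function(seq) {
  box <- strsplit("GTTTAAAACAAGC", "")[[1]]
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  hits <- integer(0)
  if (n < 13) return(hits)
  for (i in 1:(n - 12)) {
    if (sum(s[i:(i + 12)] != box) <= 1) hits <- c(hits, i)
  }
  hits
}

## start positions (with longest match length) of AAU(3..6)G(G/U)
oracle_canonical_sm <- function(seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  out <- list()
  for (i in seq_len(n)) {
    best <- NA_integer_
    for (u in 6:3) {  # longest first
      len <- 2 + u + 2
      if (i + len - 1 > n) next
      w <- s[i:(i + len - 1)]
      if (w[1] == "A" && w[2] == "A" && all(w[3:(2 + u)] == "T") &&
          w[3 + u] == "G" && w[4 + u] %in% c("G", "T")) {
        best <- len
        break
      }
    }
    if (!is.na(best)) out[[length(out) + 1]] <- c(i, i + best - 1L)
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

## all-pairs amplicon enumeration by naive character comparison
oracle_pcr <- function(template, fwd, rev, max_product = 5000) {
  n <- nchar(template)
  rc <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  match_at <- function(primer, pos) {
    pos + nchar(primer) - 1 <= n &&
      substr(template, pos, pos + nchar(primer) - 1) == primer
  }
  f_sites <- Filter(function(p) match_at(fwd, p), seq_len(n))
  r_sites <- Filter(function(p) match_at(rc(rev), p), seq_len(n))
  out <- list()
  for (f in f_sites) {
    for (r in r_sites) {
      re <- r + nchar(rev) - 1
      if (r >= f + nchar(fwd) && f < re && re - f + 1 <= max_product)
        out[[length(out) + 1]] <- c(f, re)
    }
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

## exhaustive structure enumeration (no memoisation): maximum number of
## WC/GU pairs with hairpin loops >= min_loop
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(s[i], s[k])) {
        v <- rec(i + 1L, k - 1L) + 1L + rec(k + 1L, j)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, length(s))
}
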