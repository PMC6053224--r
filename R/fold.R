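## Watson-Crick + wobble pairing on U/T-normalized bases
can_pair_base <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Fold an RNA by base-pair maximization
#'
#' Nussinov-style dynamic programming over Watson-Crick and GU pairs with a
#' minimum hairpin loop, with a deterministic traceback (prefer leaving base
#' i unpaired; otherwise pair i with its smallest admissible partner). This
#' is a combinatorial approximation of thermodynamic folding; an externally
#' computed dot-bracket (e.g. an MFE fold) can be supplied instead via
#' [as_secondary_structure()].
#'
#' @param seq RNA or DNA sequence (<= 500 nt).
#' @param min_loop minimum hairpin loop length (default 3 nt).
#' @return a `secondary_structure`: sequence, dot-bracket string, pair
#'   matrix, `source = "internal_fold"`.
#' @export
fold <- function(seq, min_loop = 3) {
  s <- chartr("U", "T", toupper(seq))
  if (grepl("[^ACGTN]", s)) stop("invalid characters in sequence")
  n <- nchar(s)
  if (n > 500) stop("sequence longer than 500 nt; supply an external structure")
  ch <- strsplit(s, "")[[1]]
  if (n == 0) stop("empty sequence")
  cp <- outer(ch, ch, FUN = function(a, b) paste0(a, b)) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG")
  cp <- matrix(cp, n, n)
  ## F is (n+1) x (n+1) so F[a, b] = 0 whenever a > b
  F <- matrix(0L, n + 1, n + 1)
  if (n >= min_loop + 2) {
    for (span in (min_loop + 1):(n - 1)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- F[i + 1, j]
        ks <- (i + min_loop + 1):j
        ks <- ks[cp[i, ks]]
        if (length(ks)) {
          vals <- F[i + 1, ks - 1] + 1L + F[cbind(ks + 1, j)]
          best <- max(best, vals)
        }
        F[i, j] <- best
      }
    }
  }
  ## deterministic traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j || j - i < min_loop + 1) next
    if (F[i, j] == F[i + 1, j]) {
      stack[[length(stack) + 1]] <- c(i + 1L, j)
      next
    }
    ks <- (i + min_loop + 1):j
    ks <- ks[cp[i, ks]]
    for (k in ks) {
      if (F[i + 1, k - 1] + 1L + F[k + 1, j] == F[i, j]) {
        pairs <- rbind(pairs, c(i, k))
        stack[[length(stack) + 1]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1]] <- c(k + 1L, j)
        break
      }
    }
  }
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  structure(list(seq = seq, dotbracket = paste(db, collapse = ""),
                 pairs = pairs[order(pairs[, 1]), , drop = FALSE],
                 source = "internal_fold"),
            class = "secondary_structure")
}

#' Build a secondary structure from a dot-bracket string
#'
#' Accepts an externally computed fold (e.g. a thermodynamic MFE structure):
#' brackets must balance, every pair must be Watson-Crick or GU, and hairpin
#' loops must be at least `min_loop` nt.
#'
#' @param seq the folded sequence.
#' @param dotbracket matching dot-bracket string.
#' @param source provenance label (default `"external"`).
#' @param min_loop minimum hairpin loop enforced (default 3).
#' @return a `secondary_structure`.
#' @export
as_secondary_structure <- function(seq, dotbracket, source = "external",
                                   min_loop = 3) {
  s <- chartr("U", "T", toupper(seq))
  if (nchar(dotbracket) != nchar(s)) stop("structure/sequence length mismatch")
  ch <- strsplit(s, "")[[1]]
  db <- strsplit(dotbracket, "")[[1]]
  if (!all(db %in% c("(", ")", "."))) stop("invalid dot-bracket characters")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!can_pair_base(ch[j], ch[i]))
        stop("non-canonical pair at (", j, ", ", i, ")")
      if (i - j - 1 < min_loop) stop("hairpin loop shorter than ", min_loop)
      pairs <- rbind(pairs, c(j, i))
    }
  }
  if (length(stack)) stop("unbalanced brackets")
  structure(list(seq = seq, dotbracket = dotbracket,
                 pairs = pairs[order(pairs[, 1]), , drop = FALSE],
                 source = source),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "  (", nrow(x$pairs), " pairs, ",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Enumerate stem-loops in a secondary structure
#'
#' Hairpins are the innermost paired regions enclosing a loop; stems are
#' extended outward across bulges of up to `max_bulge` unpaired nt per side
#' (recorded as bulges). Stem-loops are ordered 5' to 3' and numbered with
#' roman numerals; stems shorter than 3 bp are not reported.
#'
#' @param structure a `secondary_structure`.
#' @param max_bulge maximum bulge width crossed while extending a stem
#'   (default 3 nt).
#' @return list of `stem_loop` lists (name, outer interval, stem length in
#'   bp, loop interval, bulge intervals).
#' @export
find_stem_loops <- function(structure, max_bulge = 3) {
  pr <- structure$pairs
  if (!nrow(pr)) return(list())
  paired <- logical(nchar(structure$dotbracket))
  paired[c(pr[, 1], pr[, 2])] <- TRUE
  ## hairpins: pairs enclosing no other pair
  is_hairpin <- vapply(seq_len(nrow(pr)), function(r) {
    !any(pr[, 1] > pr[r, 1] & pr[, 2] < pr[r, 2])
  }, logical(1))
  out <- list()
  for (r in which(is_hairpin)) {
    a <- pr[r, 1]; b <- pr[r, 2]
    loop <- c(a + 1L, b - 1L)
    stem_pairs <- 1L
    bulges <- list()
    repeat {
      ## closest enclosing pair reachable across small bulges
      enc <- which(pr[, 1] < a & pr[, 2] > b)
      if (!length(enc)) break
      cand <- enc[which.max(pr[enc, 1])]
      ga <- a - pr[cand, 1] - 1L
      gb <- pr[cand, 2] - b - 1L
      if (ga > max_bulge || gb > max_bulge) break
      ## the gap must be unpaired (otherwise it is a multiloop junction)
      gap_pos <- c(if (ga > 0) (pr[cand, 1] + 1L):(a - 1L),
                   if (gb > 0) (b + 1L):(pr[cand, 2] - 1L))
      if (length(gap_pos) && any(paired[gap_pos])) break
      if (ga > 0) bulges <- c(bulges, list(c(pr[cand, 1] + 1L, a - 1L)))
      if (gb > 0) bulges <- c(bulges, list(c(b + 1L, pr[cand, 2] - 1L)))
      a <- pr[cand, 1]; b <- pr[cand, 2]
      stem_pairs <- stem_pairs + 1L
    }
    if (stem_pairs < 3) next
    out[[length(out) + 1]] <- list(outer = c(a, b), stem_length = stem_pairs,
                                   loop = loop, bulges = bulges)
  }
  if (!length(out)) return(list())
  out <- out[order(vapply(out, function(x) x$outer[1], integer(1)))]
  for (i in seq_along(out)) {
    out[[i]]$name <- as.character(utils::as.roman(i))
    class(out[[i]]) <- "stem_loop"
  }
  out
}
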