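#' Construct a set of sequence records
#'
#' The unit flowing through the pipeline: a data frame with columns `id`,
#' `seq` and (optionally) `qual`, one row per record. Sequences are stored
#' uppercase; quality strings, when present, must match sequence lengths.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of sequences (DNA or protein).
#' @param qual optional character vector of Phred+33 quality strings.
#' @return a `seq_set` data frame.
#' @export
seq_set <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("empty sequence in records: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  df <- data.frame(id = as.character(id), seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != length(seq)) stop("qual length mismatch")
    bad <- which(nchar(qual) != nchar(seq))
    if (length(bad)) stop("quality/sequence length mismatch at record ", bad[1])
    df$qual <- as.character(qual)
  }
  class(df) <- c("seq_set", "data.frame")
  df
}

#' Read sequences from FASTA or FASTQ
#'
#' Order-preserving; multi-line FASTA and CRLF line endings are tolerated and
#' lowercase letters are upcased. Malformed input is rejected with an error.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @return a [seq_set()].
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) stop("malformed FASTA in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    seq_set(names(ss), as.character(ss))
  } else {
    validate_fastq(path)
    ss <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    seq_set(sub("\\s.*$", "", names(ss)), as.character(ss),
            qual = as.character(Biostrings::quality(ss)))
  }
}

## light structural validation so malformed records are rejected with the
## record index rather than a parser-internal message
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ in ", path,
                                    ": line count not a multiple of 4")
  n <- length(lines) / 4
  for (i in seq_len(n)) {
    b <- (i - 1) * 4
    if (!startsWith(lines[b + 1], "@")) stop("malformed FASTQ record ", i, ": missing @ header")
    if (!startsWith(lines[b + 3], "+")) stop("malformed FASTQ record ", i, ": missing + line")
    if (nchar(lines[b + 2]) != nchar(lines[b + 4]))
      stop("malformed FASTQ record ", i, ": quality length differs from sequence length")
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a [seq_set()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires a `qual` column).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(setNames(x$seq, x$id))
    Biostrings::writeXStringSet(ss, path, format = "fasta")
  } else {
    if (is.null(x$qual)) stop("FASTQ output requires a qual column")
    ## the quality container predictably drops mcols; nothing is lost here
    withCallingHandlers({
      dna <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
      q <- Biostrings::PhredQuality(x$qual)
      qs <- Biostrings::QualityScaledDNAStringSet(dna, q)
      Biostrings::writeQualityScaledXStringSet(qs, path)
    }, warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  invisible(path)
}

#' Write annotation rows as TSV or GFF3
#'
#' GFF3 output is 1-based inclusive; recognised feature types include
#' `SL_RNA_gene` and `trans_splice_acceptor`.
#'
#' @param rows data frame; for GFF3 it must have columns `seqid`, `type`,
#'   `start`, `end`, `strand` and optionally `attributes`.
#' @param path output file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(rows, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (nrow(rows) && all(c("start", "end") %in% names(rows)) &&
      any(rows$end < rows$start))
    stop("interval end < start in annotation rows")
  if (dialect == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    need <- c("seqid", "type", "start", "end", "strand")
    if (nrow(rows) && !all(need %in% names(rows)))
      stop("GFF3 rows need columns: ", paste(need, collapse = ", "))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(rows)) {
      attrs <- rows$attributes %||% rep(".", nrow(rows))
      writeLines(paste(rows$seqid, "slseeker", rows$type, rows$start, rows$end,
                       ".", rows$strand, ".", attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Default run configuration
#'
#' Stage parameters shared by the pipeline, each bounds-checked by
#' [load_config()].
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    min_read_len = 30,
    screen_k = 15,
    screen_containment_min = 0.5,
    nterm_len = 50,
    seed_len = 8,
    min_score = 40,
    cluster_skip_5p = 40,
    cluster_k = 15,
    cluster_share_min = 0.5,
    leader_window = 40,
    leader_kmer = 12,
    cluster_fraction_min = 0.5,
    min_clusters = 5,
    scan_max_mismatch = 2,
    downstream_window = 300,
    intron_prefix = 60,
    identity_min = 0.8,
    conservation_window = 10,
    conservation_min = 0.9,
    tss_min_identity = 0.95,
    tss_min_coverage = 0.9,
    upstream_window = 5000,
    min_intron = 40,
    max_product = 5000
  )
}

config_bounds <- function() {
  list(
    min_read_len = c(0, Inf), screen_k = c(4, 32),
    screen_containment_min = c(0, 1), nterm_len = c(1, Inf),
    seed_len = c(3, 20), min_score = c(0, Inf), cluster_skip_5p = c(0, Inf),
    cluster_k = c(4, 32), cluster_share_min = c(0, 1), leader_window = c(1, Inf),
    leader_kmer = c(4, 32), cluster_fraction_min = c(0, 1),
    min_clusters = c(1, Inf), scan_max_mismatch = c(0, 5),
    downstream_window = c(1, Inf), intron_prefix = c(1, Inf),
    identity_min = c(0, 1), conservation_window = c(1, Inf),
    conservation_min = c(0, 1), tss_min_identity = c(0, 1),
    tss_min_coverage = c(0, 1), upstream_window = c(1, Inf),
    min_intron = c(1, Inf), max_product = c(1, Inf)
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; every known parameter is bounds-checked; keys
#' absent from the file keep their defaults. `overrides` (e.g. command-line
#' values) beat file values.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file; an empty file
#'   yields pure defaults.
#' @param overrides named list applied on top of the file.
#' @return named list (a `RunConfig`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(vals)) vals <- list()
  }
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  bounds <- config_bounds()
  for (nm in names(bounds)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < bounds[[nm]][1] || v > bounds[[nm]][2])
      stop("parameter out of bounds: ", nm, " = ", v,
           " (allowed [", bounds[[nm]][1], ", ", bounds[[nm]][2], "])")
  }
  cfg
}

#' Build a per-stage filtering report
#'
#' Each stage reports how many records entered, how many were kept, and the
#' discard counts by reason; chaining the reports reconstructs the filtering
#' cascade.
#'
#' @param stage stage name.
#' @param input_count records entering the stage.
#' @param kept_count records surviving.
#' @param discarded named integer vector of discard counts by reason.
#' @return a `filter_report` list.
#' @export
filter_report <- function(stage, input_count, kept_count, discarded = integer(0)) {
  if (input_count != kept_count + sum(discarded))
    stop("filter report does not balance: ", input_count, " != ",
         kept_count, " + ", sum(discarded))
  structure(list(stage = stage, input_count = input_count,
                 kept_count = kept_count, discarded = discarded),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] in=%d kept=%d", x$stage, x$input_count, x$kept_count))
  if (length(x$discarded))
    cat(" discarded:", paste(names(x$discarded), x$discarded, sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}
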