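#' HT-SELEX read pool
#'
#' A pool is the set of sequenced oligonucleotides for one selection round.
#' Round 0 is the initial (unselected) library used to train the Markov
#' background.
#'
#' @param x Character vector of reads, or a path to a FASTQ, FASTA or
#'   one-sequence-per-line text file.
#' @param round_index Selection round (integer >= 0).
#' @param format File format, `"auto"` (by extension/first byte), `"fastq"`,
#'   `"fasta"` or `"txt"`. Ignored when `x` is already a character vector of
#'   reads.
#' @return Object of class `read_pool`: list with `reads`, `round_index`,
#'   `source_file`.
#' @export
read_pool <- function(x, round_index, format = c("auto", "fastq", "fasta", "txt")) {
  format <- match.arg(format)
  source_file <- NA_character_
  if (length(x) == 1 && file.exists(x)) {
    source_file <- x
    reads <- .read_sequences(x, format)
  } else {
    reads <- x
  }
  reads <- unname(toupper(reads))
  reads <- reads[nzchar(reads)]
  if (length(reads) == 0) stop("empty read pool")
  if (round_index < 0) stop("round_index must be >= 0")
  structure(list(reads = reads, round_index = as.integer(round_index),
                 source_file = source_file),
            class = "read_pool")
}

.read_sequences <- function(path, format = "auto") {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq"
      else if (ext %in% c("fa", "fasta", "fna")) "fasta"
      else {
        first <- substr(readLines(path, n = 1), 1, 1)
        if (first == "@") "fastq" else if (first == ">") "fasta" else "txt"
      }
  }
  if (format == "txt") return(readLines(path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readDNAStringSet(path, format = format)))
  }
  # plain-text fallback parsers
  lines <- readLines(path)
  if (format == "fastq") {
    if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
    return(lines[seq(2, length(lines), by = 4)])
  }
  hdr <- grepl("^>", lines)
  unname(tapply(lines[!hdr], cumsum(hdr)[!hdr], paste, collapse = ""))
}

#' Write a read pool to disk
#'
#' @param pool A [read_pool()] object or character vector of reads.
#' @param path Output file.
#' @param format `"txt"` (one sequence per line), `"fasta"`, or `"fastq"`
#'   (dummy `I` qualities).
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path, format = c("txt", "fasta", "fastq")) {
  format <- match.arg(format)
  reads <- if (inherits(pool, "read_pool")) pool$reads else pool
  lines <- switch(format,
    txt = reads,
    fasta = as.vector(rbind(paste0(">read", seq_along(reads)), reads)),
    fastq = as.vector(rbind(paste0("@read", seq_along(reads)), reads, "+",
                            vapply(nchar(reads),
                                   function(n) strrep("I", n), character(1)))))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.read_pool <- function(x, ...) {
  cat("HT-SELEX read pool: round ", x$round_index, ", ",
      length(x$reads), " reads of length ",
      paste(unique(range(nchar(x$reads))), collapse = "-"), "\n", sep = "")
  invisible(x)
}

# integer codes 0..3 for A,C,G,T; NA for anything else.
# Returns an n x L matrix (reads must share one length).
.code_matrix <- function(reads) {
  L <- unique(nchar(reads))
  if (length(L) != 1) stop("reads must all have the same length")
  ch <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
               nrow = length(reads), ncol = L, byrow = TRUE)
  m <- match(ch, BASES) - 1L
  dim(m) <- dim(ch)
  m
}
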