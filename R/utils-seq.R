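# Low-level sequence handling. Sequences travel through the package as plain
# character vectors (one string per scaffold/read); integer encodings
# (A=1, C=2, G=3, T=4, other=0) are used internally for vectorised matching.

.BASE2INT <- local({
  m <- integer(256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

.INT2CODE <- c(utf8ToInt("N"), utf8ToInt("A"), utf8ToInt("C"),
               utf8ToInt("G"), utf8ToInt("T"))

seq_to_int <- function(s) .BASE2INT[utf8ToInt(s)]

int_to_seq <- function(v) intToUtf8(.INT2CODE[v + 1L])

# integer complement: A<->T, C<->G, invalid stays invalid
.INT_COMP <- c(0L, 4L, 3L, 2L, 1L)

revcomp_int <- function(v) rev(.INT_COMP[v + 1L])

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return character vector of reverse complements (upper case).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) int_to_seq(revcomp_int(seq_to_int(s))), character(1),
         USE.NAMES = FALSE)
}

# convert a character vector of equal-length reads into an integer matrix
# (rows = reads, cols = positions)
reads_to_int_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all reads must have equal length for matrix encoding")
  codes <- .BASE2INT[utf8ToInt(paste(seqs, collapse = ""))]
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

int_matrix_to_seqs <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  codes <- .INT2CODE[t(m) + 1L]
  n <- nrow(m); L <- ncol(m)
  vapply(seq_len(n), function(i) intToUtf8(codes[((i - 1L) * L + 1L):(i * L)]),
         character(1))
}

random_dna <- function(len) {
  int_to_seq(sample.int(4L, len, replace = TRUE))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path (".gz" suffix enables compression).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file path (".gz" suffix enables compression).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

# headerless writer for BED-style tables
write_bed_file <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
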