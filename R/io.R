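# FASTA/FASTQ and tabular I/O, via Biostrings at the boundaries.

#' Read a FASTA file
#'
#' @param path file path (optionally gzipped).
#' @return named character vector of sequences (full header as name).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Keeps the full header line (including any `BX:Z:` barcode comment) as the
#' read name.
#'
#' @param path file path (optionally gzipped).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (constant quality)
#'
#' @param seqs named character vector of reads.
#' @param path output path.
#' @param qual_char quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs) %||% paste0("read", seq_along(seqs))
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep(qual_char, n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write a de Bruijn graph as GFA-like text
#'
#' Segments (`S`) carry a `dp:f:` depth tag; links (`L`) carry the exact
#' (k-1)-mer overlap. Junction segments are tagged `jn:i:1`.
#'
#' @param graph a `dbg` object from [build_graph()].
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tkm:i:%d", graph$k), con)
  nd <- graph$nodes
  writeLines(sprintf("S\t%d\t%s\tdp:f:%.4f\tjn:i:%d",
                     seq_len(nrow(nd)), nd$seq, nd$depth,
                     as.integer(nd$junction)), con)
  ed <- graph$edges
  if (nrow(ed)) {
    # end 1 = '+' exit (3' of stored), end 0 = '-' exit
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                       ed$a, ifelse(ed$ea == 1L, "+", "-"),
                       ed$b, ifelse(ed$eb == 0L, "+", "-"),
                       graph$k - 1L), con)
  }
  invisible(path)
}

#' Read a GFA-like graph written by [write_gfa()]
#'
#' @param path input path.
#' @return a `dbg` object.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[startsWith(lines, "H")][1], "\t")[[1]]
  k <- as.integer(sub("km:i:", "", grep("^km:i:", hd, value = TRUE)[1]))
  sl <- strsplit(lines[startsWith(lines, "S\t")], "\t")
  nodes <- data.frame(
    seq = vapply(sl, `[`, character(1), 3L),
    depth = as.numeric(sub("dp:f:", "", vapply(sl, `[`, character(1), 4L))),
    junction = sub("jn:i:", "", vapply(sl, `[`, character(1), 5L)) == "1",
    stringsAsFactors = FALSE)
  nodes$len <- nchar(nodes$seq)
  ll <- strsplit(lines[startsWith(lines, "L\t")], "\t")
  if (length(ll)) {
    edges <- data.frame(
      a = as.integer(vapply(ll, `[`, character(1), 2L)),
      ea = ifelse(vapply(ll, `[`, character(1), 3L) == "+", 1L, 0L),
      b = as.integer(vapply(ll, `[`, character(1), 4L)),
      eb = ifelse(vapply(ll, `[`, character(1), 5L) == "+", 0L, 1L))
  } else {
    edges <- empty_edges()
  }
  new_dbg(k, nodes, edges)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
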