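# Alignment plumbing: a thin wrapper around the minimap2 command-line
# aligner producing PAF records as a data.frame, plus parsing of long-form
# cs tags into aligned blocks. Only the filter contracts implemented in
# this package are normative; any aligner producing the same fields works
# (see read_paf() for externally produced alignments).

minimap2_available <- function() nzchar(Sys.which("minimap2"))

#' Align query sequences to target sequences with minimap2
#'
#' @param query named character vector of query sequences.
#' @param target named character vector of target sequences, or a file path.
#' @param preset additional minimap2 options (character vector).
#' @param cs request the long-form cs tag needed for base-level blocks.
#' @return PAF data.frame (see [read_paf()]); zero rows if nothing aligns.
#' @export
align_minimap2 <- function(query, target,
                           preset = c("-c", "-k", "19", "-w", "5", "-A", "1",
                                      "-B", "4", "-P"),
                           cs = TRUE) {
  if (!minimap2_available()) stop("minimap2 not found on PATH")
  qf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, tf_clean)), add = TRUE)
  names(query) <- names(query) %||% paste0("q", seq_along(query))
  write_fasta(query, qf)
  if (length(target) == 1L && file.exists(target)) {
    tf <- target
    tf_clean <- character(0)
  } else {
    tf <- tempfile(fileext = ".fa")
    tf_clean <- tf
    names(target) <- names(target) %||% paste0("t", seq_along(target))
    write_fasta(target, tf)
  }
  args <- c(preset, if (cs) "--cs=long", tf, qf)
  out <- suppressWarnings(system2("minimap2", args, stdout = TRUE,
                                  stderr = FALSE))
  parse_paf_lines(out)
}

#' Self-alignment of a sequence set with minimap2 (all-vs-all, -X)
#'
#' @inheritParams align_minimap2
#' @param seqs named character vector.
#' @return PAF data.frame excluding self-alignments.
#' @export
self_align_minimap2 <- function(seqs, cs = TRUE) {
  align_minimap2(seqs, seqs,
                 preset = c("-c", "-k", "19", "-w", "5", "-p", "0", "-N", "50",
                            "-X"),
                 cs = cs)
}

#' Read a PAF file
#'
#' @param path PAF file path.
#' @return data.frame with the 12 standard columns (`query`, `qlen`,
#'   `qstart`, `qend`, `strand`, `target`, `tlen`, `tstart`, `tend`,
#'   `matches`, `aln_len`, `mapq`) plus `NM` (edit distance) and `cs` tags
#'   when present.
#' @export
read_paf <- function(path) parse_paf_lines(readLines(path))

parse_paf_lines <- function(lines) {
  empty <- data.frame(query = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), target = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), matches = integer(0),
                      aln_len = integer(0), mapq = integer(0),
                      NM = integer(0), cs = character(0),
                      stringsAsFactors = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(fields, `[`, character(1), i)
  tag <- function(prefix) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
    }, character(1))
  }
  data.frame(
    query = getf(1), qlen = as.integer(getf(2)),
    qstart = as.integer(getf(3)), qend = as.integer(getf(4)),
    strand = getf(5), target = getf(6), tlen = as.integer(getf(7)),
    tstart = as.integer(getf(8)), tend = as.integer(getf(9)),
    matches = as.integer(getf(10)), aln_len = as.integer(getf(11)),
    mapq = as.integer(getf(12)),
    NM = suppressWarnings(as.integer(tag("NM:i:"))),
    cs = tag("cs:Z:"), stringsAsFactors = FALSE)
}

# Parse a long-form cs tag into per-op tables.
# Ops: "=ACGT" exact run, "*ac" substitution (target base, query base),
# "+acgt" insertion to query, "-acgt" deletion from query.
parse_cs <- function(cs) {
  m <- gregexpr("[=*+-][A-Za-z]+", cs)[[1]]
  ops <- regmatches(cs, gregexpr("[=*+-][A-Za-z]+", cs))[[1]]
  if (length(ops) == 0L || m[1] == -1L)
    return(data.frame(op = character(0), seq = character(0)))
  data.frame(op = substr(ops, 1L, 1L), seq = toupper(substring(ops, 2L)),
             stringsAsFactors = FALSE)
}

# expand a cs tag into aligned sequence columns (target row, query row,
# '-' for gaps); target/query run in alignment orientation
cs_to_alignment <- function(cs) {
  ops <- parse_cs(cs)
  tgt <- character(nrow(ops))
  qry <- character(nrow(ops))
  for (i in seq_len(nrow(ops))) {
    s <- ops$seq[i]
    switch(ops$op[i],
      "=" = { tgt[i] <- s; qry[i] <- s },
      "*" = { tgt[i] <- substr(s, 1L, 1L); qry[i] <- substr(s, 2L, 2L) },
      "+" = { tgt[i] <- strrep("-", nchar(s)); qry[i] <- s },
      "-" = { tgt[i] <- s; qry[i] <- strrep("-", nchar(s)) })
  }
  list(target = paste(tgt, collapse = ""), query = paste(qry, collapse = ""))
}

# count N bases inside the aligned region of both sequences
n_bases_in_alignment <- function(paf_row, qseqs, tseqs) {
  q <- substring(qseqs[[paf_row$query]], paf_row$qstart + 1L, paf_row$qend)
  t <- substring(tseqs[[paf_row$target]], paf_row$tstart + 1L, paf_row$tend)
  sum(vapply(gregexpr("N", c(q, t), fixed = TRUE), function(g)
    sum(g > 0L), numeric(1)))
}
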