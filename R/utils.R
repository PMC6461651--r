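#' @useDynLib haplotangle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rgeom rnorm runif setNames weighted.mean
#' @importFrom utils head read.table tail write.table
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Characters
#' outside `ACGTacgt` become `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  cpp_revcomp(as.character(x))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; used by the simulator for genome backgrounds.
#'
#' @param n sequence length in bp.
#' @return a single string of length `n`.
#' @export
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a private, seeded RNG state
#'
#' Restores the caller's RNG state on exit so simulation calls are
#' deterministic without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# split a sequence into contigs at runs of >= 1 N
split_at_gaps <- function(seq) {
  parts <- strsplit(seq, "N+")[[1]]
  parts[nzchar(parts)]
}

# non-overlapping fixed-length fragments from position 0; trailing partial
# fragment discarded
fragmentize <- function(seqs, fragment_len, drop_n = TRUE) {
  out <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    nf <- n %/% fragment_len
    if (nf == 0L) return(NULL)
    starts <- (seq_len(nf) - 1L) * fragment_len + 1L
    frags <- substring(s, starts, starts + fragment_len - 1L)
    data.frame(source = i, start = starts - 1L, frag = frags,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(source = integer(0), start = integer(0),
                      frag = character(0), stringsAsFactors = FALSE))
  }
  if (drop_n) res <- res[!grepl("N", res$frag, fixed = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}
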