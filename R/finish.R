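# Finishing: close scaffold gaps by local assembly of uniquely mapped
# reads, and build consensus scaffolds from primary bubbles plus
# non-bubble sequences.

#' Close gaps in phased blocks by local assembly
#'
#' For every `N` run, reads whose unique placements (their own or their
#' mate's) fall within the flank windows are collected and assembled with
#' a small de Bruijn graph; the gap is replaced if and only if exactly one
#' simple path connects the two flank anchor k-mers within the expansion
#' bound. Non-N bases are never modified.
#'
#' @param blocks a `phased_blocks` object (or data.frame with `seq`).
#' @param libs read libraries used for assignment (short libraries only).
#' @param k_local local assembly k (default: half the final graph k,
#'   passed by the pipeline; standalone default 45).
#' @param max_expand path length bound as a multiple of the gap estimate.
#' @param flank window size around the gap for read assignment (`NULL`:
#'   largest library insert).
#' @return the blocks with closed gaps, plus a `report` attribute
#'   (data.frame: block, gap position, status, inserted length).
#' @export
close_gaps <- function(blocks, libs, k_local = 45L, max_expand = 10,
                       flank = NULL) {
  df <- if (inherits(blocks, "phased_blocks")) blocks$blocks else blocks
  if (inherits(libs, "read_library")) libs <- list(libs)
  short <- Filter(function(l) l$spec$type %in% c("paired", "mate"), libs)
  if (length(short) == 0L) return(blocks)
  flank <- flank %||% max(vapply(short, function(l) l$spec$insert_mean,
                                 numeric(1)))
  reads1 <- reads2 <- character(0)
  for (lib in short) {
    r1 <- unname(lib$reads1); r2 <- unname(lib$reads2)
    if (lib$spec$type == "mate") { r1 <- revcomp(r1); r2 <- revcomp(r2) }
    reads1 <- c(reads1, r1); reads2 <- c(reads2, r2)
  }
  all_reads <- c(reads1, reads2)
  n1 <- length(reads1)
  pl <- cpp_map_reads(df$seq, all_reads, 32L)
  pl <- primary_placements(transform(pl,
                                     pair = ifelse(read <= n1, read,
                                                   read - n1),
                                     mate = ifelse(read <= n1, 1L, 2L)))
  report <- list()
  for (bi in seq_len(nrow(df))) {
    s <- df$seq[bi]
    gaps <- gregexpr("N+", s)[[1]]
    if (gaps[1] == -1L) next
    glen <- attr(gaps, "match.length")
    # close right-to-left so earlier coordinates stay valid
    for (gi in rev(seq_along(gaps))) {
      g0 <- gaps[gi]; gl <- glen[gi]
      res <- close_one_gap(s, g0, gl, bi, pl, all_reads, n1, k_local,
                           max_expand, flank)
      report[[length(report) + 1L]] <- data.frame(
        block = df$name[bi] %||% bi, pos = g0, gap_len = gl,
        status = res$status, inserted = res$inserted,
        stringsAsFactors = FALSE)
      if (res$status == "closed") s <- res$seq
    }
    df$seq[bi] <- s
  }
  report <- if (length(report)) do.call(rbind, report) else NULL
  if (inherits(blocks, "phased_blocks")) {
    blocks$blocks <- df
    attr(blocks, "gap_report") <- report
    blocks
  } else {
    attr(df, "gap_report") <- report
    df
  }
}

close_one_gap <- function(s, g0, gl, bi, pl, all_reads, n1, k_local,
                          max_expand, flank) {
  fail <- function(status) list(status = status, inserted = NA_integer_,
                                seq = s)
  left_end <- g0 - 1L # last non-N base before the gap (1-based)
  right_start <- g0 + gl
  if (left_end < k_local || right_start + k_local - 1L > nchar(s))
    return(fail("no_anchor"))
  # negative true gap: scaffold joins over a sequence overlap are rendered
  # as a minimal N run; close them by exact flank overlap
  lf <- substring(s, max(1L, left_end - 3L * k_local), left_end)
  rf <- substring(s, right_start,
                  min(nchar(s), right_start + 3L * k_local - 1L))
  max_ov <- min(nchar(lf), nchar(rf))
  for (ov in (if (max_ov >= 30L) seq(max_ov, 30L) else integer(0))) {
    if (substring(lf, nchar(lf) - ov + 1L) == substring(rf, 1L, ov)) {
      new_seq <- paste0(substring(s, 1L, left_end),
                        substring(s, right_start + ov, nchar(s)))
      return(list(status = "closed", inserted = -ov, seq = new_seq))
    }
  }
  lo <- max(1L, left_end - flank)
  hi <- min(nchar(s), right_start + flank)
  near <- pl$node == bi & pl$rstart >= lo - 1L & pl$rstart <= hi - 1L
  ids <- unique(pl$pair[near])
  if (length(ids) == 0L) return(fail("no_reads"))
  rd <- c(all_reads[ids], all_reads[n1 + ids])
  rd <- rd[!is.na(rd) & nchar(rd) >= k_local]
  if (length(rd) == 0L) return(fail("no_reads"))
  kset <- local_kmer_set(c(rd, revcomp(rd)), k_local)
  left_anchor <- substring(s, left_end - k_local + 1L, left_end)
  right_anchor <- substring(s, right_start, right_start + k_local - 1L)
  path <- unique_path(kset, left_anchor, right_anchor,
                      max_len = gl * max_expand + 2L * k_local + 100L)
  if (is.null(path)) return(fail("no_unique_path"))
  middle <- substring(path, k_local + 1L, nchar(path) - k_local)
  new_seq <- paste0(substring(s, 1L, left_end), middle,
                    substring(s, right_start, nchar(s)))
  list(status = "closed", inserted = nchar(middle), seq = new_seq)
}

local_kmer_set <- function(reads, k) {
  env <- new.env(parent = emptyenv(), size = 4096L)
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    km <- substring(r, 1:(n - k + 1L), k:n)
    km <- km[!grepl("N", km, fixed = TRUE)]
    for (x in km) assign(x, TRUE, envir = env)
  }
  env
}

# all simple paths from `from` to `to` in the directed k-mer graph; returns
# the spelled path iff exactly one exists within the bounds
unique_path <- function(kset, from, to, max_len, max_states = 20000L,
                        max_paths = 10L) {
  k <- nchar(from)
  if (!exists(from, envir = kset) || !exists(to, envir = kset)) return(NULL)
  paths <- character(0)
  states <- 0L
  stack <- list(list(km = from, spell = from))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    states <- states + 1L
    if (states > max_states) return(NULL)
    if (st$km == to && nchar(st$spell) > k) {
      paths <- c(paths, st$spell)
      if (length(paths) > max_paths) return(NULL)
      next
    }
    if (st$km == to && nchar(st$spell) == k && from == to) next
    if (nchar(st$spell) > max_len) next
    suffix <- substring(st$km, 2L, k)
    for (b in c("A", "C", "G", "T")) {
      nxt <- paste0(suffix, b)
      if (exists(nxt, envir = kset)) {
        stack[[length(stack) + 1L]] <- list(km = nxt,
                                            spell = paste0(st$spell, b))
      }
    }
  }
  # `to` reached as the terminal k-mer: path spells from..to
  if (from == to) return(NULL)
  if (length(paths) == 1L) paths else NULL
}

#' Build consensus scaffolds from primary bubbles and non-bubble sequences
#'
#' Detects exact (k-1)-length end overlaps among the primary-bubble and
#' non-bubble sequences; a pair is concatenated when its overlap is
#' unambiguous (exactly one exit and one entry carry that overlap string).
#' The connected sequences are then passed through the link-based
#' scaffolding procedure when libraries are supplied.
#'
#' @param blocks a `phased_blocks` object.
#' @param k the final de Bruijn graph k (overlap length is k-1).
#' @param libs optional read libraries for the scaffolding pass.
#' @param min_link minimum links per scaffold bundle.
#' @return named character vector of consensus scaffolds.
#' @export
build_consensus <- function(blocks, k, libs = NULL, min_link = 2L) {
  df <- blocks$blocks
  seqs <- df$seq[df$role %in% c("primary", "nonbubble")]
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  ov <- k - 1L
  exit_str <- function(i, e) {
    s <- seqs[i]
    if (e == 1L) substring(s, nchar(s) - ov + 1L, nchar(s)) else
      revcomp(substring(s, 1L, ov))
  }
  entry_str <- function(i, e) {
    s <- seqs[i]
    if (e == 0L) substring(s, 1L, ov) else
      revcomp(substring(s, nchar(s) - ov + 1L, nchar(s)))
  }
  idx <- expand.grid(i = seq_along(seqs), e = c(0L, 1L))
  exits <- mapply(exit_str, idx$i, idx$e)
  entries <- mapply(entry_str, idx$i, idx$e)
  joins <- list()
  for (u in intersect(exits, entries)) {
    if (grepl("N", u, fixed = TRUE)) next
    xi <- which(exits == u)
    yi <- which(entries == u)
    # a palindromic or shared overlap on several ends is ambiguous
    if (length(xi) != 1L || length(yi) != 1L) next
    if (idx$i[xi] == idx$i[yi]) next
    joins[[length(joins) + 1L]] <- data.frame(
      a = idx$i[xi], ea = idx$e[xi], b = idx$i[yi],
      eb = idx$e[yi], gap = -ov)
  }
  merged <- overlap_merge(seqs, joins, ov)
  if (!is.null(libs)) {
    ss <- scaffold_init(data.frame(seq = merged, depth = 1))
    mp <- map_short_reads(merged, libs)
    ph <- scaffold_phase(ss, mp$links, c_hetero = NA_real_,
                         min_link = min_link)
    sg <- build_scaffold_graph(ph$ss, mp$links, min_link)
    j <- join_unambiguous(ph$ss, sg$bundles)
    merged <- scaffold_seqs(j$ss)
  }
  setNames(merged, sprintf("consensus_%d", seq_along(merged)))
}

# chain-merge sequences over exact overlaps (gap = -overlap)
overlap_merge <- function(seqs, joins, ov) {
  if (length(joins) == 0L) return(seqs)
  jdf <- do.call(rbind, joins)
  # enforce at most one join per (seq, end)
  key_a <- paste(jdf$a, jdf$ea); key_b <- paste(jdf$b, jdf$eb)
  dup <- duplicated(key_a) | duplicated(key_b)
  jdf <- jdf[!dup, , drop = FALSE]
  jmap <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(jdf))) {
    assign(paste(jdf$a[i], jdf$ea[i]), c(jdf$b[i], jdf$eb[i]), envir = jmap)
    assign(paste(jdf$b[i], jdf$eb[i]), c(jdf$a[i], jdf$ea[i]), envir = jmap)
  }
  joined <- function(s, e) exists(paste(s, e), envir = jmap)
  visited <- logical(length(seqs))
  out <- character(0)
  for (s in seq_along(seqs)) {
    if (visited[s]) next
    outer <- if (!joined(s, 0L) && joined(s, 1L)) 0L
      else if (!joined(s, 1L) && joined(s, 0L)) 1L
      else if (!joined(s, 0L) && !joined(s, 1L)) { # isolated
        visited[s] <- TRUE; out <- c(out, seqs[s]); next
      } else next
    cur <- s; inner <- 1L - outer
    acc <- if (outer == 0L) seqs[s] else revcomp(seqs[s])
    visited[s] <- TRUE
    repeat {
      key <- paste(cur, inner)
      if (!exists(key, envir = jmap)) break
      nxt <- get(key, envir = jmap)
      if (visited[nxt[1]]) break
      nxt_seq <- if (nxt[2] == 0L) seqs[nxt[1]] else revcomp(seqs[nxt[1]])
      acc <- paste0(acc, substring(nxt_seq, ov + 1L))
      visited[nxt[1]] <- TRUE
      cur <- nxt[1]; inner <- 1L - nxt[2]
    }
    out <- c(out, acc)
  }
  # cycles: emit members unmerged
  c(out, seqs[!visited])
}
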