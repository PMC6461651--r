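# Independent brute-force oracles. These re-derive expected values by the
# most literal method available and stay independent of the package
# implementation paths they check.

# -- division boundaries (majority counterpart + division score) ----------
oracle_division <- function(b, l) {
  if (all(b == 0)) return(NULL)
  ids <- sort(unique(b[b != 0]))
  best <- -Inf; B <- NA
  for (x in ids) {
    s <- 0
    for (i in seq_along(b)) if (b[i] == x) s <- s + l[i]
    if (s > best) { best <- s; B <- x } # ascending ids: ties keep smaller
  }
  idx <- which(b == B)
  d0 <- min(idx); d1 <- max(idx)
  # forward pass
  S <- numeric(0); prev <- 0
  for (x in d0:d1) {
    step <- if (b[x] == 0) 0 else if (b[x] == B) -l[x] else l[x]
    prev <- prev + step
    S <- c(S, prev)
  }
  dmin <- d0
  if (max(S) > 0) dmin <- (d0:d1)[which(S == max(S))[1]]
  # backward pass
  Sb <- numeric(0); prev <- 0
  for (x in d1:d0) {
    step <- if (b[x] == 0) 0 else if (b[x] == B) -l[x] else l[x]
    prev <- prev + step
    Sb <- c(prev, Sb)
  }
  dmax <- d1
  if (max(Sb) > 0) dmax <- (d0:d1)[which(Sb == max(Sb))[1]]
  if (dmin > dmax) { dmin <- d0; dmax <- d1 }
  list(B_max = B, d_min = dmin, d_max = dmax)
}

# -- untangling decision rule ---------------------------------------------
oracle_untangle_decision <- function(par, crs, method, center_len = 0,
                                     ratio = 4) {
  if (method == "barcode" && center_len >= 200000) return("unresolved")
  if (par >= 1 && par >= ratio * crs) return("parallel")
  if (crs >= 1 && crs >= ratio * par) return("cross")
  "unresolved"
}

# -- NG50/LG50 by sort-and-scan -------------------------------------------
oracle_ng50 <- function(lens, genome_size) {
  lens <- sort(lens, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc > genome_size / 2) return(list(ng50 = lens[i], lg50 = i))
  }
  list(ng50 = 0L, lg50 = 0L)
}

# -- canonical k-mer counting by direct window enumeration ----------------
oracle_count_kmers <- function(seqs, k) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  tab <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substring(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      cw <- min(w, rc1(w))
      cur <- if (exists(cw, envir = tab)) get(cw, envir = tab) else 0L
      assign(cw, cur + 1L, envir = tab)
    }
  }
  out <- sort(unlist(as.list(tab)))
  out
}

# -- brute-force de Bruijn graph: k-mer nodes, (k-1)-overlap adjacency ----
# returns canonicalised straight-node sequences and the junction count
oracle_dbg <- function(seqs, k) {
  cnt <- oracle_count_kmers(seqs, k)
  kmers <- names(cnt)
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  canon <- function(s) min(s, rc1(s))
  present <- new.env(parent = emptyenv())
  for (x in kmers) assign(x, TRUE, envir = present)
  succs <- function(s) { # oriented successors of oriented k-mer s
    out <- character(0)
    for (b in c("A", "C", "G", "T")) {
      t <- paste0(substring(s, 2), b)
      if (exists(canon(t), envir = present)) out <- c(out, t)
    }
    out
  }
  is_junction <- vapply(kmers, function(x)
    length(succs(x)) > 1 || length(succs(rc1(x))) > 1 || x == rc1(x),
    logical(1))
  names(is_junction) <- kmers
  visited <- new.env(parent = emptyenv())
  units <- character(0)
  for (x in kmers) {
    if (is_junction[[x]] || exists(x, envir = visited)) next
    # walk back
    cur <- x
    repeat {
      pr <- succs(rc1(cur))
      if (length(pr) != 1) break
      p <- rc1(pr)
      if (is_junction[[canon(p)]]) break
      fw <- succs(p)
      if (length(fw) != 1 || canon(fw) != canon(cur)) break
      if (canon(p) == canon(x) || exists(canon(p), envir = visited)) break
      cur <- p
    }
    seqs_acc <- cur
    assign(canon(cur), TRUE, envir = visited)
    repeat {
      nx <- succs(cur)
      if (length(nx) != 1) break
      if (is_junction[[canon(nx)]]) break
      bk <- succs(rc1(nx))
      if (length(bk) != 1) break
      if (exists(canon(nx), envir = visited)) break
      seqs_acc <- paste0(seqs_acc, substring(nx, k, k))
      assign(canon(nx), TRUE, envir = visited)
      cur <- nx
    }
    units <- c(units, canon(seqs_acc))
  }
  list(straight = sort(units), n_junction = sum(is_junction))
}

# -- greedy long-alignment selection, re-derived step by step -------------
oracle_greedy_select <- function(aln, k) {
  ord <- order(-aln$matches, aln$qstart, aln$tstart)
  taken <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in taken) {
      ov <- min(aln$qend[i], aln$qend[j]) - max(aln$qstart[i], aln$qstart[j])
      if (ov >= k) ok <- FALSE
    }
    if (ok) taken <- c(taken, i)
  }
  sort(taken)
}

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x)
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}
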