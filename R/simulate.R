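# Diploid genome and sequencing-library simulator: the test substrate for
# the assembler. Haplotype B is derived from haplotype A by per-base SNVs,
# small indels and highly divergent regions (HDRs, optionally inverted),
# with every variant recorded so B can be reconstructed from A exactly.

#' Specification of a simulated diploid genome
#'
#' @param length haploid genome length in bp.
#' @param snv_rate background per-base heterozygous SNV rate (0-0.2).
#' @param indel_rate background per-base small-indel rate (0-0.2); indel
#'   lengths are geometric with mean `indel_mean`.
#' @param indel_mean mean indel length in bp.
#' @param hdr data frame of highly divergent regions with columns `start`
#'   (1-based, on haplotype A), `length`, `divergence` (per-base SNV rate
#'   inside the HDR) and `inversion` (logical). Intervals must be disjoint
#'   and within bounds.
#' @param repeats optional data frame of planted exact repeats with columns
#'   `length` and `copies`; copies are placed at random positions.
#' @param seed random seed making the genome reproducible.
#' @return an object of class `diploid_spec`.
#' @export
diploid_spec <- function(length = 200000L, snv_rate = 0.01,
                         indel_rate = 5e-4, indel_mean = 3,
                         hdr = NULL, repeats = NULL, seed = 1L) {
  stopifnot(length > 0, snv_rate >= 0, snv_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2)
  if (!is.null(hdr)) {
    hdr <- as.data.frame(hdr)
    stopifnot(all(c("start", "length", "divergence", "inversion") %in% names(hdr)))
    hdr <- hdr[order(hdr$start), , drop = FALSE]
    ends <- hdr$start + hdr$length - 1L
    if (any(hdr$start < 1L) || any(ends > length))
      stop("HDR intervals out of bounds")
    if (nrow(hdr) > 1L && any(hdr$start[-1L] <= ends[-nrow(hdr)]))
      stop("HDR intervals overlap")
    if (any(hdr$divergence < 0 | hdr$divergence > 0.2))
      stop("HDR divergence out of range")
  }
  structure(list(length = as.integer(length), snv_rate = snv_rate,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 hdr = hdr, repeats = repeats, seed = as.integer(seed)),
            class = "diploid_spec")
}

# mutate one segment: SNVs at snv_rate, indels at indel_rate; returns the
# mutated sequence and the variant table in segment-local coordinates
mutate_segment <- function(seg, snv_rate, indel_rate, indel_mean) {
  n <- nchar(seg)
  bases <- strsplit(seg, "")[[1]]
  u <- runif(n)
  snv_pos <- which(u < snv_rate)
  indel_pos <- which(u >= snv_rate & u < snv_rate + indel_rate)
  vars <- list()
  if (length(snv_pos)) {
    alts <- vapply(bases[snv_pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    vars[[1L]] <- data.frame(pos = snv_pos, type = "snv",
                             ref = bases[snv_pos], alt = alts,
                             stringsAsFactors = FALSE)
  }
  if (length(indel_pos)) {
    lens <- rgeom(length(indel_pos), 1 / indel_mean) + 1L
    is_ins <- runif(length(indel_pos)) < 0.5
    ins <- which(is_ins)
    del <- which(!is_ins)
    dl <- list()
    if (length(ins)) {
      dl[[1L]] <- data.frame(
        pos = indel_pos[ins], type = "ins", ref = "",
        alt = vapply(lens[ins], function(l)
          paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
          character(1)),
        stringsAsFactors = FALSE)
    }
    if (length(del)) {
      dpos <- indel_pos[del]
      dlen <- pmin(lens[del], n - dpos + 1L)
      dl[[2L]] <- data.frame(
        pos = dpos, type = "del",
        ref = substring(seg, dpos, dpos + dlen - 1L), alt = "",
        stringsAsFactors = FALSE)
    }
    vars[[2L]] <- do.call(rbind, dl)
  }
  vars <- do.call(rbind, vars)
  if (is.null(vars) || nrow(vars) == 0L) {
    return(list(seq = seg,
                vars = data.frame(pos = integer(0), type = character(0),
                                  ref = character(0), alt = character(0),
                                  stringsAsFactors = FALSE)))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  # drop variants overlapping an earlier deletion
  keep <- logical(nrow(vars))
  last_end <- 0L
  for (i in seq_len(nrow(vars))) {
    if (vars$pos[i] <= last_end) next
    keep[i] <- TRUE
    if (vars$type[i] == "del")
      last_end <- vars$pos[i] + nchar(vars$ref[i]) - 1L
  }
  vars <- vars[keep, , drop = FALSE]
  list(seq = apply_segment_variants(seg, vars), vars = vars)
}

# apply a sorted, non-overlapping variant table to one segment
apply_segment_variants <- function(seg, vars) {
  if (nrow(vars) == 0L) return(seg)
  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    if (p > cur) pieces <- c(pieces, substring(seg, cur, p - 1L))
    if (vars$type[i] == "snv") {
      pieces <- c(pieces, vars$alt[i])
      cur <- p + 1L
    } else if (vars$type[i] == "ins") {
      pieces <- c(pieces, substring(seg, p, p), vars$alt[i])
      cur <- p + 1L
    } else { # del
      cur <- p + nchar(vars$ref[i])
    }
  }
  if (cur <= nchar(seg)) pieces <- c(pieces, substring(seg, cur, nchar(seg)))
  paste(pieces, collapse = "")
}

#' Simulate a diploid genome
#'
#' Generates haplotype A (uniform random background, optionally with planted
#' repeats) and derives haplotype B by Bernoulli per-base SNVs and geometric
#' indels at background rates, with elevated divergence and optional
#' inversion inside each HDR. Deterministic under the spec seed.
#'
#' @param spec a [diploid_spec()].
#' @return list with `hap_a`, `hap_b` (strings), `variants` (data frame with
#'   1-based haplotype-A coordinates), and `hdr` (the realised HDR table).
#' @export
simulate_diploid <- function(spec) {
  stopifnot(inherits(spec, "diploid_spec"))
  with_seed(spec$seed, {
    hap_a <- rand_dna(spec$length)
    if (!is.null(spec$repeats)) {
      for (i in seq_len(nrow(spec$repeats))) {
        rl <- spec$repeats$length[i]
        unit <- rand_dna(rl)
        pos <- sort(sample.int(spec$length - rl, spec$repeats$copies[i]))
        for (p in pos) substr(hap_a, p, p + rl - 1L) <- unit
      }
    }
    segs <- segment_table(spec)
    pieces <- character(nrow(segs))
    all_vars <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      seg <- substring(hap_a, segs$start[i], segs$end[i])
      if (segs$hdr[i]) {
        m <- mutate_segment(seg, segs$divergence[i], 0, spec$indel_mean)
      } else {
        m <- mutate_segment(seg, spec$snv_rate, spec$indel_rate,
                            spec$indel_mean)
      }
      if (segs$inversion[i]) m$seq <- revcomp(m$seq)
      pieces[i] <- m$seq
      if (nrow(m$vars)) {
        m$vars$pos <- m$vars$pos + segs$start[i] - 1L
        all_vars[[i]] <- m$vars
      }
    }
    variants <- do.call(rbind, all_vars)
    if (is.null(variants))
      variants <- data.frame(pos = integer(0), type = character(0),
                             ref = character(0), alt = character(0),
                             stringsAsFactors = FALSE)
    list(hap_a = hap_a, hap_b = paste(pieces, collapse = ""),
         variants = variants, hdr = spec$hdr)
  })
}

# partition [1, length] into HDR and non-HDR segments
segment_table <- function(spec) {
  n <- spec$length
  if (is.null(spec$hdr) || nrow(spec$hdr) == 0L) {
    return(data.frame(start = 1L, end = n, hdr = FALSE, divergence = 0,
                      inversion = FALSE))
  }
  h <- spec$hdr
  rows <- list()
  cur <- 1L
  for (i in seq_len(nrow(h))) {
    s <- h$start[i]; e <- s + h$length[i] - 1L
    if (s > cur)
      rows[[length(rows) + 1L]] <- data.frame(start = cur, end = s - 1L,
                                              hdr = FALSE, divergence = 0,
                                              inversion = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(start = s, end = e, hdr = TRUE,
                                            divergence = h$divergence[i],
                                            inversion = isTRUE(h$inversion[i]))
    cur <- e + 1L
  }
  if (cur <= n)
    rows[[length(rows) + 1L]] <- data.frame(start = cur, end = n, hdr = FALSE,
                                            divergence = 0, inversion = FALSE)
  do.call(rbind, rows)
}

#' Reconstruct haplotype B from haplotype A and the truth tables
#'
#' Round-trip check of the simulator: applies the recorded variants
#' segment-wise and re-inverts inverted HDRs.
#'
#' @param hap_a haplotype A string.
#' @param variants variant table from [simulate_diploid()].
#' @param hdr HDR table (or `NULL`).
#' @return the reconstructed haplotype B string.
#' @export
reconstruct_hap_b <- function(hap_a, variants, hdr = NULL) {
  spec_like <- list(length = nchar(hap_a), hdr = hdr)
  segs <- segment_table(spec_like)
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    seg <- substring(hap_a, segs$start[i], segs$end[i])
    v <- variants[variants$pos >= segs$start[i] & variants$pos <= segs$end[i], ,
                  drop = FALSE]
    v$pos <- v$pos - segs$start[i] + 1L
    out <- apply_segment_variants(seg, v)
    if (segs$inversion[i]) out <- revcomp(out)
    pieces[i] <- out
  }
  paste(pieces, collapse = "")
}

#' Specification of a sequencing library
#'
#' @param type one of `"paired"` (inward paired-end), `"mate"` (outward
#'   mate-pair), `"linked"` (barcoded paired-end from long fragments) or
#'   `"long"` (single-molecule reads).
#' @param read_len read length in bp (for `"long"`: mean read length).
#' @param insert_mean,insert_sd insert size distribution (bp); for `"mate"`
#'   the insert is the jump size. Ignored for `"long"`.
#' @param coverage target total sequence coverage of the haploid genome
#'   length (both haplotypes together).
#' @param error_rate per-base substitution error rate.
#' @param frag_len linked-read DNA fragment length (bp).
#' @param reads_per_frag read pairs per linked-read fragment.
#' @param seed seed for read simulation.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(type = c("paired", "mate", "linked", "long"),
                         read_len = 150L, insert_mean = 400L,
                         insert_sd = NULL, coverage = 40,
                         error_rate = 0, frag_len = 50000L,
                         reads_per_frag = 40L, seed = 1L) {
  type <- match.arg(type)
  insert_sd <- insert_sd %||% round(insert_mean * 0.1)
  stopifnot(coverage > 0, read_len > 0, error_rate >= 0, error_rate < 1)
  if (type %in% c("paired", "linked") && insert_mean < read_len)
    stop("insert mean below read length for an inward library")
  structure(list(type = type, read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd, coverage = coverage,
                 error_rate = error_rate, frag_len = as.integer(frag_len),
                 reads_per_frag = as.integer(reads_per_frag),
                 seed = as.integer(seed)),
            class = "library_spec")
}

apply_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    b <- strsplit(reads[i], "")[[1]]
    b[pos] <- vapply(b[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    reads[i] <- paste(b, collapse = "")
  }
  reads
}

#' Simulate reads from a diploid genome
#'
#' Fragments are drawn alternately from the two haplotypes until the target
#' total coverage is reached. Paired-end reads are inward-facing; mate-pairs
#' outward-facing; linked reads are grouped under shared barcodes (one
#' barcode per source fragment, `BX:Z:` tag in the read name); long reads
#' carry i.i.d. substitution errors. Deterministic under the library seed.
#'
#' @param haps list with `hap_a` and `hap_b` strings (e.g. from
#'   [simulate_diploid()]).
#' @param lib a [library_spec()].
#' @return a list of class `read_library`: `spec`, `reads1`, `reads2`
#'   (`NULL` for `"long"`), `names`, and a truth `placements` data frame
#'   (fragment, haplotype, 1-based position, strand).
#' @export
simulate_reads <- function(haps, lib) {
  stopifnot(inherits(lib, "library_spec"))
  hs <- c(haps$hap_a, haps$hap_b)
  if (any(!nzchar(hs))) stop("empty haplotype sequence")
  hlen <- nchar(hs)
  with_seed(lib$seed, {
    out <- switch(lib$type,
      paired = , mate = sim_pairs(hs, hlen, lib),
      linked = sim_linked(hs, hlen, lib),
      long = sim_long(hs, hlen, lib))
    structure(c(out, list(spec = lib)), class = "read_library")
  })
}

sim_pairs <- function(hs, hlen, lib) {
  L <- lib$read_len
  n_frag <- ceiling(lib$coverage * hlen[1] / (2 * L))
  hap <- rep_len(c(1L, 2L), n_frag)
  ins <- pmax(round(rnorm(n_frag, lib$insert_mean, lib$insert_sd)), L)
  ins <- pmin(ins, hlen[hap])
  start <- floor(runif(n_frag) * (hlen[hap] - ins + 1L)) + 1L
  strand <- sample(c("+", "-"), n_frag, TRUE)
  frags <- substring(hs[hap], start, start + ins - 1L)
  flip <- strand == "-"
  frags[flip] <- revcomp(frags[flip])
  r1 <- substring(frags, 1L, L)
  r2 <- revcomp(substring(frags, ins - L + 1L, ins))
  if (lib$type == "mate") { # outward orientation
    r1 <- revcomp(r1)
    r2 <- revcomp(r2)
  }
  r1 <- apply_errors(r1, lib$error_rate)
  r2 <- apply_errors(r2, lib$error_rate)
  nm <- sprintf("frag%07d", seq_len(n_frag))
  list(reads1 = setNames(r1, paste0(nm, "/1")),
       reads2 = setNames(r2, paste0(nm, "/2")),
       placements = data.frame(fragment = nm, hap = hap, pos = start,
                               insert = ins, strand = strand,
                               stringsAsFactors = FALSE))
}

sim_linked <- function(hs, hlen, lib) {
  L <- lib$read_len
  pair_bases <- 2L * L
  n_frag <- ceiling(lib$coverage * hlen[1] / (lib$reads_per_frag * pair_bases))
  hap <- rep_len(c(1L, 2L), n_frag)
  flen <- pmin(lib$frag_len, hlen[hap])
  fstart <- floor(runif(n_frag) * (hlen[hap] - flen + 1L)) + 1L
  r1 <- r2 <- names1 <- character(0)
  plc <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    bc <- sprintf("BC%06d", i)
    ins <- pmax(round(rnorm(lib$reads_per_frag, lib$insert_mean,
                            lib$insert_sd)), L)
    ins <- pmin(ins, flen[i])
    ps <- floor(runif(lib$reads_per_frag) * (flen[i] - ins + 1L)) + fstart[i]
    frag <- substring(hs[hap[i]], ps, ps + ins - 1L)
    r1 <- c(r1, substring(frag, 1L, L))
    r2 <- c(r2, revcomp(substring(frag, ins - L + 1L, ins)))
    names1 <- c(names1, sprintf("lnk%06d_%03d BX:Z:%s", i,
                                seq_len(lib$reads_per_frag), bc))
    plc[[i]] <- data.frame(fragment = sprintf("lnk%06d", i), hap = hap[i],
                           pos = fstart[i], insert = flen[i], strand = "+",
                           stringsAsFactors = FALSE)
  }
  r1 <- apply_errors(r1, lib$error_rate)
  r2 <- apply_errors(r2, lib$error_rate)
  list(reads1 = setNames(r1, sub(" ", "/1 ", names1, fixed = TRUE)),
       reads2 = setNames(r2, sub(" ", "/2 ", names1, fixed = TRUE)),
       placements = unique(do.call(rbind, plc)))
}

sim_long <- function(hs, hlen, lib) {
  L <- lib$read_len
  n_read <- ceiling(lib$coverage * hlen[1] / L)
  hap <- rep_len(c(1L, 2L), n_read)
  rl <- pmin(pmax(round(rnorm(n_read, L, L * 0.1)), 500L), hlen[hap])
  start <- floor(runif(n_read) * (hlen[hap] - rl + 1L)) + 1L
  strand <- sample(c("+", "-"), n_read, TRUE)
  rd <- substring(hs[hap], start, start + rl - 1L)
  rd[strand == "-"] <- revcomp(rd[strand == "-"])
  rd <- apply_errors(rd, lib$error_rate)
  nm <- sprintf("long%06d", seq_len(n_read))
  list(reads1 = setNames(rd, nm), reads2 = NULL,
       placements = data.frame(fragment = nm, hap = hap, pos = start,
                               insert = rl, strand = strand,
                               stringsAsFactors = FALSE))
}
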